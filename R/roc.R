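#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' The AUC is computed as the tie-corrected Mann-Whitney probability that a
#' randomly chosen positive period scores higher than a randomly chosen
#' negative one (ties count one half).  The 95% CI uses the Hanley-McNeil
#' variance by default (the nonparametric default of classic SPSS
#' analyses), or the DeLong placement variance.  The threshold sweep visits
#' every distinct observed score value; a period is flagged when its score
#' is greater than or equal to the threshold.
#'
#' @param scores Numeric crowding-score values, finite; `NA` pairs are
#'   dropped.
#' @param labels Logical (or 0/1) reference-standard labels; both classes
#'   must be present.
#' @param ci_method `"hanley"` (default) or `"delong"`.
#' @param conf_level Confidence level of the AUC interval.
#' @return An object of class `ed_roc`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `auc_ci`, `ci_method`,
#'   `chosen_cutoff`, `flagged_fraction`, `n_pos`, `n_neg`.
#' @seealso [best_cutoff()]
#' @export
#' @examples
#' r <- roc_auc(c(1, 2, 3, 4, 5, 6), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' r$auc  # 1: perfectly separated
roc_auc <- function(scores, labels, ci_method = c("hanley", "delong"),
                    conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    labels <- labels == 1
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present in the reference standard",
         call. = FALSE)
  }

  r <- rank(scores)  # midranks: ties contribute 1/2
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  v <- switch(ci_method,
    hanley = auc_var_hanley(auc, n_pos, n_neg),
    delong = auc_var_delong(scores, labels)
  )
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * sqrt(v)), min(1, auc + zq * sqrt(v)))

  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))

  res <- structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, auc_ci = ci, ci_method = ci_method,
         conf_level = conf_level,
         chosen_cutoff = NA_real_, flagged_fraction = NA_real_,
         n_pos = n_pos, n_neg = n_neg),
    class = "ed_roc"
  )
  bc <- best_cutoff(res)
  res$chosen_cutoff <- bc$threshold
  res$flagged_fraction <- mean(scores >= bc$threshold)
  res
}

auc_var_hanley <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

auc_var_delong <- function(scores, labels) {
  x <- scores[labels]   # positives
  y <- scores[!labels]  # negatives
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(a) mean(psi(a, y)), numeric(1))
  v01 <- vapply(y, function(b) mean(psi(x, b)), numeric(1))
  var(v10) / length(x) + var(v01) / length(y)
}

#' Youden-index cutoff
#'
#' Selects the threshold that maximises Youden's J = sensitivity +
#' specificity - 1, the usual operationalisation of "highest sensitivity
#' and specificity".  Ties are broken toward the lower threshold (higher
#' sensitivity).  When all scores are identical the single degenerate
#' threshold (J = 0) is returned with a warning.
#'
#' @param roc An `ed_roc` object from [roc_auc()].
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
best_cutoff <- function(roc) {
  stopifnot(inherits(roc, "ed_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  i <- which(j == max(j))[1L]  # thresholds sorted ascending: first = lowest
  if (length(roc$thresholds) == 1L) {
    warning("all scores identical: degenerate cutoff with J = 0",
            call. = FALSE)
  }
  list(threshold = roc$thresholds[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i], youden_j = j[i])
}

#' @export
print.ed_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: %d positives / %d negatives\n  AUC %.3f (%s %.0f%% CI %.3f-%.3f)\n",
    x$n_pos, x$n_neg, x$auc,
    if (x$ci_method == "hanley") "Hanley-McNeil" else "DeLong",
    100 * x$conf_level, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  Youden cutoff %.3f (flags %.1f%% of periods)\n",
              x$chosen_cutoff, 100 * x$flagged_fraction))
  invisible(x)
}
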