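#' 2x2 confusion matrix
#'
#' Integer counts of a flagged-vs-event classification: `tp` flagged
#' periods with the event, `fp` flagged without, `fn` unflagged with, `tn`
#' unflagged without.
#'
#' @param tp,fp,fn,tn Non-negative integer counts; the total must be >= 1.
#' @return An object of class `ed_confusion`.
#' @export
#' @examples
#' confusion_matrix(tp = 13, fp = 99, fn = 19, tn = 328)
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts %% 1 != 0)) {
    stop("confusion-matrix cells must be non-negative integers",
         call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion matrix is empty", call. = FALSE)
  structure(as.list(as.integer(counts)) |>
              stats::setNames(c("tp", "fp", "fn", "tn")),
            class = "ed_confusion")
}

#' @export
print.ed_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("flagged", "not flagged"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Exact Clopper-Pearson binomial interval
#'
#' Two-sided exact interval for a binomial proportion, via the beta-quantile
#' closed form of the tail-probability inversion (identical to the interval
#' reported by [stats::binom.test()]).
#'
#' @param x Number of successes.
#' @param n Number of trials, `>= 1`.
#' @param conf_level Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
#' @examples
#' clopper_pearson(13, 32)
clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (n < 1 || x < 0 || x > n || x %% 1 != 0 || n %% 1 != 0) {
    stop("need integer 0 <= x <= n with n >= 1", call. = FALSE)
  }
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic accuracy summary of a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)` and
#' NPV `tn/(tn+fn)`, each with a two-sided exact Clopper-Pearson interval,
#' plus the Pearson chi-square association p-value of the table.  A metric
#' whose denominator is zero is returned as `NA` (with `NA` CI) while the
#' others are still computed.
#'
#' @param cm An [confusion_matrix()] object.
#' @param conf_level Confidence level for the intervals.
#' @return An object of class `ed_diag`: list with one `list(estimate,
#'   lower, upper, x, n)` per metric, and `p_value`.
#' @export
#' @examples
#' d <- diagnostics(confusion_matrix(13, 99, 19, 328))
#' round(100 * d$npv$estimate, 1)  # 94.5
diagnostics <- function(cm, conf_level = 0.95) {
  stopifnot(inherits(cm, "ed_confusion"))
  metric <- function(x, n) {
    if (n == 0) {
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  x = x, n = n))
    }
    ci <- clopper_pearson(x, n, conf_level)
    list(estimate = x / n, lower = ci[["lower"]], upper = ci[["upper"]],
         x = x, n = n)
  }
  p <- tryCatch(chi_square_2x2(cm)$p_value, warning = function(w) NA_real_)
  structure(
    list(sensitivity = metric(cm$tp, cm$tp + cm$fn),
         specificity = metric(cm$tn, cm$tn + cm$fp),
         ppv = metric(cm$tp, cm$tp + cm$fp),
         npv = metric(cm$tn, cm$tn + cm$fn),
         p_value = p, conf_level = conf_level),
    class = "ed_diag"
  )
}

#' @export
print.ed_diag <- function(x, ...) {
  fmt <- function(m, name) {
    if (is.na(m$estimate)) {
      cat(sprintf("  %-12s undefined (0 denominator)\n", name))
    } else {
      cat(sprintf("  %-12s %5.1f%% (%.1f-%.1f)  [%d/%d]\n", name,
                  100 * m$estimate, 100 * m$lower, 100 * m$upper, m$x, m$n))
    }
  }
  cat(sprintf("Diagnostic summary (%.0f%% Clopper-Pearson CIs):\n",
              100 * x$conf_level))
  fmt(x$sensitivity, "sensitivity")
  fmt(x$specificity, "specificity")
  fmt(x$ppv, "PPV")
  fmt(x$npv, "NPV")
  cat(sprintf("  association p = %.4g\n", x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default; the Yates correction is
#' available by flag.  A zero row or column marginal makes the statistic
#' undefined: `NA` is returned with a warning.
#'
#' @param cm An [confusion_matrix()] object or a 2x2 numeric matrix.
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic`, `p_value`, `df`, `correct`.
#' @export
#' @examples
#' chi_square_2x2(confusion_matrix(10, 0, 0, 10))$statistic  # 20
chi_square_2x2 <- function(cm, correct = FALSE) {
  m <- if (inherits(cm, "ed_confusion")) {
    matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2, byrow = TRUE)
  } else if (is.matrix(cm) && all(dim(cm) == 2L)) {
    cm
  } else {
    stop("cm must be an ed_confusion object or a 2x2 matrix", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero marginal: chi-square statistic undefined", call. = FALSE)
    return(list(statistic = NA_real_, p_value = NA_real_, df = 1L,
                correct = correct))
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = 1L, correct = correct)
}

#' Reconstruct a 2x2 table from printed summary figures
#'
#' Given a sensitivity and specificity printed to a fixed number of decimal
#' places (percent scale), the number of flagged units and the total,
#' enumerates every integer table `(tp, fp, fn, tn)` consistent with the
#' rounding and returns it if unique.  This recovers worked-example tables
#' from published summary rows.
#'
#' @param sensitivity,specificity Printed percentages (e.g. `40.6`).
#' @param flagged Number of flagged units (`tp + fp`).
#' @param total Total units.
#' @param digits Decimal places of the printed percentages.
#' @return An [confusion_matrix()] object, or an error naming the number of
#'   consistent tables when the reconstruction is not unique.
#' @export
#' @examples
#' confusion_from_summary(40.6, 76.8, flagged = 112, total = 459)
confusion_from_summary <- function(sensitivity, specificity, flagged,
                                   total, digits = 1) {
  stopifnot(flagged >= 0, flagged <= total, total >= 2)
  half <- 0.5 * 10^(-digits) + 1e-9  # half-ulp band of the printed value
  hits <- list()
  for (pos in seq_len(total - 1L)) {
    neg <- total - pos
    tp_range <- 0:min(pos, flagged)
    for (tp in tp_range) {
      fp <- flagged - tp
      if (fp > neg) next
      tn <- neg - fp
      if (abs(100 * tp / pos - sensitivity) > half) next
      if (abs(100 * tn / neg - specificity) > half) next
      hits[[length(hits) + 1L]] <- c(tp = tp, fp = fp, fn = pos - tp,
                                     tn = tn)
    }
  }
  if (length(hits) != 1L) {
    stop("printed figures are consistent with ", length(hits),
         " integer tables; cannot reconstruct a unique 2x2", call. = FALSE)
  }
  h <- hits[[1L]]
  confusion_matrix(h[["tp"]], h[["fp"]], h[["fn"]], h[["tn"]])
}
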