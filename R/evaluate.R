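#' Percentage to printed precision
#'
#' Report-layer helper: `100 * x / n` rounded to `digits` decimals, the
#' form in which descriptive proportions are printed (e.g. 24 of 459
#' periods is 5.2).
#'
#' @param x Numerator count.
#' @param n Denominator count, `>= 1`.
#' @param digits Decimal places.
#' @return Numeric percentage.
#' @export
#' @examples
#' pct(24, 459)  # 5.2
pct <- function(x, n, digits = 1) {
  stopifnot(n >= 1)
  round(100 * x / n, digits)
}

#' Inflate a planned sample size for anticipated missing data
#'
#' Rounds `n * (1 + inflation)` up to the next integer, the usual way a
#' planned sample size (e.g. 437 periods) is padded (5% gives 459).
#'
#' @param n Planned sample size.
#' @param inflation Fractional inflation, default 0.05.
#' @return Integer inflated size.
#' @export
#' @examples
#' sample_size_inflated(437)  # 459
sample_size_inflated <- function(n, inflation = 0.05) {
  stopifnot(n >= 1, inflation >= 0)
  as.integer(ceiling(n * (1 + inflation)))
}

median_iqr <- function(x, digits = 1) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%s (%s-%s)", round(q[2], digits), round(q[1], digits),
          round(q[3], digits))
}

mean_sd <- function(x, digits = 2) {
  sprintf("%s (%s)", round(mean(x), digits), round(sd(x), digits))
}

#' Evaluate crowding scores against perception and adverse events
#'
#' Runs the complete diagnostic evaluation of the four crowding scores on a
#' study of two-hour ED periods:
#' \describe{
#'   \item{table1}{per-shift descriptives (median/IQR) of staffing, census
#'     and boarding, with one-way ANOVA p-values across shifts;}
#'   \item{table2}{per-shift mean (SD) of each crowding score and of code
#'     activations / adverse events;}
#'   \item{correlations}{Spearman rho of each score against the Likert
#'     perception rating (undefined EDWIN periods excluded pairwise, count
#'     reported);}
#'   \item{rocs}{ROC/AUC of each score against the overcrowding reference
#'     standard, Likert `>= likert_threshold`;}
#'   \item{table3}{Youden cutoff of each score from its perception ROC,
#'     then the 2x2 diagnostics of the resulting overcrowding flag against
#'     the period-level outcome "any adverse event", with exact CIs and
#'     chi-square association p-values.}
#' }
#' A degenerate reference standard (one Likert class only) yields a partial
#' report: the ROC and table3 stages are omitted and listed in `$notes`.
#'
#' @param periods Full-schema period table (see [read_periods()]).
#' @param scores Optional pre-computed [score_all()] output; computed from
#'   `periods` when `NULL`.
#' @param likert_threshold Likert rating at or above which a period counts
#'   as overcrowded (reference standard), in 2..6.
#' @param config An [score_config()] used when `scores` is `NULL`.
#' @param ci_method AUC confidence-interval method, see [roc_auc()].
#' @return An object of class `ed_report`.
#' @export
#' @examples
#' p <- simulate_study(sim_config(n_periods = 120, seed = 11))
#' r <- evaluate_study(p)
#' r$correlations
evaluate_study <- function(periods, scores = NULL, likert_threshold = 5,
                           config = score_config(),
                           ci_method = c("hanley", "delong")) {
  ci_method <- match.arg(ci_method)
  if (!(likert_threshold %in% 2:6)) {
    stop("likert_threshold must be in 2..6", call. = FALSE)
  }
  periods <- validate_periods(periods, level = "full")
  if (is.null(scores)) scores <- suppressMessages(score_all(periods, config))
  if (nrow(scores) != nrow(periods)) {
    stop("scores and periods disagree in length", call. = FALSE)
  }

  notes <- character(0)
  shift <- factor(periods$shift, levels = .shift_levels)
  census <- rowSums(periods[.ctas_columns])
  reference <- periods$likert >= likert_threshold
  any_ae <- rowSums(periods[.ae_columns]) > 0

  ## table 1: per-shift descriptives
  desc_vars <- list(
    physicians = periods$physicians, nurses = periods$nurses,
    patients_on_board = census,
    ctas_I = periods$ctas1, ctas_II = periods$ctas2,
    ctas_III = periods$ctas3, ctas_IV = periods$ctas4,
    ctas_V = periods$ctas5,
    waiting = periods$waiting,
    disposition_plan = periods$boarding + periods$referrals,
    admitted_boarding = periods$boarding, referrals = periods$referrals
  )
  table1 <- do.call(rbind, lapply(names(desc_vars), function(nm) {
    v <- desc_vars[[nm]]
    p <- tryCatch(compare_groups(v, shift)$p_value, error = function(e) NA)
    data.frame(variable = nm,
               total = median_iqr(v),
               morning = median_iqr(v[shift == "morning"]),
               evening = median_iqr(v[shift == "evening"]),
               night = median_iqr(v[shift == "night"]),
               p_value = p)
  }))

  ## table 2: scores and event rates per shift
  score_rows <- lapply(.score_names, function(nm) {
    v <- scores[[nm]]
    ok <- !is.na(v)
    p <- tryCatch(compare_groups(v[ok], shift[ok])$p_value,
                  error = function(e) NA)
    data.frame(variable = nm, total = mean_sd(v[ok]),
               morning = mean_sd(v[ok & shift == "morning"]),
               evening = mean_sd(v[ok & shift == "evening"]),
               night = mean_sd(v[ok & shift == "night"]),
               p_value = p)
  })
  codes_total <- rowSums(periods[.code_columns])
  aes_total <- rowSums(periods[.ae_columns])
  rate_vars <- list(code_activations = codes_total,
                    adverse_events = aes_total,
                    ihca = periods$ae_ihca)
  rate_rows <- lapply(names(rate_vars), function(nm) {
    v <- rate_vars[[nm]]
    p <- tryCatch(compare_groups(v, shift)$p_value, error = function(e) NA)
    data.frame(variable = nm, total = mean_sd(v),
               morning = mean_sd(v[shift == "morning"]),
               evening = mean_sd(v[shift == "evening"]),
               night = mean_sd(v[shift == "night"]),
               p_value = p)
  })
  table2 <- do.call(rbind, c(score_rows, rate_rows))

  ## correlations with perception
  correlations <- do.call(rbind, lapply(.score_names, function(nm) {
    v <- scores[[nm]]
    sr <- tryCatch(suppressWarnings(spearman_rho(v, periods$likert)),
                   error = function(e) list(rho = NA, p_value = NA,
                                            n = sum(!is.na(v))))
    data.frame(score = nm, rho = sr$rho, p_value = sr$p_value,
               n_used = sr$n, n_excluded = sum(is.na(v)))
  }))

  ## ROC against the perception reference standard, then adverse-event
  ## diagnostics at the Youden cutoff
  rocs <- list()
  table3 <- NULL
  if (length(unique(reference)) < 2L) {
    notes <- c(notes, paste0(
      "reference standard degenerate (all periods on one side of Likert ",
      likert_threshold, "): ROC and cutoff diagnostics omitted"))
  } else {
    t3 <- lapply(.score_names, function(nm) {
      v <- scores[[nm]]
      ok <- !is.na(v)
      roc <- roc_auc(v[ok], reference[ok], ci_method = ci_method)
      cut <- best_cutoff(roc)
      flag <- v >= cut$threshold
      flag[!ok] <- FALSE
      cm <- confusion_matrix(sum(flag & any_ae), sum(flag & !any_ae),
                             sum(!flag & any_ae), sum(!flag & !any_ae))
      d <- diagnostics(cm)
      rocs[[nm]] <<- roc
      fmt_ci <- function(m) sprintf("%.1f (%.1f-%.1f)", 100 * m$estimate,
                                    100 * m$lower, 100 * m$upper)
      data.frame(
        score = nm, cutoff = cut$threshold,
        flagged = sum(flag), flagged_pct = pct(sum(flag), length(flag)),
        auc = roc$auc, auc_lower = roc$auc_ci[1], auc_upper = roc$auc_ci[2],
        sensitivity = fmt_ci(d$sensitivity),
        specificity = fmt_ci(d$specificity),
        ppv = fmt_ci(d$ppv), npv = fmt_ci(d$npv),
        p_value = d$p_value
      )
    })
    table3 <- do.call(rbind, t3)
  }

  structure(
    list(n_periods = nrow(periods),
         n_patients = sum(census),
         n_reference_positive = sum(reference),
         reference_positive_pct = pct(sum(reference), nrow(periods)),
         n_any_ae = sum(any_ae),
         likert_threshold = likert_threshold,
         table1 = table1, table2 = table2,
         correlations = correlations,
         rocs = rocs, table3 = table3, notes = notes),
    class = "ed_report"
  )
}

#' @export
print.ed_report <- function(x, ...) {
  cat(sprintf("ED crowding evaluation: %d periods, %d patients\n",
              x$n_periods, x$n_patients))
  cat(sprintf("  overcrowded by perception (Likert >= %d): %d (%.1f%%)\n",
              x$likert_threshold, x$n_reference_positive,
              x$reference_positive_pct))
  cat(sprintf("  periods with any adverse event: %d\n\n", x$n_any_ae))
  cat("Spearman correlation with perception:\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  if (!is.null(x$table3)) {
    cat("\nCutoff diagnostics vs any adverse event:\n")
    show <- x$table3[, c("score", "cutoff", "flagged_pct", "auc",
                         "sensitivity", "specificity", "ppv", "npv",
                         "p_value")]
    print(show, row.names = FALSE, digits = 3)
  }
  for (n in x$notes) cat("note: ", n, "\n", sep = "")
  invisible(x)
}
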