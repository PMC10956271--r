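# Row-level validation of period tables.  `level = "scoring"` checks only
# the columns the score calculators need; `level = "full"` enforces the
# complete CSV schema including perception, code and adverse-event columns.
validate_periods <- function(periods, level = c("full", "scoring")) {
  level <- match.arg(level)
  if (!is.data.frame(periods)) {
    stop("periods must be a data frame", call. = FALSE)
  }
  needed <- if (level == "scoring") {
    c("period_index", .ctas_columns, "physicians", "nurses", "waiting",
      "boarding", "referrals")
  } else {
    .period_columns
  }
  missing_cols <- setdiff(needed, names(periods))
  if (length(missing_cols)) {
    stop("period table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      shown <- utils::head(rows, 5L)
      more <- if (length(rows) > 5L) sprintf(" (+%d more)", length(rows) - 5L)
              else ""
      problems <<- c(problems,
                     sprintf("row %s: %s%s",
                             paste(shown, collapse = ", "), what, more))
    }
  }

  count_cols <- intersect(
    c("period_index", .ctas_columns, "waiting", "boarding", "referrals",
      .code_columns, .ae_columns),
    names(periods)
  )
  for (cl in count_cols) {
    v <- periods[[cl]]
    bad <- which(!is.finite(v) | v < 0 | v %% 1 != 0)
    note(bad, paste0(cl, " must be a non-negative integer"))
  }
  for (cl in intersect(c("physicians", "nurses", "bays"), names(periods))) {
    v <- periods[[cl]]
    bad <- which(!is.finite(v) | v < 1 | v %% 1 != 0)
    note(bad, paste0(cl, " must be a positive integer"))
  }

  if (!length(problems)) {
    census <- rowSums(periods[.ctas_columns])
    note(which(periods$boarding + periods$referrals > census),
         "boarding + referrals exceed the on-board census")
    if (level == "full") {
      bad_shift <- which(!(periods$shift %in% .shift_levels))
      note(bad_shift, paste0("shift must be one of ",
                             paste(.shift_levels, collapse = "/")))
      note(which(!(periods$likert %in% 1:6)), "likert must be in 1..6")
      for (k in c("stroke", "stemi", "sepsis", "tbi")) {
        bad <- which(periods[[paste0("ae_", k)]] >
                       periods[[paste0("code_", k)]])
        note(bad, paste0("ae_", k, " exceeds code_", k))
      }
    }
  }

  if (length(problems)) {
    stop("invalid period table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  periods
}
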