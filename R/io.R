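#' Read a period table from CSV
#'
#' One row per two-hour ED period.  The header is fixed:
#' `period_index, shift, ctas1..ctas5, physicians, nurses, bays, waiting,
#' boarding, referrals, likert, code_stroke, code_stemi, code_sepsis,
#' code_tbi, ae_stroke, ae_stemi, ae_sepsis, ae_tbi, ae_ihca`.
#' Every row is validated (non-negative integer counts, shift names,
#' Likert in 1..6, boarding + referrals within the census, per-type
#' adverse events within code activations); violations abort with the
#' offending row numbers.
#'
#' @param path CSV file path.
#' @return Validated data frame of period snapshots.
#' @export
read_periods <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.period_columns, names(df))
  if (length(missing_cols)) {
    stop("input ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in setdiff(.period_columns, "shift")) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))))
      stop("column ", cl, " is not numeric (first bad data row: ",
           if (length(bad)) bad[1] else "?", ")", call. = FALSE)
    }
  }
  validate_periods(df[.period_columns], level = "full")
}

#' Write a period table to CSV
#'
#' @param periods Period table in the schema of [read_periods()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_periods <- function(periods, path) {
  periods <- validate_periods(periods, level = "full")
  write.csv(periods[.period_columns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write score records to CSV
#'
#' Undefined EDWIN values (boarders filling every bay) are written as empty
#' fields.
#'
#' @param scores [score_all()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a key-value configuration file
#'
#' Plain `key = value` lines, `#` comments, optional `[section]` headers
#' (keys inside a section are returned in a named sub-list).  Values that
#' parse as numbers are returned numeric; comma-separated values become
#' vectors.
#'
#' @param path Config file path.
#' @return Named list (possibly of sub-lists).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (ln == "") next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config line ", i, " is not 'key = value': ", lines[i],
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(nums)) nums else parts
    if (is.null(section)) out[[key]] <- parsed
    else out[[section]][[key]] <- parsed
  }
  out
}
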