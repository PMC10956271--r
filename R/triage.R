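#' Reversed CTAS acuity weights
#'
#' The Canadian Triage and Acuity Scale (CTAS) assigns level I to the most
#' acute patients and level V to the least.  EDWIN-style workload indices
#' reverse the scale so that acuity contributes positively: level I receives
#' weight 5 and level V weight 1.
#'
#' @return A named integer vector of length 5 mapping CTAS levels
#'   `"I".."V"` to weights `5..1`.
#' @seealso [triage_weight()], [acuity_load()]
#' @export
#' @examples
#' triage_weights()
triage_weights <- function() {
  stats::setNames(5:1, c("I", "II", "III", "IV", "V"))
}

#' Acuity weight of a CTAS level
#'
#' Returns the reversed triage weight `6 - level` used in the EDWIN and Work
#' Score numerators.  Levels may be given as Roman numerals (`"I".."V"`) or
#' integers (`1..5`); the function is vectorised.
#'
#' @param level CTAS level(s): character `"I".."V"` (case-insensitive) or
#'   integer `1..5`.
#' @param weights Named weight vector as produced by [triage_weights()].
#'   Must map I..V bijectively onto 5..1, strictly decreasing.
#' @return Integer weight(s) in `1..5`.
#' @export
#' @examples
#' triage_weight("I")  # 5, most acute
#' triage_weight(1:5)  # 5 4 3 2 1
triage_weight <- function(level, weights = triage_weights()) {
  check_triage_weights(weights)
  roman <- names(triage_weights())
  if (is.numeric(level)) {
    if (anyNA(level) || any(level %% 1 != 0) || any(level < 1L | level > 5L)) {
      stop("CTAS level must be an integer in 1..5 or one of ",
           paste(roman, collapse = ", "), call. = FALSE)
    }
    lev <- roman[level]
  } else {
    lev <- toupper(trimws(as.character(level)))
    bad <- !(lev %in% roman)
    if (any(bad)) {
      stop("unknown CTAS level(s): ",
           paste(unique(level[bad]), collapse = ", "),
           "; expected I, II, III, IV, V (or 1..5)", call. = FALSE)
    }
  }
  unname(weights[lev])
}

check_triage_weights <- function(weights) {
  roman <- names(triage_weights())
  if (!is.numeric(weights) || length(weights) != 5L ||
      !identical(names(weights), roman)) {
    stop("triage weighting must be a numeric vector named I..V", call. = FALSE)
  }
  if (weights[["I"]] != 5 || weights[["V"]] != 1 ||
      any(diff(weights) >= 0) || anyDuplicated(weights)) {
    stop("triage weighting must be bijective and strictly decreasing with ",
         "weight(I) = 5 and weight(V) = 1", call. = FALSE)
  }
  invisible(weights)
}

#' Acuity-weighted census
#'
#' The EDWIN/Work Score numerator: the sum over CTAS levels of patient count
#' times reversed triage weight.
#'
#' @param ctas_counts Either a numeric vector of 5 non-negative counts in
#'   CTAS order I..V (one period), or a data frame / matrix with columns
#'   `ctas1..ctas5` (one row per period).
#' @param weights Acuity weights, see [triage_weights()].
#' @return Numeric vector of acuity loads, one per period.
#' @export
#' @examples
#' acuity_load(c(1, 2, 4, 1, 0))  # 1*5 + 2*4 + 4*3 + 1*2 = 27
acuity_load <- function(ctas_counts, weights = triage_weights()) {
  check_triage_weights(weights)
  m <- ctas_count_matrix(ctas_counts)
  as.vector(m %*% weights)
}

ctas_count_matrix <- function(ctas_counts) {
  if (is.data.frame(ctas_counts)) {
    if (!all(.ctas_columns %in% names(ctas_counts))) {
      stop("data frame input must contain columns ",
           paste(.ctas_columns, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(ctas_counts[.ctas_columns])
  } else if (is.matrix(ctas_counts)) {
    if (ncol(ctas_counts) != 5L) {
      stop("CTAS count matrix must have 5 columns (levels I..V)",
           call. = FALSE)
    }
    m <- ctas_counts
  } else {
    if (length(ctas_counts) != 5L) {
      stop("CTAS counts must have one entry per level I..V", call. = FALSE)
    }
    m <- matrix(as.numeric(ctas_counts), nrow = 1L)
  }
  storage.mode(m) <- "numeric"
  if (anyNA(m) || any(m < 0) || any(m %% 1 != 0)) {
    stop("CTAS counts must be non-negative integers", call. = FALSE)
  }
  m
}
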