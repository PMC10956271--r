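#' ED occupancy rate (EDOR)
#'
#' On-board census divided by the number of licensed (monitored) treatment
#' beds.  EDOR has no upper bound: the census may exceed the licensed bed
#' count.  Waiting-room patients are not part of the numerator.
#'
#' @param census Non-negative on-board patient count(s), all CTAS levels.
#' @param licensed_beds Positive number of licensed/monitored treatment
#'   beds.  The study site value is 15.
#' @return Numeric EDOR value(s), `>= 0`.
#' @export
#' @examples
#' edor(15, 15)  # full occupancy
#' edor(6, 15)   # a quiet night-shift period
edor <- function(census, licensed_beds = 15) {
  if (length(licensed_beds) != 1L || is.na(licensed_beds) ||
      licensed_beds < 1) {
    stop("licensed_beds must be a single value >= 1", call. = FALSE)
  }
  if (anyNA(census) || any(census < 0)) {
    stop("census must be non-negative", call. = FALSE)
  }
  census / licensed_beds
}

#' ED Work Index (EDWIN) and modified EDWIN
#'
#' EDWIN divides the acuity-weighted census by physician capacity:
#' `sum(n_i * t_i) / (N_a * (B_T - B_A))`, where `n_i` is the patient count
#' at CTAS level i, `t_i` the reversed triage weight, `N_a` the attending
#' physicians on duty, `B_T` the treatment bays and `B_A` the admitted
#' patients boarding in the ED.  The modified EDWIN additionally counts
#' patients with a plan to refer to another hospital as boarders
#' (`include_referrals = TRUE`), shrinking the free-bay denominator, so a
#' defined modified EDWIN is never smaller than the plain EDWIN of the same
#' period.
#'
#' When boarders occupy every bay (`B_T - B_A <= 0`) the index is undefined
#' and `NA` is returned rather than an error or `Inf`, so batch scoring can
#' proceed and rank statistics are not corrupted.
#'
#' @param acuity Acuity-weighted census, see [acuity_load()].
#' @param physicians Attending physicians on duty, `>= 1`.
#' @param bays Treatment bays, `>= 1`.  The study site has 16.
#' @param boarding Admitted patients held in the ED.
#' @param referrals Patients with a plan to refer to another hospital.
#' @param include_referrals If `TRUE`, referral-planned patients count as
#'   boarders (the modified EDWIN).
#' @return Numeric EDWIN value(s); `NA` where the denominator is
#'   non-positive.
#' @export
#' @examples
#' edwin(27, physicians = 4, bays = 16, boarding = 1)            # 0.45
#' edwin(27, 4, 16, boarding = 1, referrals = 1,
#'       include_referrals = TRUE)                               # 27 / 56
edwin <- function(acuity, physicians, bays, boarding, referrals = 0,
                  include_referrals = FALSE) {
  if (anyNA(physicians) || any(physicians < 1)) {
    stop("physicians on duty must be >= 1", call. = FALSE)
  }
  if (anyNA(bays) || any(bays < 1)) {
    stop("treatment bays must be >= 1", call. = FALSE)
  }
  if (anyNA(boarding) || any(boarding < 0) ||
      anyNA(referrals) || any(referrals < 0)) {
    stop("boarding and referral counts must be non-negative", call. = FALSE)
  }
  effective_boarding <- boarding + if (include_referrals) referrals else 0
  free_bays <- bays - effective_boarding
  out <- acuity / (physicians * free_bays)
  out[rep_len(free_bays <= 0, length(out))] <- NA_real_
  out
}

#' Work Score
#'
#' A weighted combination of waiting-room pressure, acuity load per nurse,
#' and boarding burden:
#' `3.23 * P_wait / B_T + 0.097 * sum(n_i t_i) / N_n + 10.92 * B_A / B_T`.
#' Unlike EDWIN it divides the acuity load by nurses rather than
#' physicians, and its boarding term uses admitted boarders only (planned
#' referrals are never included).
#'
#' @param waiting Patients in the waiting room.
#' @param acuity Acuity-weighted census, see [acuity_load()].
#' @param nurses Nurses on duty, `>= 1`.
#' @param boarding Admitted patients held in the ED.
#' @param bays Treatment bays, `>= 1`.
#' @param coefficients Named numeric vector of the three published term
#'   weights; exposed for sensitivity analyses only.
#' @return Numeric Work Score value(s), `>= 0`.
#' @export
#' @examples
#' work_score(waiting = 0, acuity = 27, nurses = 6, boarding = 1, bays = 16)
work_score <- function(waiting, acuity, nurses, boarding, bays,
                       coefficients = c(waiting = 3.23, acuity = 0.097,
                                        boarding = 10.92)) {
  if (anyNA(nurses) || any(nurses < 1)) {
    stop("nurses on duty must be >= 1", call. = FALSE)
  }
  if (anyNA(bays) || any(bays < 1)) {
    stop("treatment bays must be >= 1", call. = FALSE)
  }
  if (anyNA(waiting) || any(waiting < 0) || anyNA(boarding) ||
      any(boarding < 0)) {
    stop("waiting and boarding counts must be non-negative", call. = FALSE)
  }
  stopifnot(identical(names(coefficients), c("waiting", "acuity", "boarding")))
  coefficients[["waiting"]] * waiting / bays +
    coefficients[["acuity"]] * acuity / nurses +
    coefficients[["boarding"]] * boarding / bays
}

#' Scoring configuration
#'
#' Bundles the site parameters of the four crowding scores.  EDOR's
#' denominator (licensed monitored beds, study value 15) is deliberately
#' separate from the EDWIN/Work Score bay count (study value 16); both are
#' configurable, never hard-coded.
#'
#' @param licensed_beds_edor Licensed/monitored beds for the EDOR
#'   denominator.
#' @param treatment_bays Treatment bays used by EDWIN and the Work Score
#'   when the period table has no `bays` column.
#' @param triage_weights Acuity weighting, see [triage_weights()].
#' @return A list of class `ed_score_config`.
#' @export
score_config <- function(licensed_beds_edor = 15, treatment_bays = 16,
                         triage_weights = edcrowd::triage_weights()) {
  check_triage_weights(triage_weights)
  if (licensed_beds_edor < 1 || treatment_bays < 1) {
    stop("bed and bay counts must be >= 1", call. = FALSE)
  }
  structure(
    list(licensed_beds_edor = licensed_beds_edor,
         treatment_bays = treatment_bays,
         triage_weights = triage_weights),
    class = "ed_score_config"
  )
}

#' Score a table of ED periods
#'
#' Computes EDOR, EDWIN, modified EDWIN and the Work Score for every
#' two-hour period in a period table (see [read_periods()] for the column
#' schema).  Periods whose boarders fill every bay get `NA` EDWIN values;
#' the number of such periods is reported via `message()` and carried in
#' the `n_undefined_edwin` attribute so downstream rank statistics can
#' exclude them explicitly.
#'
#' @param periods Data frame of period snapshots; must contain
#'   `period_index`, `ctas1..ctas5`, `physicians`, `nurses`, `waiting`,
#'   `boarding` and `referrals` (a `bays` column is used when present,
#'   otherwise `config$treatment_bays`).
#' @param config An [score_config()] object.
#' @return Data frame with columns `period_index`, `edor`, `edwin`,
#'   `modified_edwin`, `work_score`, one row per input period, in input
#'   order.
#' @export
#' @examples
#' p <- simulate_study(sim_config(n_periods = 12, seed = 42))
#' head(score_all(p))
score_all <- function(periods, config = score_config()) {
  if (!inherits(config, "ed_score_config")) {
    stop("config must come from score_config()", call. = FALSE)
  }
  periods <- validate_periods(periods, level = "scoring")
  if (nrow(periods) == 0L) {
    stop("no periods to score: the input table is empty", call. = FALSE)
  }
  load <- acuity_load(periods, config$triage_weights)
  census <- rowSums(periods[.ctas_columns])
  bays <- if ("bays" %in% names(periods)) periods$bays
          else rep(config$treatment_bays, nrow(periods))
  out <- data.frame(
    period_index = periods$period_index,
    edor = edor(census, config$licensed_beds_edor),
    edwin = edwin(load, periods$physicians, bays, periods$boarding),
    modified_edwin = edwin(load, periods$physicians, bays,
                           periods$boarding, periods$referrals,
                           include_referrals = TRUE),
    work_score = work_score(periods$waiting, load, periods$nurses,
                            periods$boarding, bays)
  )
  n_undef <- sum(is.na(out$edwin)) + sum(is.na(out$modified_edwin))
  if (n_undef > 0L) {
    message(sum(is.na(out$edwin)), " period(s) with undefined EDWIN and ",
            sum(is.na(out$modified_edwin)),
            " with undefined modified EDWIN (boarders occupy all bays); ",
            "carried as NA")
  }
  attr(out, "n_undefined_edwin") <- sum(is.na(out$edwin))
  attr(out, "n_undefined_modified_edwin") <- sum(is.na(out$modified_edwin))
  out
}
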