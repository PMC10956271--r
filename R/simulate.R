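#' Perception link for the synthetic generator
#'
#' The physician Likert rating is modelled as an ordered-threshold
#' (cumulative-link style) transform of a latent crowding index.  The index
#' is a weighted blend of the standardized crowding scores — by default
#' standardized EDOR alone — to which Gaussian noise is added before cutting
#' at five strictly increasing thresholds to produce the six ordinal
#' categories.  Standardization uses fixed reference means/SDs (so a single
#' period can be rated without seeing the whole study), not the realised
#' sample moments.
#'
#' @param index_weights Named non-negative weights over
#'   `c("edor", "edwin", "modified_edwin", "work_score")`; scores with zero
#'   or absent weight are ignored.  Blending prevents the generator from
#'   trivially guaranteeing that EDOR wins every comparison.
#' @param reference Per-score `c(mean, sd)` pairs used for standardization.
#' @param noise_sd Standard deviation of the rating noise (latent-index
#'   units).
#' @param cutpoints Five strictly increasing thresholds on the noisy latent
#'   index separating Likert categories 1..6.
#' @return A list of class `ed_perception_link`.
#' @export
perception_link <- function(index_weights = c(edor = 1),
                            reference = list(
                              edor = c(mean = 0.65, sd = 0.25),
                              edwin = c(mean = 0.45, sd = 0.22),
                              modified_edwin = c(mean = 0.46, sd = 0.22),
                              work_score = c(mean = 1.30, sd = 0.95)
                            ),
                            noise_sd = 0.6,
                            cutpoints = c(-1.70, -0.60, 0.65, 2.25, 3.40)) {
  if (is.null(names(index_weights)) ||
      !all(names(index_weights) %in% .score_names)) {
    stop("index_weights must be named after crowding scores: ",
         paste(.score_names, collapse = ", "), call. = FALSE)
  }
  if (any(index_weights < 0) || sum(index_weights) <= 0) {
    stop("index_weights must be non-negative with positive sum",
         call. = FALSE)
  }
  if (length(cutpoints) != 5L || any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be 5 strictly increasing thresholds",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(index_weights = index_weights, reference = reference,
                 noise_sd = noise_sd, cutpoints = cutpoints),
            class = "ed_perception_link")
}

#' Adverse-event link for the synthetic generator
#'
#' Each code activation carries a Bernoulli risk of breaching its treatment
#' time target (the adverse event); the risk follows a logistic model in the
#' latent crowding index: `p = plogis(intercept + slope * z)`.  A slope of 0
#' gives the null model in which adverse events are independent of
#' crowding, used for type-I-error calibration.
#'
#' @param intercept Log-odds of an adverse event at average crowding
#'   (`z = 0`).  The default corresponds to roughly a 13% per-code risk.
#' @param slope Log-odds increase per SD of latent crowding.
#' @return A list of class `ed_ae_link`.
#' @export
ae_link <- function(intercept = qlogis(0.13), slope = 0.8) {
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(list(intercept = intercept, slope = slope), class = "ed_ae_link")
}

#' Simulation configuration
#'
#' Generative parameters for seeded sequences of two-hour ED period
#' snapshots with shift-dependent structure: census per CTAS level is
#' negative-binomial (integer, overdispersed), staffing is the per-shift
#' median with small symmetric jitter, boarders/referrals arise by thinning
#' the census, code activations are Poisson with shift-dependent rates, the
#' Likert rating follows [perception_link()] and adverse events follow
#' [ae_link()].  Defaults reproduce the per-shift medians of a winter
#' single-centre study (physicians 5/4/3 and nurses 6/6/5 across
#' morning/evening/night, on-board census about 11/11/6, mean code
#' activations 0.95/0.55/0.20 per period) with about 5% of periods rated
#' Likert 5–6.
#'
#' @param n_periods Number of two-hour periods (12 per day; default 459).
#' @param seed Integer seed; every draw in [simulate_study()] derives from
#'   it.
#' @param physicians,nurses Named per-shift medians of staff on duty.
#' @param staffing_jitter Probability of one-unit deviation to each side of
#'   the staffing median.
#' @param census_means 3x5 matrix (shifts x CTAS levels) of mean on-board
#'   counts.
#' @param census_size Negative-binomial `size` (inverse overdispersion) for
#'   the census draws; larger is closer to Poisson.
#' @param p_boarding,p_referral Per-patient thinning probabilities for
#'   admitted boarders and referral-planned patients.
#' @param waiting_rate Poisson mean of the waiting-room count (the study
#'   site has no waiting room; the median is 0).
#' @param code_rate Named per-shift mean total code activations per period.
#' @param code_mix Mixture over code types (normalised internally).
#' @param ihca_rate Named per-shift mean in-hospital cardiac arrests per
#'   period (independent of code activations).
#' @param treatment_bays,licensed_beds Site size parameters; `bays` is
#'   written into every snapshot, `licensed_beds` standardizes EDOR in the
#'   latent index.
#' @param perception An [perception_link()] object.
#' @param ae An [ae_link()] object.
#' @return A list of class `ed_sim_config`.
#' @export
sim_config <- function(n_periods = 459L,
                       seed = 1L,
                       physicians = c(morning = 5, evening = 4, night = 3),
                       nurses = c(morning = 6, evening = 6, night = 5),
                       staffing_jitter = 0.2,
                       census_means = rbind(
                         morning = c(1.2, 3.0, 5.0, 2.0, 0.4),
                         evening = c(1.2, 3.0, 4.5, 2.2, 0.4),
                         night   = c(0.8, 1.4, 3.0, 1.2, 0.2)
                       ),
                       census_size = 8,
                       p_boarding = 0.12,
                       p_referral = 0.015,
                       waiting_rate = 0.05,
                       code_rate = c(morning = 0.95, evening = 0.55,
                                     night = 0.20),
                       code_mix = c(stroke = 0.55, stemi = 0.12,
                                    sepsis = 0.25, tbi = 0.08),
                       ihca_rate = c(morning = 0.02, evening = 0.05,
                                     night = 0.02),
                       treatment_bays = 16L,
                       licensed_beds = 15L,
                       perception = perception_link(),
                       ae = ae_link()) {
  if (n_periods < 1) stop("n_periods must be >= 1", call. = FALSE)
  for (nm in c("physicians", "nurses", "code_rate", "ihca_rate")) {
    v <- get(nm)
    if (!identical(names(v), .shift_levels)) {
      stop(nm, " must be named morning/evening/night", call. = FALSE)
    }
    if (any(v < 0)) stop(nm, " must be non-negative", call. = FALSE)
  }
  if (!is.matrix(census_means) || !identical(rownames(census_means),
                                             .shift_levels) ||
      ncol(census_means) != 5L || any(census_means < 0)) {
    stop("census_means must be a non-negative 3x5 matrix with rows ",
         "morning/evening/night", call. = FALSE)
  }
  if (p_boarding < 0 || p_boarding > 1 || p_referral < 0 || p_referral > 1) {
    stop("thinning probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (census_size <= 0 || waiting_rate < 0) {
    stop("census_size must be > 0 and waiting_rate >= 0", call. = FALSE)
  }
  if (any(code_mix < 0) || sum(code_mix) <= 0 ||
      !identical(names(code_mix), c("stroke", "stemi", "sepsis", "tbi"))) {
    stop("code_mix must be non-negative and named ",
         "stroke/stemi/sepsis/tbi", call. = FALSE)
  }
  stopifnot(inherits(perception, "ed_perception_link"),
            inherits(ae, "ed_ae_link"))
  structure(
    list(n_periods = as.integer(n_periods), seed = as.integer(seed),
         physicians = physicians, nurses = nurses,
         staffing_jitter = staffing_jitter,
         census_means = census_means, census_size = census_size,
         p_boarding = p_boarding, p_referral = p_referral,
         waiting_rate = waiting_rate,
         code_rate = code_rate, code_mix = code_mix / sum(code_mix),
         ihca_rate = ihca_rate,
         treatment_bays = as.integer(treatment_bays),
         licensed_beds = as.integer(licensed_beds),
         perception = perception, ae = ae),
    class = "ed_sim_config"
  )
}

# shift of a 0-based period index: 12 two-hour periods per day in blocks of
# four — morning, evening, night
shift_of_period <- function(period_index) {
  .shift_levels[(period_index %% 12L) %/% 4L + 1L]
}

# vectorised core: draws one snapshot per entry of `shifts`, using the
# current RNG state
draw_periods <- function(period_index, shifts, config) {
  n <- length(shifts)
  si <- match(shifts, .shift_levels)

  jit <- config$staffing_jitter
  jitter_draw <- function(n) {
    sample(c(-1L, 0L, 1L), n, replace = TRUE,
           prob = c(jit, 1 - 2 * jit, jit))
  }
  physicians <- pmax(1L, config$physicians[si] + jitter_draw(n))
  nurses <- pmax(1L, config$nurses[si] + jitter_draw(n))

  mu <- config$census_means[si, , drop = FALSE]
  ctas <- matrix(0L, n, 5L)
  for (j in 1:5) {
    ctas[, j] <- ifelse(mu[, j] > 0,
                        rnbinom(n, size = config$census_size, mu = mu[, j]),
                        0L)
  }
  census <- rowSums(ctas)

  boarding <- rbinom(n, census, config$p_boarding)
  referrals <- rbinom(n, census - boarding, config$p_referral)
  waiting <- rpois(n, config$waiting_rate)

  # latent crowding index and Likert rating
  z <- latent_crowding(ctas, physicians, nurses, waiting, boarding,
                       referrals, config)
  zn <- z + rnorm(n, 0, config$perception$noise_sd)
  likert <- findInterval(zn, config$perception$cutpoints) + 1L
  likert[census == 0L] <- 1L

  codes <- matrix(0L, n, 4L)
  aes <- matrix(0L, n, 4L)
  p_ae <- plogis(config$ae$intercept + config$ae$slope * z)
  for (k in 1:4) {
    codes[, k] <- rpois(n, config$code_rate[si] * config$code_mix[k])
    aes[, k] <- rbinom(n, codes[, k], p_ae)
  }
  ihca <- rpois(n, config$ihca_rate[si])

  out <- data.frame(
    period_index = period_index, shift = shifts,
    ctas1 = ctas[, 1], ctas2 = ctas[, 2], ctas3 = ctas[, 3],
    ctas4 = ctas[, 4], ctas5 = ctas[, 5],
    physicians = as.integer(physicians), nurses = as.integer(nurses),
    bays = rep(config$treatment_bays, n),
    waiting = waiting, boarding = boarding, referrals = referrals,
    likert = likert,
    code_stroke = codes[, 1], code_stemi = codes[, 2],
    code_sepsis = codes[, 3], code_tbi = codes[, 4],
    ae_stroke = aes[, 1], ae_stemi = aes[, 2],
    ae_sepsis = aes[, 3], ae_tbi = aes[, 4],
    ae_ihca = ihca,
    stringsAsFactors = FALSE
  )
  out
}

# weighted blend of standardized crowding scores; undefined EDWIN values in
# a blend fall back to the per-score reference mean (z contribution 0)
latent_crowding <- function(ctas, physicians, nurses, waiting, boarding,
                            referrals, config) {
  pl <- config$perception
  wts <- pl$index_weights[pl$index_weights > 0]
  load <- as.vector(ctas %*% triage_weights())
  census <- rowSums(ctas)
  vals <- list(
    edor = edor(census, config$licensed_beds),
    edwin = edwin(load, physicians, config$treatment_bays, boarding),
    modified_edwin = edwin(load, physicians, config$treatment_bays,
                           boarding, referrals, include_referrals = TRUE),
    work_score = work_score(waiting, load, nurses, boarding,
                            config$treatment_bays)
  )
  z <- 0
  for (nm in names(wts)) {
    ref <- pl$reference[[nm]]
    zk <- (vals[[nm]] - ref[["mean"]]) / ref[["sd"]]
    zk[is.na(zk)] <- 0
    z <- z + wts[[nm]] * zk
  }
  z / sum(wts)
}

#' Simulate a single ED period
#'
#' Draws one period snapshot for the given shift using the current RNG
#' state (no seed is set; thread reproducibility through
#' [simulate_study()] or `withr::with_seed()`).
#'
#' @param shift One of `"morning"`, `"evening"`, `"night"`.
#' @param config An [sim_config()] object.
#' @param period_index Index recorded in the snapshot.
#' @return One-row data frame in the period schema.
#' @export
#' @examples
#' withr::with_seed(7, simulate_period("morning", sim_config()))
simulate_period <- function(shift, config = sim_config(),
                            period_index = 0L) {
  stopifnot(inherits(config, "ed_sim_config"))
  shift <- match.arg(shift, .shift_levels)
  draw_periods(as.integer(period_index), shift, config)
}

#' Simulate a full study of ED periods
#'
#' Generates `config$n_periods` consecutive two-hour snapshots cycling
#' through the 12-per-day shift pattern (four morning, four evening, four
#' night periods per day), fully reproducible from `config$seed`.  The
#' caller's RNG state is left untouched.
#'
#' @param config An [sim_config()] object.
#' @return Data frame of period snapshots in the CSV schema (see
#'   [read_periods()]), one row per period.
#' @export
#' @examples
#' p <- simulate_study(sim_config(n_periods = 24, seed = 1))
#' table(p$shift)
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "ed_sim_config"))
  idx <- seq_len(config$n_periods) - 1L
  shifts <- shift_of_period(idx)
  out <- withr::with_seed(config$seed, draw_periods(idx, shifts, config))
  validate_periods(out, level = "full")
}
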