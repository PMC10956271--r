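test_that("triage weights reverse the CTAS scale", {
  expect_equal(triage_weight("I"), 5)
  expect_equal(triage_weight("V"), 1)
  expect_equal(triage_weight("III"), 3)
  expect_equal(triage_weight(1:5), 5:1)
  expect_equal(unname(triage_weights()), 5:1)
  expect_error(triage_weight("VI"), "unknown CTAS level")
  expect_error(triage_weight(0), "1\\.\\.5")
  bad <- stats::setNames(c(5, 4, 4, 2, 1), c("I", "II", "III", "IV", "V"))
  expect_error(triage_weight("I", weights = bad), "strictly decreasing")
})

test_that("acuity load sums count times weight", {
  expect_equal(acuity_load(c(0, 0, 0, 0, 0)), 0)
  expect_equal(acuity_load(c(1, 2, 4, 1, 0)), 27)
  expect_equal(acuity_load(c(0, 0, 0, 0, 10)), 10)
  df <- data.frame(ctas1 = c(1, 0), ctas2 = c(2, 0), ctas3 = c(4, 0),
                   ctas4 = c(1, 0), ctas5 = c(0, 10))
  expect_equal(acuity_load(df), c(27, 10))
  expect_error(acuity_load(c(1, -1, 0, 0, 0)), "non-negative integers")
})

test_that("EDWIN matches hand arithmetic and handles full boarding", {
  expect_equal(edwin(0, physicians = 4, bays = 16, boarding = 0), 0)
  expect_equal(edwin(27, 4, 16, boarding = 1), 0.45)
  m <- edwin(27, 4, 16, boarding = 1, referrals = 1,
             include_referrals = TRUE)
  expect_equal(m, 27 / (4 * 14))
  expect_gt(m, edwin(27, 4, 16, boarding = 1))
  expect_true(is.na(edwin(27, 4, 16, boarding = 16)))
  expect_true(is.na(edwin(27, 4, 16, boarding = 17)))
  expect_error(edwin(27, physicians = 0, bays = 16, boarding = 0), ">= 1")
})

test_that("EDOR is census over licensed beds, unbounded above, linear", {
  expect_equal(edor(15, 15), 1)
  expect_equal(edor(0, 15), 0)
  expect_equal(edor(6, 15), 0.4)
  expect_equal(edor(45, 15), 3)  # census may exceed licensed beds
  expect_error(edor(5, licensed_beds = 0), ">= 1")
  for (k in c(1, 3, 7, 11)) {
    expect_equal(edor(2 * k, 15), 2 * edor(k, 15))
  }
})

test_that("Work Score is the sum of its three published terms", {
  expect_equal(work_score(0, 0, nurses = 6, boarding = 0, bays = 16), 0)
  expect_equal(work_score(0, 27, nurses = 6, boarding = 1, bays = 16),
               0.097 * 27 / 6 + 10.92 / 16)
  # coefficient isolation
  expect_equal(work_score(16, 0, 6, 0, bays = 16), 3.23)
  expect_equal(work_score(0, 6, 6, 0, bays = 16), 0.097)
  expect_equal(work_score(0, 0, 6, 16, bays = 16), 10.92)
  # additivity of the isolated terms
  joint <- work_score(5, 30, 6, 2, 16)
  parts <- work_score(5, 0, 6, 0, 16) + work_score(0, 30, 6, 0, 16) +
    work_score(0, 0, 6, 2, 16)
  expect_equal(joint, parts)
  expect_error(work_score(0, 10, nurses = 0, boarding = 0, bays = 16),
               ">= 1")
})

test_that("EDWIN equals the literal formula over exhaustive census vectors", {
  grid <- as.matrix(expand.grid(0:5, 0:5, 0:5, 0:5, 0:5))
  sample_idx <- withr::with_seed(11, sample(nrow(grid), 250))
  loads <- acuity_load(grid[sample_idx, , drop = FALSE])
  got <- edwin(loads, physicians = 4, bays = 16, boarding = 3)
  want <- apply(grid[sample_idx, , drop = FALSE], 1,
                edwin_oracle, n_attending = 4, bays = 16, boarding = 3)
  expect_equal(got, want)
})

test_that("adding a patient at any CTAS level never decreases a score", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      counts <- rpois(5, 2)
      phys <- sample(1:6, 1)
      nurses <- sample(3:8, 1)
      boarding <- sample(0:5, 1)
      waiting <- rpois(1, 1)
      base_load <- acuity_load(counts)
      for (lvl in 1:5) {
        bumped <- counts
        bumped[lvl] <- bumped[lvl] + 1
        bumped_load <- acuity_load(bumped)
        expect_gte(edor(sum(bumped), 15), edor(sum(counts), 15))
        e0 <- edwin(base_load, phys, 16, boarding)
        e1 <- edwin(bumped_load, phys, 16, boarding)
        if (!is.na(e0) && !is.na(e1)) expect_gte(e1, e0)
        expect_gte(work_score(waiting, bumped_load, nurses, boarding, 16),
                   work_score(waiting, base_load, nurses, boarding, 16))
      }
    }
  })
})

test_that("score_all preserves order, carries NA EDWIN, rejects empty input", {
  p <- toy_period_row()
  s <- expect_silent(score_all(p))
  expect_equal(nrow(s), 1L)
  expect_false(anyNA(unlist(s)))
  expect_equal(s$edwin, 27 / (4 * 15))

  pf <- toy_period_row(ctas = c(4, 6, 4, 2, 0), boarding = 16)
  expect_message(sf <- score_all(pf), "undefined EDWIN")
  expect_true(is.na(sf$edwin))
  expect_true(is.na(sf$modified_edwin))
  expect_false(is.na(sf$edor))
  expect_false(is.na(sf$work_score))
  expect_equal(attr(sf, "n_undefined_edwin"), 1L)

  expect_error(score_all(toy_period_row()[0, ]), "empty")

  sim <- simulate_study(sim_config(n_periods = 459, seed = 5))
  ssim <- suppressMessages(score_all(sim))
  expect_equal(nrow(ssim), 459L)
  expect_equal(ssim$period_index, sim$period_index)
})

test_that("modified EDWIN dominates EDWIN whenever both are defined", {
  p <- simulate_study(sim_config(n_periods = 200, seed = 9,
                                 p_referral = 0.2))
  s <- suppressMessages(score_all(p))
  both <- !is.na(s$edwin) & !is.na(s$modified_edwin)
  expect_gt(sum(both), 100)
  expect_true(all(s$modified_edwin[both] >= s$edwin[both]))
})

test_that("EDOR and EDWIN denominators are independent configuration", {
  p <- toy_period_row()
  s10 <- score_all(p, score_config(licensed_beds_edor = 10))
  expect_equal(s10$edor, 8 / 10)
  expect_equal(s10$edwin, 27 / (4 * 15))  # bays column still 16
  p2 <- p[, setdiff(names(p), "bays")]
  s2 <- score_all(p2, score_config(treatment_bays = 20))
  expect_equal(s2$edwin, 27 / (4 * 19))
})
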