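test_that("Spearman rho matches the midrank oracle and handles edge cases", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(1:4, c(4, 3, 2, 1))$rho, -1)
  expect_equal(spearman_rho(1:4, c(4, 3, 2, 1))$p_value, 0)
  withr::with_seed(41, {
    for (i in 1:20) {
      x <- sample(1:5, 8, replace = TRUE)  # ties on purpose
      y <- sample(1:5, 8, replace = TRUE)
      if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
      expect_equal(spearman_rho(x, y)$rho, spearman_oracle(x, y))
    }
  })
  expect_warning(out <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(out$rho) && out$constant)
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  # NA pairs removed before ranking
  expect_equal(spearman_rho(c(1, 2, NA, 3), c(2, 4, 9, 6))$n, 3L)
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  withr::with_seed(43, {
    x <- rnorm(30)
    y <- x + rnorm(30)
    r0 <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y)$rho, r0)
    expect_equal(spearman_rho(x, y^3 + 5 * y)$rho, r0)
    expect_equal(spearman_rho(-x, y)$rho, -r0)
  })
})

test_that("exhaustive permutation p-value is exact for small samples", {
  # perfectly monotone 4-vector: only identity and reversal reach |rho|=1
  out <- spearman_rho(1:4, c(10, 20, 30, 40), p_method = "permutation")
  expect_equal(out$p_value, 2 / factorial(4))
})

test_that("AUC equals exhaustive pair counting and the perfect/null limits", {
  r <- roc_auc(1:6, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$auc_ci, c(1, 1))
  withr::with_seed(47, {
    for (i in 1:40) {
      n <- sample(5:12, 1)
      scores <- sample(1:4, n, replace = TRUE)  # heavy ties
      labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
      expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels))
    }
    null_scores <- rnorm(4000)
    null_labels <- rep(c(TRUE, FALSE), 2000)
    expect_lt(abs(roc_auc(null_scores, null_labels)$auc - 0.5), 0.03)
  })
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC and DeLong interval agree with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(53, {
    scores <- c(rnorm(60, 1), rnorm(80))
    labels <- rep(c(TRUE, FALSE), c(60, 80))
  })
  mine <- roc_auc(scores, labels, ci_method = "delong")
  ref <- pROC::roc(response = labels, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$auc_ci, ci[c(1, 3)], tolerance = 1e-8)
})

test_that("ROC sensitivity is non-increasing and the CI brackets the AUC", {
  withr::with_seed(59, {
    scores <- round(rnorm(200), 1)
    labels <- rbinom(200, 1, plogis(scores)) == 1
  })
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$sensitivity) <= 0))
  expect_true(all(diff(r$specificity) >= 0))
  expect_gte(r$auc, r$auc_ci[1])
  expect_lte(r$auc, r$auc_ci[2])
})

test_that("the Youden cutoff matches a brute-force sweep", {
  withr::with_seed(61, {
    for (i in 1:15) {
      scores <- round(rnorm(10), 1)
      labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 8, TRUE))
      r <- roc_auc(scores, labels)
      bc <- best_cutoff(r)
      j_all <- vapply(r$thresholds, function(t) {
        mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1
      }, numeric(1))
      expect_equal(bc$youden_j, max(j_all))
      # tie-break toward the lower threshold
      expect_equal(bc$threshold,
                   min(r$thresholds[j_all == max(j_all)]))
      if (r$auc >= 0.5) expect_gte(bc$youden_j, 0)
    }
  })
  r1 <- suppressWarnings(roc_auc(rep(2, 6), rep(c(TRUE, FALSE), 3)))
  expect_warning(bc <- best_cutoff(r1), "degenerate")
  expect_equal(bc$youden_j, 0)
})

test_that("diagnostics reproduce the published worked-example row", {
  d <- diagnostics(confusion_matrix(tp = 13, fp = 99, fn = 19, tn = 328))
  expect_equal(round(100 * d$sensitivity$estimate, 1), 40.6)
  expect_equal(round(100 * d$specificity$estimate, 1), 76.8)
  expect_equal(round(100 * d$ppv$estimate, 1), 11.6)
  expect_equal(round(100 * d$npv$estimate, 1), 94.5)
  d2 <- diagnostics(confusion_matrix(5, 0, 0, 5))
  expect_equal(d2$sensitivity$estimate, 1)
  expect_equal(d2$npv$estimate, 1)
  # zero denominator: metric NA, others intact
  d3 <- diagnostics(confusion_matrix(0, 0, 3, 7))
  expect_true(is.na(d3$ppv$estimate))
  expect_equal(d3$npv$estimate, 0.7)
})

test_that("Clopper-Pearson matches binomial-tail inversion", {
  cases <- rbind(c(13, 32), c(0, 20), c(20, 20), c(1, 459), c(112, 459))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, 1]
    n <- cases[i, 2]
    expect_equal(unname(clopper_pearson(x, n)), cp_oracle(x, n),
                 tolerance = 1e-8)
  }
  expect_equal(unname(clopper_pearson(13, 32)),
               as.numeric(binom.test(13, 32)$conf.int))
})

test_that("each diagnostic point estimate lies inside its interval", {
  withr::with_seed(67, {
    for (i in 1:10) {
      cm <- confusion_matrix(sample(1:50, 1), sample(1:50, 1),
                             sample(1:50, 1), sample(1:50, 1))
      d <- diagnostics(cm)
      for (m in d[c("sensitivity", "specificity", "ppv", "npv")]) {
        expect_gte(m$estimate, m$lower)
        expect_lte(m$estimate, m$upper)
      }
    }
  })
})

test_that("chi-square on 2x2 follows the closed-form identity", {
  expect_equal(chi_square_2x2(confusion_matrix(10, 0, 0, 10))$statistic, 20)
  prop <- chi_square_2x2(confusion_matrix(10, 20, 5, 10))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  withr::with_seed(71, {
    for (i in 1:20) {
      cm <- confusion_matrix(sample(1:40, 1), sample(1:40, 1),
                             sample(1:40, 1), sample(1:40, 1))
      expect_equal(chi_square_2x2(cm)$statistic,
                   chisq_identity(cm$tp, cm$fn, cm$fp, cm$tn))
    }
  })
  expect_warning(out <- chi_square_2x2(confusion_matrix(0, 0, 5, 5)),
                 "zero marginal")
  expect_true(is.na(out$statistic))
  # the Yates correction shrinks the statistic
  cm <- confusion_matrix(12, 5, 4, 14)
  expect_lt(chi_square_2x2(cm, correct = TRUE)$statistic,
            chi_square_2x2(cm)$statistic)
})

test_that("Fleiss' kappa matches its formula transcription", {
  all_agree <- rbind(c(3, 0), c(0, 3), c(3, 0), c(0, 3))
  expect_equal(fleiss_kappa(all_agree)$kappa, 1)
  toy <- rbind(c(2, 1, 0), c(0, 3, 0), c(1, 1, 1), c(0, 0, 3))
  out <- fleiss_kappa(toy)
  expect_equal(out$kappa, fleiss_oracle(toy))
  expect_gte(out$kappa, out$ci[1])
  expect_lte(out$kappa, out$ci[2])
  # chance-level ratings over 2 categories: kappa near 0
  withr::with_seed(73, {
    counts <- rbinom(400, 4, 0.5)
    chance <- cbind(counts, 4 - counts)
  })
  expect_lt(abs(fleiss_kappa(chance)$kappa), 0.08)
  expect_error(fleiss_kappa(rbind(c(1, 0), c(0, 1))), "at least 2 raters")
  expect_error(fleiss_kappa(rbind(c(2, 0), c(0, 3))), "same number")
})

test_that("group comparisons dispatch to rank, t and ANOVA correctly", {
  same <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$method, "wilcoxon")
  expect_equal(same$p_value, 1)
  far <- compare_groups(c(1, 2, 3, 101, 102, 103),
                        rep(c("a", "b"), each = 3))
  expect_lt(far$p_value, 0.05)
  expect_true(far$statistic %in% c(0, 9))  # rank-sum at its extreme
  tt <- compare_groups(c(1, 2, 3, 8, 9, 10), rep(c("a", "b"), each = 3),
                       method = "t")
  expect_equal(tt$method, "t")
  vals <- c(1, 2, 3, 4, 8, 9, 10, 2, 3, 4)
  grp <- rep(c("a", "b", "c"), c(4, 3, 3))
  out <- compare_groups(vals, grp)
  expect_equal(out$method, "anova")
  expect_equal(out$statistic, anova_oracle(vals, grp))
  expect_error(compare_groups(1:4, c("a", "b", "c", "c")),
               "2 values per group")
  expect_error(compare_groups(1:3, rep("a", 3)), "at least 2")
})

test_that("confusion matrices reconstruct exactly from summary figures", {
  withr::with_seed(79, {
    for (i in 1:10) {
      cm <- confusion_matrix(sample(5:60, 1), sample(5:60, 1),
                             sample(5:60, 1), sample(5:60, 1))
      total <- cm$tp + cm$fp + cm$fn + cm$tn
      d <- diagnostics(cm)
      back <- confusion_from_summary(
        round(100 * d$sensitivity$estimate, 4),
        round(100 * d$specificity$estimate, 4),
        flagged = cm$tp + cm$fp, total = total, digits = 4)
      expect_equal(unclass(back), unclass(cm))
    }
  })
})

test_that("evaluate_study assembles the full report", {
  p <- simulate_study(sim_config(n_periods = 459, seed = 1))
  r <- evaluate_study(p)
  expect_s3_class(r, "ed_report")
  expect_equal(r$n_periods, 459L)
  expect_equal(nrow(r$correlations), 4L)
  expect_equal(nrow(r$table3), 4L)
  expect_setequal(names(r$rocs),
                  c("edor", "edwin", "modified_edwin", "work_score"))
  # perception is driven by standardized EDOR, so EDOR must top the rhos
  best <- r$correlations$score[which.max(r$correlations$rho)]
  expect_equal(best, "edor")
  expect_output(print(r), "459 periods")
})

test_that("a degenerate reference standard yields a partial report", {
  p <- simulate_study(sim_config(n_periods = 48, seed = 4))
  p$likert <- pmin(p$likert, 4L)  # nobody rates the ED overcrowded
  r <- evaluate_study(p)
  expect_null(r$table3)
  expect_length(r$rocs, 0L)
  expect_match(r$notes, "degenerate")
  expect_equal(nrow(r$correlations), 4L)  # correlations still reported
})
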