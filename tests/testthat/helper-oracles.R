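# Independent brute-force oracles used across the suite.  Each transcribes
# the defining formula directly (loops, no shared code with R/).

# literal EDWIN quotient: sum of count x reversed weight over physicians
# times free bays
edwin_oracle <- function(counts, n_attending, bays, boarding) {
  num <- 0
  for (i in 1:5) num <- num + counts[i] * (6 - i)
  if (bays - boarding <= 0) return(NA_real_)
  num / (n_attending * (bays - boarding))
}

# AUC as exhaustive concordant-pair counting (ties count one half)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (a in pos) {
    for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# explicit midranks, then the Pearson product-moment formula
midranks <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1))
}

spearman_oracle <- function(x, y) {
  rx <- midranks(x)
  ry <- midranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# chi-square on a 2x2 via the closed-form identity
chisq_identity <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Clopper-Pearson bounds by direct inversion of the binomial tails
cp_oracle <- function(x, n, alpha = 0.05) {
  lower <- if (x == 0) 0 else {
    uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (x == n) 1 else {
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower, upper)
}

# Fleiss' kappa by literal transcription of the agreement formulas
fleiss_oracle <- function(m) {
  n <- unique(rowSums(m))
  N <- nrow(m)
  p_j <- colSums(m) / (N * n)
  P_i <- (rowSums(m^2) - n) / (n * (n - 1))
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# one-way ANOVA F as the between/within mean-square ratio
anova_oracle <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g)
  n <- length(values)
  grand <- mean(values)
  ss_between <- sum(vapply(g, function(v) {
    length(v) * (mean(v) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# a small fully valid period table used by several suites
toy_period_row <- function(ctas = c(1, 2, 4, 1, 0), physicians = 4,
                           nurses = 6, bays = 16, waiting = 0,
                           boarding = 1, referrals = 0, likert = 3,
                           shift = "morning") {
  data.frame(period_index = 0L, shift = shift,
             ctas1 = ctas[1], ctas2 = ctas[2], ctas3 = ctas[3],
             ctas4 = ctas[4], ctas5 = ctas[5],
             physicians = physicians, nurses = nurses, bays = bays,
             waiting = waiting, boarding = boarding, referrals = referrals,
             likert = likert,
             code_stroke = 0L, code_stemi = 0L, code_sepsis = 0L,
             code_tbi = 0L, ae_stroke = 0L, ae_stemi = 0L,
             ae_sepsis = 0L, ae_tbi = 0L, ae_ihca = 0L,
             stringsAsFactors = FALSE)
}
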