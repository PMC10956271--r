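#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected Spearman rho (Pearson correlation of midranks) with a
#' p-value from the t-distribution approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.  For small
#' samples a permutation p-value is available: exact enumeration up to
#' `n = 7`, otherwise Monte Carlo (which consumes RNG state).
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs are removed
#'   before ranking.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo resamples when permutation is not exhaustive.
#' @return List with `rho`, `p_value`, `n` (pairs used) and `constant`
#'   (`TRUE` when either argument was constant, in which case `rho` is
#'   `NA`).
#' @export
#' @examples
#' spearman_rho(1:4, c(4, 3, 2, 1))$rho  # -1
spearman_rho <- function(x, y, p_method = c("t", "permutation"),
                         n_perm = 10000L) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input: Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                constant = TRUE))
  }
  rho <- cor(x, y, method = "spearman")
  p <- if (p_method == "t") {
    if (abs(rho) >= 1) {
      0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tt), df = n - 2)
    }
  } else {
    perm_p_spearman(x, y, rho, n_perm)
  }
  list(rho = rho, p_value = p, n = n, constant = FALSE)
}

perm_p_spearman <- function(x, y, rho_obs, n_perm) {
  n <- length(x)
  rho_of <- function(perm) cor(x, y[perm], method = "spearman")
  if (n <= 7L) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1L, rho_of)
    mean(abs(stats) >= abs(rho_obs) - 1e-12)
  } else {
    stats <- replicate(n_perm, rho_of(sample.int(n)))
    (sum(abs(stats) >= abs(rho_obs) - 1e-12) + 1) / (n_perm + 1)
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement among a fixed number of raters assigning
#' subjects to nominal categories, with the large-sample standard error of
#' Fleiss (as used for the overall kappa in standard inter-rater software)
#' and the corresponding normal-approximation confidence interval.
#'
#' @param ratings Integer matrix, one row per subject and one column per
#'   category; cell `(i, j)` is the number of raters assigning subject `i`
#'   to category `j`.  Row sums (raters per subject) must be constant and
#'   `>= 2`.
#' @param conf_level Confidence level.
#' @return List with `kappa`, `se`, `ci` (`c(lower, upper)`), `z`,
#'   `p_value`, `n_subjects`, `n_raters`.
#' @export
#' @examples
#' m <- rbind(c(3, 0), c(0, 3), c(3, 0), c(2, 1))
#' fleiss_kappa(m)$kappa
fleiss_kappa <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m) || any(m < 0) || any(m %% 1 != 0)) {
    stop("ratings must be non-negative integer counts", call. = FALSE)
  }
  n_raters <- unique(rowSums(m))
  if (length(n_raters) != 1L) {
    stop("every subject must be rated by the same number of raters",
         call. = FALSE)
  }
  if (n_raters < 2L) stop("need at least 2 raters", call. = FALSE)
  n_sub <- nrow(m)
  p_j <- colSums(m) / (n_sub * n_raters)
  p_i <- (rowSums(m^2) - n_raters) / (n_raters * (n_raters - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (p_e == 1) {  # all mass in one category: agreement trivially perfect
    return(list(kappa = 1, se = 0, ci = c(1, 1), z = Inf, p_value = 0,
                n_subjects = n_sub, n_raters = n_raters))
  }
  kappa <- (p_bar - p_e) / (1 - p_e)
  se <- sqrt(2 / (n_sub * n_raters * (n_raters - 1))) *
    sqrt(p_e - (2 * n_raters - 3) * p_e^2 +
           2 * (n_raters - 2) * sum(p_j^3)) / (1 - p_e)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- if (se > 0) kappa / se else Inf
  list(kappa = kappa, se = se,
       ci = c(kappa - zq * se, kappa + zq * se),
       z = z, p_value = 2 * pnorm(-abs(z)),
       n_subjects = n_sub, n_raters = n_raters)
}

#' Compare a continuous variable across groups
#'
#' Two groups are compared with the Wilcoxon rank-sum test (normal
#' approximation with tie correction; the default, for skewed count-like
#' data) or an independent-samples Welch t-test when `method = "t"`.
#' More than two groups are compared with a classic
#' one-way ANOVA F-test (equal-variance).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length as `values`.
#' @param method `"auto"` (rank test for 2 groups, ANOVA for more),
#'   `"rank"` or `"t"` for the two-group case.
#' @return List with `statistic`, `p_value`, `method`, `n_groups`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3))
compare_groups <- function(values, groups, method = c("auto", "rank", "t")) {
  method <- match.arg(method)
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  g <- factor(groups[keep])
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  if (k == 2L) {
    if (method == "t") {
      ht <- t.test(values ~ g)
      return(list(statistic = unname(ht$statistic),
                  p_value = ht$p.value, method = "t", n_groups = 2L))
    }
    ht <- suppressWarnings(
      wilcox.test(values ~ g, exact = FALSE, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "wilcoxon", n_groups = 2L)
  } else {
    if (any(table(g) < 2L)) {
      stop("one-way ANOVA needs at least 2 values per group",
           call. = FALSE)
    }
    ht <- oneway.test(values ~ g, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "anova", n_groups = k)
  }
}
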