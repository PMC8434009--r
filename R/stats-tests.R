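# StatResult constructor shared by all tests.
new_stat_result <- function(method, statistic, p_value, n, exact = NA,
                            estimate = NULL, note = NULL) {
  structure(list(
    method = method,
    statistic = unname(statistic),
    p_value = unname(p_value),
    n = n,
    exact = exact,
    estimate = estimate,
    note = note,
    alpha = 0.05
  ), class = "bci_stat")
}

#' Mean and standard deviation for reporting
#'
#' Arithmetic mean and standard deviation with divisor n (population
#' convention — the convention under which the published per-subject tables'
#' printed SD rows are recovered from their own columns), both rounded to 2
#' decimals half away from zero.
#'
#' @param values Numeric vector, length >= 1.
#' @return List with `mean`, `sd`, `n`.
#' @export
describe <- function(values) {
  if (length(values) < 1) stop("describe() needs at least one value", call. = FALSE)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  list(mean = round_half_up(m, 2), sd = round_half_up(s, 2), n = length(values))
}

# Exact null distribution of the signed-rank statistic W+ for given
# (midrank-tied) ranks: probability mass over 2*W+ = 0..sum(2r), by
# generating-function convolution over sign assignments.
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  pm <- numeric(total + 1)
  pm[1] <- 1
  for (s in ranks2) {
    shifted <- c(rep(0, s), pm[seq_len(total + 1 - s)])
    pm <- (pm + shifted) / 2
  }
  pm  # index i is P(2*W+ = i - 1)
}

two_sided_p <- function(pm, stat2) {
  # pm over 0..length-1 on the doubled scale; two-sided doubling rule
  idx <- stat2 + 1
  p_le <- sum(pm[seq_len(min(idx, length(pm)))])
  p_ge <- sum(pm[seq(min(idx, length(pm)), length(pm))])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped;
#' absolute differences are midranked under ties. For 25 or fewer usable
#' pairs the p-value is exact, computed from the full null distribution of
#' the positive-rank sum over all sign assignments (ties handled by
#' convolving the doubled midranks); for larger n a normal approximation
#' with tie-corrected variance is used (no continuity correction). This
#' differs from [stats::wilcox.test()], which cannot compute exact p-values
#' in the presence of ties or zeros.
#'
#' @param x,y Paired numeric vectors, or differences in `x` with `y = NULL`.
#' @return A `bci_stat` with the positive-rank-sum statistic `W`, `p_value`,
#'   usable pair count `n`, and whether the p-value is exact.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; test is degenerate", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    pm <- signed_rank_null(as.integer(round(2 * r)))
    p <- two_sided_p(pm, as.integer(round(2 * W)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  new_stat_result("wilcoxon_signed_rank", W, p, n, exact,
                  note = if (n_zero > 0) sprintf("%d zero difference(s) dropped", n_zero))
}

# Exact null distribution of the rank sum of group A (size na) drawn from the
# combined doubled midranks: counts of subsets of size na by doubled rank sum.
rank_sum_null <- function(ranks2, na) {
  total <- sum(ranks2)
  f <- matrix(0, nrow = na + 1, ncol = total + 1)
  f[1, 1] <- 1
  for (s in ranks2) {
    for (k in rev(seq_len(na))) {
      row <- f[k, ]
      shifted <- c(rep(0, s), row[seq_len(total + 1 - s)])
      f[k + 1, ] <- f[k + 1, ] + shifted
    }
  }
  f[na + 1, ] / choose(length(ranks2), na)  # index i: P(2*W_A = i - 1)
}

#' Wilcoxon rank-sum test for two independent samples
#'
#' Two-sided test on the rank sum of the first group, with midranks under
#' ties. For a combined sample size of 20 or fewer the p-value is exact
#' (full distribution of the group-A rank sum over all group labelings,
#' ties included); otherwise a normal approximation with tie-corrected
#' variance is used (no continuity correction).
#'
#' @param a,b Numeric samples.
#' @return A `bci_stat` with the group-`a` rank-sum statistic `W`, `p_value`,
#'   `n = c(length(a), length(b))`, and whether the p-value is exact.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both groups must be nonempty", call. = FALSE)
  N <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  if (N <= 20) {
    pm <- rank_sum_null(as.integer(round(2 * r)), na)
    p <- two_sided_p(pm, as.integer(round(2 * W)))
    exact <- TRUE
  } else {
    mu <- na * (N + 1) / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  new_stat_result("wilcoxon_rank_sum", W, p, c(na, nb), exact)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of `values` against a normal distribution with the
#' sample's own mean and (sample) standard deviation, with the asymptotic
#' KS p-value. Used as the screen that motivates the nonparametric pairwise
#' tests.
#'
#' @param values Numeric vector, n >= 3, non-degenerate.
#' @return A `bci_stat` with the KS sup-distance statistic and p-value.
#' @export
ks_normality <- function(values) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance; KS normality test is degenerate", call. = FALSE)
  res <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s, exact = FALSE)
  )
  new_stat_result("ks", res$statistic, res$p.value, length(values), FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (monotonicity enforced,
#' input order preserved). Thin wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A `bci_stat` with `estimate` r and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation is degenerate", call. = FALSE)
  }
  res <- stats::cor.test(x, y, method = "pearson")
  new_stat_result("pearson", res$statistic, res$p.value, length(x), NA,
                  estimate = unname(res$estimate))
}
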