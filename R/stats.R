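#' Exact and classical tests for recovery and sex-ratio comparisons
#'
#' All tests return a list of class `adna_test` with `statistic`,
#' `p_value`, `method` and `n`. The two exact tests use the "minlike"
#' two-sided convention — the p-value sums the probabilities of every
#' outcome no more likely than the observed one, with a `1 + 1e-7`
#' relative tolerance on the comparison to absorb floating-point noise.
#'
#' @name adna_tests
NULL

new_test_result <- function(statistic, p_value, method, n, extra = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(c(list(statistic = statistic, p_value = p_value,
                   method = method, n = n), extra),
            class = "adna_test")
}

#' @export
print.adna_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %s (n = %s)\n", x$method,
              format(x$statistic, digits = 4),
              format(x$p_value, digits = 4), x$n))
  invisible(x)
}

# relative tolerance of the minlike outcome comparison
.minlike_tol <- 1 + 1e-7

#' Two-tailed exact binomial test
#'
#' Exact test of `k` successes in `n` trials against success probability
#' `p0`, used to test observed male:female ratios against 1:1. The
#' two-sided p-value is computed by direct enumeration of all outcomes
#' `0..n`, summing those whose probability does not exceed that of the
#' observed outcome (minlike convention); for `p0 = 0.5` this equals the
#' doubled smaller tail, capped at 1.
#'
#' @param k Observed successes (`0 <= k <= n`).
#' @param n Trials (`>= 1`).
#' @param p0 Null success probability.
#' @return An `adna_test` with `statistic = k/n`.
#' @examples
#' binomial_two_tailed(4, 15)$p_value   # sex ratio 4:11 vs 1:1
#' @export
binomial_two_tailed <- function(k, n, p0 = 0.5) {
  if (!is.numeric(k) || !is.numeric(n) || n < 1 || k < 0 || k > n ||
      k != round(k) || n != round(n)) {
    stop("need integers 0 <= k <= n with n >= 1", call. = FALSE)
  }
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]", call. = FALSE)
  probs <- stats::dbinom(0:n, n, p0)
  p <- sum(probs[probs <= probs[k + 1] * .minlike_tol])
  new_test_result(statistic = k / n, p_value = min(1, p),
                  method = "two-tailed exact binomial", n = n,
                  extra = list(k = k, p0 = p0))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Enumerates every 2x2 table with the observed margins under the
#' hypergeometric null and sums the probabilities of those no more likely
#' than the observed table (minlike convention). Used to compare
#' male:female ratios between materials or periods. Degenerate margins (an
#' empty row or column) give `p = 1`.
#'
#' @param tab A 2x2 matrix of non-negative counts (rows = groups,
#'   columns = categories), e.g. from [contingency_table()].
#' @return An `adna_test`; `statistic` is the observed table probability.
#' @examples
#' fisher_two_sided(contingency_table(3, 5, 1, 6))$p_value  # ivory vs bone
#' @export
fisher_two_sided <- function(tab) {
  if (!is.matrix(tab) || !all(dim(tab) == 2) || any(tab < 0) ||
      any(tab != round(tab))) {
    stop("need a 2x2 matrix of non-negative integer counts", call. = FALSE)
  }
  if (sum(tab) == 0) stop("table must contain at least one count",
                          call. = FALSE)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) {
    # a zero margin fixes the table; only one outcome exists
    return(new_test_result(statistic = 1, p_value = 1,
                           method = "two-sided Fisher exact", n = N))
  }
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- probs[support == tab[1, 1]]
  p <- sum(probs[probs <= p_obs * .minlike_tol])
  new_test_result(statistic = p_obs, p_value = min(1, p),
                  method = "two-sided Fisher exact", n = N)
}

#' Build a 2x2 contingency table row-wise
#'
#' @param a,b First row (e.g. group 1 males, females).
#' @param c2,d Second row.
#' @return A 2x2 integer matrix.
#' @export
contingency_table <- function(a, b, c2, d) {
  tab <- matrix(as.integer(c(a, c2, b, d)), 2)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(tab) == 0) stop("table must contain at least one count",
                          call. = FALSE)
  tab
}

#' Shapiro-Wilk normality gate
#'
#' Normality check applied to paired differences before a paired t-test;
#' at small sample sizes it is the only practical gate. The gate is
#' advisory: downstream t-tests report it alongside their own result
#' rather than refusing to run.
#'
#' @param x Numeric vector of differences (`3 <= length(x) <= 50`, not
#'   constant).
#' @param alpha Gate level (default 0.05).
#' @return An `adna_test` with `statistic = W` and an extra `normal`
#'   logical (`p > alpha`).
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3 || length(x) > 50) {
    stop("Shapiro-Wilk requires 3 <= n <= 50", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("Shapiro-Wilk is undefined for a constant vector", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  new_test_result(statistic = unname(sw$statistic), p_value = sw$p.value,
                  method = "Shapiro-Wilk", n = length(x),
                  extra = list(normal = sw$p.value > alpha))
}

#' Paired t-test with advisory normality gate
#'
#' Classical paired t-test on `b - a` differences (dentin vs cementum
#' values of one metric, paired by specimen), two-sided. The Shapiro-Wilk
#' gate on the differences is attached when `n >= 3` but never blocks the
#' test.
#'
#' @param a,b Equal-length numeric vectors (`length >= 2`).
#' @param log_scale Test `log(b) - log(a)` instead of raw differences
#'   (requires positive values); raw is the default.
#' @return An `adna_test` with `statistic = t`, extra fields `df`,
#'   `mean_difference` and `shapiro` (an `adna_test` or `NULL`).
#' @export
paired_t <- function(a, b, log_scale = FALSE) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("need equal-length vectors with n >= 2", call. = FALSE)
  }
  if (log_scale) {
    if (any(a <= 0) || any(b <= 0)) {
      stop("log-scale comparison requires positive values", call. = FALSE)
    }
    a <- log(a); b <- log(b)
  }
  d <- b - a
  degenerate <- stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))
  sw <- if (length(d) >= 3 && !degenerate) shapiro_gate(d) else NULL
  if (degenerate) {
    return(new_test_result(statistic = NA_real_, p_value = NA_real_,
                           method = "paired t", n = length(d),
                           extra = list(df = length(d) - 1,
                                        mean_difference = mean(d),
                                        shapiro = sw)))
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  new_test_result(statistic = unname(tt$statistic), p_value = tt$p.value,
                  method = "paired t", n = length(d),
                  extra = list(df = unname(tt$parameter),
                               mean_difference = mean(d), shapiro = sw))
}

#' Fold difference between paired substrate metrics
#'
#' A single printed fold change can hide two estimators, so both are
#' reported: the mean of per-pair ratios `mean(b_i / a_i)` and the ratio
#' of group means `mean(b) / mean(a)`.
#'
#' @param a,b Equal-length numeric vectors; `a` (and `b` for
#'   mean-of-ratios) must be free of zeros.
#' @return Named numeric vector `c(mean_of_ratios, ratio_of_means)`;
#'   entries are `NA` when a denominator is zero.
#' @export
fold_difference <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  mor <- if (any(a == 0)) NA_real_ else mean(b / a)
  rom <- if (mean(a) == 0) NA_real_ else mean(b) / mean(a)
  c(mean_of_ratios = mor, ratio_of_means = rom)
}

#' Round half away from zero (report style)
#'
#' Printed p-values use conventional half-up rounding (0.125 -> 0.13),
#' not banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  trunc(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}
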