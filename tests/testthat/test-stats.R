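test_that("exact binomial p-values match published-style counts and closed forms", {
  expect_equal(round_half_up(binomial_two_tailed(4, 15)$p_value), 0.12)
  expect_equal(round_half_up(binomial_two_tailed(3, 8)$p_value), 0.73)
  expect_equal(round_half_up(binomial_two_tailed(1, 7)$p_value), 0.13)
  # closed form: both extreme tails of a fair coin
  expect_equal(binomial_two_tailed(0, 10)$p_value, 2 / 1024)
  # symmetric null: doubling the smaller tail
  expect_equal(binomial_two_tailed(4, 15)$p_value,
               2 * pbinom(4, 15, 0.5))
  expect_equal(binomial_two_tailed(7, 14)$p_value, 1)
  expect_error(binomial_two_tailed(5, 4), "k <= n")
  expect_error(binomial_two_tailed(-1, 4), "k <= n")
})

test_that("Fisher test reproduces printed group comparisons and closed forms", {
  expect_equal(round_half_up(
    fisher_two_sided(contingency_table(3, 5, 1, 6))$p_value), 0.57)
  expect_equal(fisher_two_sided(contingency_table(1, 3, 2, 2))$p_value, 1)
  # perfectly separated 5/5: only the two extreme tables are as unlikely
  expect_equal(fisher_two_sided(contingency_table(5, 0, 0, 5))$p_value,
               2 / choose(10, 5))
  # degenerate margins fix the table
  expect_equal(fisher_two_sided(contingency_table(0, 0, 3, 4))$p_value, 1)
  expect_error(fisher_two_sided(matrix(0, 2, 2)), "at least one")
})

test_that("exact tests agree with the independent enumeration oracle", {
  withr::with_seed(2024, {
    for (i in 1:300) {
      n <- sample(1:20, 1)
      k <- sample(0:n, 1)
      p0 <- sample(c(0.5, 0.3, 0.7), 1)
      expect_equal(binomial_two_tailed(k, n, p0)$p_value,
                   oracle_binom_p(k, n, p0), tolerance = 1e-12)
    }
    for (i in 1:300) {
      tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
      if (sum(tab) == 0) tab[1, 1] <- 1
      expect_equal(fisher_two_sided(tab)$p_value, oracle_fisher_p(tab),
                   tolerance = 1e-12)
    }
  })
})

test_that("exact tests agree with the stock R implementations", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(1:25, 1)
      k <- sample(0:n, 1)
      expect_equal(binomial_two_tailed(k, n)$p_value,
                   stats::binom.test(k, n)$p.value, tolerance = 1e-12)
      tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
      if (sum(tab) == 0) tab[2, 2] <- 3
      expect_equal(fisher_two_sided(tab)$p_value,
                   stats::fisher.test(tab)$p.value, tolerance = 1e-10)
    }
  })
})

test_that("Fisher p is invariant to row and column swaps", {
  withr::with_seed(11, {
    for (i in 1:25) {
      tab <- matrix(sample(0:9, 4, replace = TRUE), 2)
      if (sum(tab) == 0) tab[1, 2] <- 2
      p <- fisher_two_sided(tab)$p_value
      expect_equal(fisher_two_sided(tab[2:1, ])$p_value, p,
                   tolerance = 1e-12)
      expect_equal(fisher_two_sided(tab[, 2:1])$p_value, p,
                   tolerance = 1e-12)
    }
  })
})

test_that("Shapiro-Wilk gate flags heavy outliers and rejects degenerates", {
  sym <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  g <- shapiro_gate(sym)
  expect_gt(g$p_value, 0.05)
  expect_true(g$normal)
  expect_equal(g$p_value, stats::shapiro.test(sym)$p.value)

  out <- shapiro_gate(c(0, 0.01, -0.01, 0.02, 100))
  expect_lt(out$p_value, 0.05)
  expect_false(out$normal)

  expect_error(shapiro_gate(c(1, 1, 1, 1)), "constant")
  expect_error(shapiro_gate(c(1, 2)), "3 <= n")
})

test_that("paired t matches the analytic t distribution", {
  a <- c(3, 1, 4, 1)
  expect_equal(paired_t(a, a)$statistic, NA_real_)
  expect_true(is.na(paired_t(a, a)$p_value))  # zero-variance differences

  # differences (1,1,1,2): t = 1.25 / 0.25 = 5 on 3 df
  r <- paired_t(c(0, 0, 0, 0), c(1, 1, 1, 2))
  expect_equal(r$statistic, 5, tolerance = 1e-9)
  expect_equal(r$p_value, 2 * stats::pt(-5, 3), tolerance = 1e-6)
  expect_equal(r$df, 3)
  expect_false(is.null(r$shapiro))

  # log-scale option
  rl <- paired_t(c(1, 2, 4), c(2, 4, 8), log_scale = TRUE)
  expect_true(is.na(rl$p_value))  # constant log-fold -> zero variance
  expect_error(paired_t(c(0, 1), c(1, 2), log_scale = TRUE), "positive")
  expect_error(paired_t(1, 1:2), "equal-length")
})

test_that("fold differences report both estimators", {
  expect_equal(fold_difference(c(1, 1), c(2, 4)),
               c(mean_of_ratios = 3, ratio_of_means = 3))
  expect_equal(fold_difference(c(1, 2), c(10, 2)),
               c(mean_of_ratios = 5.5, ratio_of_means = 4))
  expect_equal(unname(fold_difference(c(2, 3), c(2, 3))), c(1, 1))
  expect_true(is.na(fold_difference(c(0, 1), c(1, 2))[["mean_of_ratios"]]))
})

test_that("all reported p-values lie in the unit interval", {
  withr::with_seed(3, {
    ps <- c(
      vapply(1:50, function(i) {
        n <- sample(1:30, 1)
        binomial_two_tailed(sample(0:n, 1), n, runif(1))$p_value
      }, numeric(1)),
      vapply(1:50, function(i) {
        tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
        if (sum(tab) == 0) tab[1, 1] <- 1
        fisher_two_sided(tab)$p_value
      }, numeric(1)))
  })
  expect_true(all(ps >= 0 & ps <= 1))
})
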