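test_that("signed-rank tail probabilities match frozen enumeration values", {
  # all five differences favour the alternative: T = 0, p = 1/32
  res <- exact_signed_rank_test(c(0.1, 0.2, 0.3, 0.4, 0.5), "greater")
  expect_equal(res$T, 0)
  expect_equal(res$n_used, 5L)
  expect_equal(res$p, 1 / 32)

  # a single nonzero difference: two equiprobable signs
  expect_equal(exact_signed_rank_test(0.3, "greater")$p, 0.5)

  # negatives at ranks 2 and 3: opposing rank sum T = 5, p = 10/32
  d <- c(0.1, -0.2, -0.3, 0.4, 0.5)
  res <- exact_signed_rank_test(d, "greater")
  expect_equal(res$T, 5)
  expect_equal(res$p, 10 / 32)

  # zeros are dropped; all-zero input is undefined
  expect_equal(exact_signed_rank_test(c(0, 0.1, 0.2), "greater")$n_used, 2L)
  expect_error(exact_signed_rank_test(c(0, 0)), "zero")
})

test_that("signed-rank test equals the 2^n enumeration oracle, ties included", {
  set.seed(11)
  for (i in 1:150) {
    n <- sample(2:10, 1)
    # discrete values induce tied absolute ranks
    d <- sample(c(-4:-1, 1:4) / 4, n, replace = TRUE)
    alt <- sample(c("greater", "less", "two_sided"), 1)
    expect_equal(exact_signed_rank_test(d, alt)$p, signed_rank_oracle(d, alt),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank test agrees with R's exact Wilcoxon when ties are absent", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(3:9, 1)
    d <- round(stats::rnorm(n), 6)
    ref <- suppressWarnings(stats::wilcox.test(d, alternative = "greater",
                                               exact = TRUE))
    expect_equal(exact_signed_rank_test(d, "greater")$p, ref$p.value,
                 tolerance = 1e-10)
  }
})

test_that("2x2 Fisher kernel reproduces forced small-table values", {
  r <- fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))
  expect_equal(r$p, 1)
  expect_equal(r$or_cmle, 1, tolerance = 1e-6)

  # margins (2,2,2,2): P(0) = P(2) = 1/6, P(1) = 4/6
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3,
               tolerance = 1e-12)

  r <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(r$or_cmle, or_cmle_oracle(matrix(c(3, 1, 1, 3), 2,
                                                byrow = TRUE)),
               tolerance = 1e-4)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_true(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$degenerate)
})

test_that("2x2 p is invariant under transposition and row/column swaps", {
  set.seed(13)
  for (i in 1:40) {
    tab <- matrix(stats::rpois(4, 4), 2)
    p0 <- fisher_exact_2x2(tab)$p
    expect_equal(fisher_exact_2x2(t(tab))$p, p0, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p, p0, tolerance = 1e-12)
  }
})

test_that("conditional-MLE odds ratio is monotone in the (1,1) cell", {
  ors <- vapply(1:4, function(x) {
    fisher_exact_2x2(matrix(c(x, 5 - x, 5 - x, x), 2, byrow = TRUE))$or_cmle
  }, 0)
  expect_true(all(diff(ors) > 0))
})

test_that("r x 2 exact test matches its oracles and special cases", {
  # any 2x2 table: equal to the two-sided 2x2 kernel
  set.seed(14)
  for (i in 1:20) {
    tab <- matrix(stats::rpois(4, 3), 2)
    if (any(rowSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab)$p, fisher_exact_2x2(tab)$p,
                 tolerance = 1e-10)
  }
  # all-zero rows carry nothing
  t3 <- matrix(c(2, 0, 0, 0, 0, 2, 1, 1), 4, 2, byrow = TRUE)
  expect_equal(fisher_exact_rxc(t3)$p,
               fisher_exact_rxc(t3[rowSums(t3) > 0, ])$p)
  # 3x2 enumeration oracle
  t32 <- matrix(c(2, 0, 0, 2, 1, 1), 3, 2, byrow = TRUE)
  expect_equal(fisher_exact_rxc(t32)$p, fisher_rxc_oracle(t32),
               tolerance = 1e-10)
  # Monte-Carlo fallback estimates the exact value
  r_mc <- fisher_exact_rxc(t32, exact_limit = 1, mc_reps = 2e4, seed = 5)
  expect_identical(r_mc$method, "monte_carlo")
  expect_lt(abs(r_mc$p - fisher_rxc_oracle(t32)), 4 * r_mc$se + 1e-4)
})

test_that("KS statistic and p-value behave as the ECDF oracle dictates", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:3, 11:14)$D, 1)
  r <- ks_two_sample(c(1, 2), c(1, 2, 3))
  expect_equal(r$D, 1 / 3, tolerance = 1e-12)
  expect_true(r$ties_present)

  set.seed(15)
  for (i in 1:30) {
    xs <- stats::rnorm(sample(3:20, 1)); ys <- stats::rnorm(sample(3:20, 1))
    mine <- ks_two_sample(xs, ys)
    expect_equal(mine$D, ks_D_oracle(xs, ys), tolerance = 1e-12)
    # monotone-transform invariance of D
    expect_equal(ks_two_sample(exp(xs), exp(ys))$D, mine$D,
                 tolerance = 1e-12)
    # exact no-ties p against R's reference implementation
    ref <- stats::ks.test(xs, ys, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  }
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
})

test_that("Cohen's kappa follows the chance-corrected formula", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)
  # confusion table [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5, kappa = 0.4
  a <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 15))
  b <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
  r <- cohens_kappa(a, b)
  expect_equal(r$kappa, 0.4, tolerance = 1e-12)
  expect_equal(r$p_observed, 0.7)
  expect_equal(r$p_expected, 0.5)
  # one coder constant, the other varying: at or below chance
  expect_lte(cohens_kappa(rep("x", 10), rep(c("x", "y"), 5))$kappa, 0)
  # invariance under category relabelling
  relab <- c(x = "Q", y = "R")
  expect_equal(cohens_kappa(relab[a], relab[b])$kappa, r$kappa)
  expect_error(cohens_kappa("a", c("a", "b")), "equal length")
})
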