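test_that("normality gate accepts plausible normal samples and rejects gross outliers", {
  set.seed(42)
  x <- rnorm(8)
  # fixture kept only if Shapiro-Wilk itself agrees (independent check)
  expect_gte(shapiro.test(x)$p.value, 0.05)
  expect_true(normality_gate(x))
  expect_false(normality_gate(c(1, 1, 1, 1, 1, 1, 1, 100)))
  expect_false(normality_gate(c(1, 2)))          # too small: fallback
  expect_false(normality_gate(rep(3, 10)))       # zero variance: fallback
  expect_false(normality_gate(x, invert = TRUE)) # escape hatch flips
})

test_that("exact signed-rank p-values match exhaustive sign enumeration", {
  set.seed(1)
  for (n in 4:12) {
    for (rep in 1:3) {
      d <- round(rnorm(n), 3)
      d <- d[d != 0]
      if (anyDuplicated(abs(d))) next
      got <- avflux:::signed_rank_test(d, 0)$p_value
      expect_equal(got, signed_rank_enum_p(d), tolerance = 1e-12,
                   info = paste("n =", length(d)))
    }
  }
  # all-positive ranks, n = 8: p = 2 / 2^8
  expect_equal(avflux:::signed_rank_test(1:8)$p_value, 2 / 256)
})

test_that("one-sample location test handles degenerate and symmetric inputs", {
  expect_equal(one_sample_location_test(rep(0, 5), mu = 0)$p_value, 1)
  x <- c(0.5, 0.6, 0.55, 0.52, 0.58, 0.61, 0.57, 0.54)
  r <- one_sample_location_test(x)
  expect_lt(r$p_value, 0.001)
  # sign symmetry: negating the data leaves p unchanged
  expect_equal(one_sample_location_test(-x)$p_value, r$p_value)
})

test_that("paired test is symmetric under group exchange and null on identity", {
  x <- c(5, 6, 7, 8, 9, 10, 11, 12)
  expect_equal(paired_two_group_test(x, x)$p_value, 1)
  set.seed(3)
  y <- x + 1 + rnorm(8, 0, 0.01)
  r1 <- paired_two_group_test(y, x)
  r2 <- paired_two_group_test(x, y)
  expect_lt(r1$p_value, 0.01)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, -r2$statistic)
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(9)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_enum_q(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("outlier rule removes only points beyond k sample SDs", {
  x <- c(rep(1, 9), 10)
  expect_equal(remove_outliers(x), rep(1, 9))  # z of 10 is ~2.85
  expect_equal(remove_outliers(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(remove_outliers(rep(4, 6)), rep(4, 6))  # zero SD: keep all
})

test_that("Spearman correlation matches the d-squared formula and flags degenerate input", {
  expect_equal(spearman_correlation(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_correlation(1:8, -(1:8))$rho, -1)
  r <- spearman_correlation(1:5, c(1, 2, 3, 5, 4))
  expect_equal(r$rho, 0.9)
  expect_equal(r$rho, spearman_enum_rho(1:5, c(1, 2, 3, 5, 4)))
  expect_true(spearman_correlation(rep(1, 6), 1:6)$flagged)
  # rank-based: invariant under strictly monotone transforms
  set.seed(5)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(spearman_correlation(exp(x), y)$rho,
               spearman_correlation(x, y)$rho)
  expect_equal(spearman_correlation(exp(x), y)$p_value,
               spearman_correlation(x, y)$p_value)
})

test_that("rank-based and t-based tests are invariant to positive rescaling", {
  set.seed(13)
  x <- rnorm(8, 1); y <- rnorm(8)
  for (c_ in c(0.01, 3, 1000)) {
    expect_equal(one_sample_location_test(c_ * x)$p_value,
                 one_sample_location_test(x)$p_value)
    expect_equal(two_group_test(c_ * x, c_ * y)$p_value,
                 two_group_test(x, y)$p_value)
  }
})
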