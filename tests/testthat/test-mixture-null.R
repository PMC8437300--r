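test_that("Storey pi0 estimator behaves at the boundaries and in a mixture", {
  expect_equal(suppressWarnings(estimate_pi0(rep(1, 50))), 1)
  S <- 1000
  expect_equal(estimate_pi0(seq_len(S) / S, 0.5), 1, tolerance = 0.01)
  set.seed(15)
  p <- c(runif(8000), rbeta(2000, 0.1, 1))
  # closed-form expectation: 0.8 + 0.2 * P(Beta(0.1, 1) > 0.5) / 0.5
  e_pi0 <- 0.8 + 0.2 * (1 - 0.5^0.1) / 0.5
  expect_lt(abs(estimate_pi0(p) - e_pi0), 3 * sqrt(0.42 * 0.58 / 1e4) / 0.5)
  expect_lt(abs(estimate_pi0(p) - 0.8), 0.05)
  expect_error(estimate_pi0(numeric(0)))
})

test_that("null proportions follow the product construction", {
  set.seed(16)
  pr <- suppressWarnings(estimate_null_proportions(runif(5000), runif(5000)))
  expect_gt(pr$k00, 0.9)
  expect_equal(pr$k00 + pr$k01 + pr$k10 + pr$k11, 1, tolerance = 1e-12)
  # forced pi0 values: pure arithmetic
  pr2 <- null_proportions(k00 = 0.8 * 0.9, k10 = 0.2 * 0.9,
                          k01 = 0.8 * 0.1, k11 = 0.2 * 0.1)
  expect_equal(unlist(pr2[c("k00", "k10", "k01", "k11")]),
               c(k00 = 0.72, k10 = 0.18, k01 = 0.08, k11 = 0.02))
  expect_error(estimate_null_proportions(runif(10), runif(9)), "length")
})

test_that("Grenander power curve recovers a known alternative CDF", {
  f_id <- grenander_alt_cdf(runif(10), 1)       # degenerate branch
  expect_equal(f_id(0.37), 0.37)
  f_point <- grenander_alt_cdf(rep(1e-6, 100), 0)
  expect_equal(f_point(0.05), 1)
  set.seed(17)
  p <- c(runif(8000), rbeta(2000, 0.1, 1))
  f1 <- grenander_alt_cdf(p, 0.8)
  u <- seq(0.001, 1, by = 0.001)
  expect_lt(max(abs(vapply(u, f1, 0) - pbeta(u, 0.1, 1))), 0.05)
  v <- vapply(u, f1, 0)
  expect_true(all(diff(v) >= -1e-12))
  expect_equal(f1(0), 0)
  expect_equal(f1(1), 1)
})

test_that("mixture-null CDF matches hand arithmetic and its invariants", {
  one <- structure(function(u) 1, class = c("alt_power_curve", "function"))
  expect_equal(pmax_null_cdf(0.1, null_proportions(1, 0, 0, 0)), 0.01)
  expect_equal(pmax_null_cdf(0.3, null_proportions(0, 0, 1, 0), p10 = one), 0.3)
  # average proportions reported across ten cancer datasets, p10 = p01 = 1
  pr <- null_proportions(k00 = 0.206, k01 = 0.001, k10 = 0.789, k11 = 0.004)
  expect_equal(pmax_null_cdf(0.05, pr, p10 = one, p01 = one),
               (0.790 * 0.05 + 0.206 * 0.0025) / 0.996, tolerance = 1e-9)
  expect_error(pmax_null_cdf(0.5, null_proportions(0, 0, 0, 1)), "null mass")

  set.seed(18)
  for (i in 1:20) {
    k <- abs(rnorm(4)); k <- k / sum(k)
    pr <- null_proportions(k[1], k[2], k[3], k[4])
    pa <- c(runif(300), rbeta(200, 0.2, 1))
    f10 <- grenander_alt_cdf(pa, 0.5)
    u <- seq(0, 1, by = 0.01)
    v <- pmax_null_cdf(u, pr, p10 = f10)
    expect_true(all(diff(v) >= -1e-12))    # non-decreasing
    expect_true(all(v <= u + 1e-12))       # never exceeds the uniform
    expect_equal(v[1], 0)
  }
})

test_that("mixture-adjusted values are uniform under the complete null", {
  set.seed(19)
  S <- 10000
  tab <- iusmmt_pvalues(runif(S), runif(S))
  expect_gt(ks.test(tab$p_iusmmt, "punif")$p.value, 0.01)
  expect_true(all(tab$p_iusmmt <= tab$p_max + 1e-12))
})

test_that("adjusted values never exceed Pmax and rejections nest", {
  set.seed(20)
  pa <- c(runif(3000), rbeta(1000, 0.1, 1))
  pb <- c(runif(2000), rbeta(2000, 0.3, 1))
  fit <- iusmmt(pa, pb)
  expect_true(all(fit$p_adjusted <= fit$p_max + 1e-12))
  for (lev in c(0.01, 0.05, 0.2)) {
    r_iut <- significance_control(fit$p_iut, "fdr", lev)
    r_mix <- significance_control(fit$p_adjusted, "fdr", lev)
    expect_true(all(r_mix[r_iut]))         # IUT discoveries are a subset
  }
})

test_that("significance control implements Bonferroni and BH", {
  expect_equal(significance_control(c(0.001, 0.9), "fwer", 0.05),
               c(TRUE, FALSE))
  expect_false(any(significance_control(rep(1, 10), "fdr", 0.05)))
  expect_error(significance_control(c(0.1), "fdr", 1.5), "level")
  set.seed(21)
  S <- 10000
  flags <- significance_control(runif(S), "fdr", 0.05)
  expect_lte(mean(flags), 0.05 + 3 * sqrt(0.05 * 0.95 / S))
})
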