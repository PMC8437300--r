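test_that("null linear fit matches the normal equations", {
  # exact linear dependence
  X <- cbind(a = c(1, 2, 3, 4), b = c(0, 1, 0, 1))
  G <- 2 + 3 * X[, 1] - X[, 2]
  f <- fit_null_linear(G, X)
  expect_lt(max(abs(f$residuals)), 1e-12)
  expect_equal(f$sigma2, 0, tolerance = 1e-24)

  # intercept-only
  f0 <- fit_null_linear(c(1, 2, 3), NULL)
  expect_equal(f0$residuals, c(-1, 0, 1))

  # random fixture vs explicit normal-equations solve
  set.seed(5)
  X <- matrix(rnorm(80), 20, 4)
  G <- rnorm(20)
  f <- fit_null_linear(G, X)
  D <- cbind(1, X)
  expect_lt(max(abs(unname(f$coef) - drop(solve(crossprod(D), crossprod(D, G))))),
            1e-10)
  expect_lt(max(abs(crossprod(D, f$residuals))), 1e-8)

  # collinear design names the offender
  expect_error(fit_null_linear(G, cbind(u = X[, 1], v = 2 * X[, 1])), "v")
})

test_that("score statistic is the linear-kernel quadratic form", {
  expect_equal(score_statistic_q(matrix(rnorm(12), 4), rep(0, 4)), 0)
  expect_equal(score_statistic_q(matrix(c(1, 0, -1), 3), c(2, 1, 0)), 4)
  set.seed(6)
  M <- matrix(rnorm(18), 6, 3)
  r <- rnorm(6)
  expect_equal(score_statistic_q(M, r),
               drop(t(r) %*% M %*% t(M) %*% r))
})

test_that("methylation-expression test agrees with a permutation reference", {
  # permutation null: Q under permuted residuals.  At n = 250 the asymptotic
  # mixture and the exact permutation law agree within Monte-Carlo error; at
  # toy n they differ by O(1/n), bounded below.
  perm_ref <- function(n, K, corr, seed, B) {
    set.seed(seed)
    M <- matrix(rnorm(n * K), n, K) + corr * rnorm(n)
    X <- cbind(rnorm(n))
    G <- 0.12 * M[, 1] + 0.3 * X[, 1] + rnorm(n)
    res <- test_methylation_expression(M, G = G, X = X)
    null <- fit_null_linear(G, X)
    qs <- numeric(B)
    for (chunk in split(seq_len(B), ceiling(seq_len(B) / 10000))) {
      R <- replicate(length(chunk), sample(null$residuals))
      qs[chunk] <- colSums(crossprod(M, R)^2) / null$sigma2
    }
    c(p = res$p_value, perm = perm_p(res$q, qs), B = B)
  }
  v <- perm_ref(250, 10, 0.3, 7, B = 60000)
  expect_lt(abs(v["p"] - v["perm"]), 3 * perm_sd(v["perm"], v["B"]))
  v2 <- perm_ref(50, 5, 0.3, 7, B = 20000)
  expect_lt(abs(v2["p"] - v2["perm"]), 0.05)
})

test_that("p-value is invariant to affine recoding of covariates", {
  gd <- make_gd(n = 80, K = 6, seed = 8, tau2 = 0.02)
  p1 <- test_methylation_expression(gd)$p_value
  A <- matrix(c(2, 1, -1, 3), 2, 2)
  X2 <- gd$covariates %*% A + 5
  p2 <- test_methylation_expression(gd$methylation$values,
                                    G = gd$expression, X = X2)$p_value
  expect_equal(p1, p2, tolerance = 1e-9)
  # and to rescaling of the mediator
  p3 <- test_methylation_expression(gd$methylation$values,
                                    G = 37 * gd$expression,
                                    X = gd$covariates)$p_value
  expect_equal(p1, p3, tolerance = 1e-9)
})

test_that("M orthogonal to the residuals gives Q = 0 and p = 1", {
  set.seed(9)
  n <- 30
  X <- cbind(rnorm(n))
  G <- rnorm(n)
  r <- fit_null_linear(G, X)$residuals
  M0 <- matrix(rnorm(n * 3), n, 3)
  M <- M0 - outer(r, drop(crossprod(M0, r)) / sum(r^2))  # project out r
  res <- test_methylation_expression(M, G = G, X = X)
  expect_equal(res$q, 0, tolerance = 1e-18)
  expect_equal(res$p_value, 1)
})

test_that("stage-1 p-values are calibrated under tau2 = 0", {
  tab <- null_scan()$results
  pa <- tab$p_alpha
  expect_gt(ks.test(pa, "punif")$p.value, 0.01)
  expect_gte(mean(pa < 0.05), 0.04)
  expect_lte(mean(pa < 0.05), 0.06)
})

test_that("REML tau2 estimate is nonnegative and tracks the truth", {
  p0 <- vapply(1:30, function(i) {
    gd <- make_gd(n = 120, K = 8, seed = 100 + i, tau2 = 0)
    test_methylation_expression(gd, estimate_tau2 = TRUE)$tau2_hat
  }, 0)
  p1 <- vapply(1:30, function(i) {
    gd <- make_gd(n = 120, K = 8, seed = 200 + i, tau2 = 0.1)
    test_methylation_expression(gd, estimate_tau2 = TRUE)$tau2_hat
  }, 0)
  expect_true(all(p0 >= 0) && all(p1 >= 0))
  expect_gt(mean(p1), mean(p0))
})
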