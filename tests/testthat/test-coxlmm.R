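test_that("covariate-free Cox null fit returns Nelson-Aalen residuals", {
  outc <- survival_outcome(c(1, 2, 3, 4, 5, 6), c(1, 1, 0, 1, 0, 1))
  f <- fit_cox_ph(outc, NULL)
  atrisk <- 6:1
  haz <- ifelse(outc$status == 1, 1 / atrisk, 0)
  expect_equal(f$martingale_residuals, outc$status - cumsum(haz),
               tolerance = 1e-10)
  expect_lt(abs(sum(f$martingale_residuals)), 1e-8)
})

test_that("Cox fit maximizes the hand-written Efron partial likelihood", {
  # n = 8 printed toy, one covariate
  time <- c(2, 5, 1, 7, 3, 4, 8, 6)
  status <- c(1, 0, 1, 1, 1, 0, 1, 1)
  z <- c(0.5, -1.2, 2.0, 0.3, -0.7, 1.5, -0.2, 0.9)
  f <- fit_cox_ph(survival_outcome(time, status), cbind(z = z))
  opt <- optimize(function(b) efron_loglik_1cov(b, z, time, status),
                  c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(f$loglik, opt$objective, tolerance = 1e-6)
  expect_equal(unname(f$coef), opt$maximum, tolerance = 1e-4)
})

test_that("duplicating every subject leaves the coefficients unchanged", {
  # exact replication invariance holds for Breslow ties (the score equations
  # scale by two); Efron's within-tie correction breaks it slightly, so the
  # Breslow flag is the one cross-checked here
  gd <- make_gd(n = 40, K = 3, seed = 10, beta = 0.5)
  X <- gd$covariates
  f1 <- fit_cox_ph(gd$outcome, X, ties = "breslow")
  idx <- rep(seq_along(gd$outcome$time), 2)
  f2 <- fit_cox_ph(survival_outcome(gd$outcome$time[idx], gd$outcome$status[idx]),
                   X[idx, ], ties = "breslow")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)
})

test_that("total-effect test agrees with a permutation reference", {
  # at n = 250 the asymptotic mixture and the exact permutation law coincide
  # within Monte-Carlo error; at toy n the two differ by O(1/n), checked with
  # a bounded gap below
  perm_ref <- function(gd, B = 60000) {
    res <- total_effect_test(gd)
    r <- fit_cox_ph(gd$outcome, gd$covariates)$martingale_residuals
    M <- gd$methylation$values
    qs <- numeric(B)
    for (chunk in split(seq_len(B), ceiling(seq_len(B) / 10000))) {
      R <- replicate(length(chunk), sample(r))  # permuting rows of M == permuting r
      qs[chunk] <- colSums(crossprod(M, R)^2)
    }
    c(p = res$p_value, perm = perm_p(res$q, qs), B = B)
  }
  gd <- make_gd(n = 250, K = 8, seed = 11, tau3 = 0, censor = 0.3)
  v <- perm_ref(gd)
  expect_lt(abs(v["p"] - v["perm"]), 3 * perm_sd(v["perm"], v["B"]))

  gd2 <- make_gd(n = 60, K = 5, seed = 11, tau3 = 0.01, censor = 0.3)
  v2 <- perm_ref(gd2, B = 20000)
  expect_lt(abs(v2["p"] - v2["perm"]), 0.05)
})

test_that("total-effect test is calibrated when gammaTE = 0", {
  st <- null_study_tau3_0()
  pt <- vapply(st$genes, function(g) total_effect_test(g)$p_value, 0)
  expect_gte(mean(pt < 0.05), 0.035)
  expect_lte(mean(pt < 0.05), 0.065)
})

test_that("coxlmm collapses to the no-CpG Cox fit as tau3 -> 0", {
  gd <- make_gd(n = 80, K = 5, seed = 12, beta = 0.4, censor = 0.3)
  f <- fit_coxlmm(gd, tau3 = 1e-8)
  cox <- survival::coxph(
    survival::Surv(gd$outcome$time, gd$outcome$status) ~ gd$expression + gd$covariates,
    ties = "efron")
  expect_lt(abs(f$beta_hat - unname(cox$coefficients[1])), 1e-4)
  expect_lt(sqrt(sum(f$gamma_hat^2)), 1e-4)
})

test_that("coxlmm matches the unpenalized joint Cox fit as tau3 -> Inf", {
  set.seed(13)
  n <- 12
  M <- matrix(rnorm(n * 2), n, 2)
  G <- rnorm(n)
  X <- cbind(rnorm(n))
  outc <- survival_outcome(rexp(n), rep(c(1, 1, 1, 0), 3))
  f <- fit_coxlmm(M, G = G, outcome = outc, X = X, tau3 = 1e4,
                  control = coxlmm_control(tol = 1e-12))
  cox <- suppressWarnings(
    survival::coxph(survival::Surv(outc$time, outc$status) ~ M + G + X,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-12,
                                                      iter.max = 50)))
  expect_lt(max(abs(c(f$gamma_hat, f$beta_hat, f$w3_hat) -
                    unname(cox$coefficients))), 1e-4)
})

test_that("Wald test follows the normal reference", {
  fake <- structure(list(beta_hat = 1.959964, se_beta = 1, converged = TRUE),
                    class = "coxlmm")
  expect_equal(wald_test_beta(fake), 0.05, tolerance = 1e-6)
  fake$beta_hat <- 0
  expect_equal(wald_test_beta(fake), 1)
  fake$se_beta <- NaN
  expect_error(wald_test_beta(fake), "finite")
})

test_that("stage-2 p-values are calibrated under beta = 0", {
  tab <- null_scan()$results
  pb <- tab$p_beta
  expect_gt(ks.test(pb, "punif")$p.value, 0.01)
  expect_gte(mean(pb < 0.05), 0.035)
  expect_lte(mean(pb < 0.05), 0.065)
})

test_that("stage-2 p-value is invariant to CpG relabeling", {
  gd <- make_gd(n = 70, K = 6, seed = 14, beta = 0.3, tau3 = 0.02)
  f1 <- suppressWarnings(fit_coxlmm(gd))
  perm <- c(4, 1, 6, 3, 2, 5)
  f2 <- suppressWarnings(
    fit_coxlmm(gd$methylation$values[, perm], G = gd$expression,
               outcome = gd$outcome, X = gd$covariates))
  expect_equal(wald_test_beta(f1), wald_test_beta(f2), tolerance = 1e-8)
  expect_equal(f1$gamma_hat[perm], f2$gamma_hat, tolerance = 1e-6)
})

test_that("coxlmm recovers the expression-survival effect in mean", {
  st <- simulate_study(scenario_config("complete_null", n = 548, S = 200,
                                       beta = 0.3, seed = 1,
                                       proportions = null_proportions(0, 1, 0, 0)))
  bh <- vapply(st$genes, function(g)
    suppressWarnings(fit_coxlmm(g, control = iusmmt:::coxlmm_control_fast()))$beta_hat, 0)
  expect_lt(abs(mean(bh) - 0.3), 2 * sd(bh) / sqrt(length(bh)))
})
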