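# Shared fixtures, all generated in code.

# Small random gene dataset with optional signal on either path.
make_gd <- function(n = 60, K = 4, seed = 1, tau2 = 0, beta = 0,
                    tau3 = 0, censor = 0.4, gene_id = "toy") {
  set.seed(seed)
  blk <- simulate_methylation_block(max(n, 10), K = K, gene_id = gene_id)
  X <- cbind(x1 = standardize(rnorm(n)), x2 = standardize(sample(1:5, n, TRUE)))
  G <- simulate_expression(blk, X, tau2)
  tt <- simulate_survival(blk, G, X, beta = beta, tau3 = tau3,
                          lambda = 1, rho = 1)
  outc <- apply_censoring(tt, censor)
  gene_dataset(blk, as.numeric(G), outc, X)
}

# Hand-written Efron partial log-likelihood for a single covariate,
# independent of both the package engine and survival::coxph.
efron_loglik_1cov <- function(b, z, time, status) {
  ord <- order(time)
  z <- z[ord]; time <- time[ord]; status <- status[ord]
  eta <- b * z
  w <- exp(eta)
  ll <- 0
  for (t0 in unique(time[status == 1])) {
    risk <- time >= t0
    tied <- time == t0 & status == 1
    d <- sum(tied)
    S0 <- sum(w[risk]); s0 <- sum(w[tied])
    ll <- ll + sum(eta[tied])
    for (l in seq_len(d) - 1) ll <- ll - log(S0 - l / d * s0)
  }
  ll
}

# Permutation tail probability with add-one correction.
perm_p <- function(stat_obs, stats_perm) {
  (1 + sum(stats_perm >= stat_obs)) / (length(stats_perm) + 1)
}

# Monte-Carlo sd of a permutation p-value estimate.
perm_sd <- function(p, B) sqrt(p * (1 - p) / B)

# Cached complete-null study (tau3 = 0.02, the design's direct-effect
# variance) shared across calibration tests; built on first use.
.null_cache <- new.env(parent = emptyenv())
null_study <- function() {
  if (is.null(.null_cache$study)) {
    .null_cache$study <- simulate_study(
      scenario_config("complete_null", n = 400, S = 2000, seed = 42))
  }
  .null_cache$study
}
null_scan <- function() {
  if (is.null(.null_cache$scan)) {
    .null_cache$scan <- suppressWarnings(run_mediation_scan(null_study()))
  }
  .null_cache$scan
}
# Variant with tau3 = 0: the null of the total-effect and reverse tests.
null_study_tau3_0 <- function() {
  if (is.null(.null_cache$study0)) {
    .null_cache$study0 <- simulate_study(
      scenario_config("complete_null", n = 400, S = 1500, tau3 = 0, seed = 43))
  }
  .null_cache$study0
}
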