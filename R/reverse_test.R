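## Passenger-methylation screen: a multivariate variance-component score
## test of expression on the CpG set.  A gene flagged here shows methylation
## responding to expression, i.e. the methylation changes are likely
## downstream passengers of expression/proliferation rather than upstream
## mediators.

#' Reverse multivariate score test of expression on methylation
#'
#' Regresses the CpG matrix on expression, \eqn{M = G\tilde\beta + XW +
#' \tilde\epsilon} with \eqn{\tilde\beta_k \sim N(0, \tau)}, and tests
#' H0: tau = 0 with the score statistic
#' \eqn{Q_M = \|G'(M - \hat\mu)\hat V^{-1}\|^2}, where \eqn{\hat\mu} holds
#' the fitted values of each CpG on the intercept-augmented covariates and
#' \eqn{\hat V} is the residual covariance across CpGs, ridge-stabilized
#' when its condition number exceeds \code{1e8}. The reference weights are
#' the eigenvalues of the score vector's null covariance
#' \eqn{(\tilde G'\tilde G)\, \hat V^{-1}} (\eqn{\tilde G} the residualized
#' expression), validated against permutation in the test suite.
#'
#' @inheritParams test_methylation_expression
#' @param ridge_delta Relative ridge added to \eqn{\hat V} when
#'   ill-conditioned (default 1e-4).
#' @return List with \code{q_m}, \code{p_value} and \code{weights}.
#' @export
reverse_score_test <- function(gd, G = NULL, X = NULL, ridge_delta = 1e-4) {
  if (inherits(gd, "gene_dataset")) {
    M <- gd$methylation$values
    G <- gd$expression
    X <- gd$covariates
  } else {
    M <- as.matrix(gd)
  }
  n <- nrow(M)
  K <- ncol(M)
  X <- if (is.null(X)) matrix(nrow = n, ncol = 0) else as.matrix(X)
  D <- cbind(1, X)
  qrD <- qr(D)
  if (n - qrD$rank <= K && ridge_delta <= 0)
    stop("K approaches n - L - 1; enable ridge regularization")
  E <- qr.resid(qrD, M)                      # M - mu_hat
  Gt <- qr.resid(qrD, G)                     # residualized expression
  V <- crossprod(E) / (n - qrD$rank)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e8) {
    V <- V + ridge_delta * mean(diag(V)) * diag(K)
    ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("residual covariance of M is singular even after regularization")
  }
  s <- drop(solve(V, crossprod(E, G)))       # (V^-1 E' G), the score vector
  q_m <- sum(s^2)
  gg <- sum(Gt^2)
  weights <- gg / ev                         # eigenvalues of gg * V^-1
  list(q_m = q_m, p_value = mixture_chisq_tail(q_m, weights),
       weights = weights)
}

#' Bonferroni passenger flags across mediating genes
#'
#' Flags gene \code{i} when \code{p[i] < alpha / length(p)}; the denominator
#' is the number of mediation-significant genes screened, not the
#' genome-wide count.
#'
#' @param p_values Reverse-test p-values of the mediating genes.
#' @param alpha Family-wise level (default 0.05).
#' @return Logical vector of passenger flags (empty input gives empty
#'   output).
#' @export
flag_passengers <- function(p_values, alpha = 0.05) {
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  if (length(p_values) == 0) return(logical(0))
  p_values < alpha / length(p_values)
}
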