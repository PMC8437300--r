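## Exposure -> mediator stage: variance-component score test under a linear
## mixed model.  The CpG effects alpha_k are treated as iid N(0, tau2) random
## effects and H0: alpha = 0 (equivalently tau2 = 0) is tested with the
## linear-kernel score statistic, whose null is a mixture of chi-squares.

#' Fit the null linear model of expression on covariates
#'
#' Least-squares fit of the mediator on the covariates plus an intercept;
#' its residuals feed the variance-component score statistic.
#'
#' @param G Numeric mediator vector (length n).
#' @param X n x L covariate matrix (may have zero columns).
#' @return List with \code{coef} (intercept first), \code{residuals},
#'   \code{sigma2} (residual variance, RSS / (n - rank)), \code{qr} (the QR
#'   decomposition of the design) and \code{rank}.
#' @export
fit_null_linear <- function(G, X) {
  G <- as.numeric(G)
  n <- length(G)
  X <- if (is.null(X)) matrix(nrow = n, ncol = 0) else as.matrix(X)
  D <- cbind("(Intercept)" = 1, X)
  if (n <= ncol(D)) stop("need n > number of covariates + 1")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coef <- qr.coef(qrD, G)
  res <- qr.resid(qrD, G)
  list(coef = coef, residuals = res,
       sigma2 = sum(res^2) / (n - qrD$rank),
       qr = qrD, rank = qrD$rank)
}

#' Linear-kernel score statistic
#'
#' \eqn{Q = \sum_k (\sum_i M_{ik} r_i)^2 = r' M M' r} with \eqn{r} the
#' null-model residuals.
#'
#' @param M n x K methylation matrix or a [methylation_block()].
#' @param residuals Null-model residual vector, length n.
#' @return Nonnegative scalar.
#' @export
score_statistic_q <- function(M, residuals) {
  if (inherits(M, "methylation_block")) M <- M$values
  M <- as.matrix(M)
  if (nrow(M) != length(residuals)) stop("dimension mismatch between M and residuals")
  sum(drop(crossprod(M, residuals))^2)
}

#' Variance-component score test of methylation on expression
#'
#' Tests H0: tau2 = 0 in \eqn{G = M\alpha + Xw + \epsilon},
#' \eqn{\alpha_k \sim N(0, \tau_2)}. The statistic \eqn{Q/\hat\sigma^2_\epsilon}
#' is referred to the mixture of chi-squares with weights the nonzero
#' eigenvalues of \eqn{M' P_0 M}, \eqn{P_0} the residual-maker of the
#' intercept-augmented covariate design; this pairing makes the p-value
#' exactly invariant to rescaling of \code{G}.
#'
#' @param gd A [gene_dataset()], or an n x K matrix when \code{G} and
#'   \code{X} are given explicitly.
#' @param G,X Mediator vector and covariate matrix (ignored when \code{gd}
#'   is a \code{gene_dataset}).
#' @param estimate_tau2 If \code{TRUE}, additionally return a REML estimate
#'   of tau2 (1-D profile search; boundary value 0 allowed).
#' @return List with \code{q} (the scaled statistic), \code{weights},
#'   \code{p_value} and optionally \code{tau2_hat}.
#' @export
test_methylation_expression <- function(gd, G = NULL, X = NULL,
                                        estimate_tau2 = FALSE) {
  if (inherits(gd, "gene_dataset")) {
    M <- gd$methylation$values
    G <- gd$expression
    X <- gd$covariates
  } else {
    M <- as.matrix(gd)
  }
  null <- fit_null_linear(G, X)
  if (null$sigma2 <= 0)
    stop("residual variance is zero under the null model; p-value undefined")
  r <- null$residuals
  q <- score_statistic_q(M, r) / null$sigma2
  Mres <- qr.resid(null$qr, M)            # P0 M
  W <- crossprod(Mres)                    # M' P0 M, K x K
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10 * max(ev)]
  ## M entirely inside the covariate span: no testable variance direction
  p <- if (length(ev) == 0) 1 else mixture_chisq_tail(q, ev)
  out <- list(q = q, weights = ev, p_value = p)
  if (estimate_tau2)
    out$tau2_hat <- reml_tau2(G, null, Mres, W)
  out
}

## REML estimate of tau2 via the spectral form of the contrast likelihood.
## With W = M'P0M = V L V', the contrast-space coordinates of G along the
## nonzero-eigenvalue directions are z_j = v_j' M' P0 G / sqrt(l_j); the
## remaining n - rank - K' directions carry variance sigma2 only.  The ratio
## phi = tau2/sigma2 is profiled on a log grid over [1e-6, 10] and refined
## by golden-section; the boundary estimate 0 is allowed.
reml_tau2 <- function(G, null, Mres, W) {
  eg <- eigen(W, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values)
  lam <- eg$values[keep]
  s <- drop(crossprod(Mres, null$residuals))         # M' P0 G
  z2 <- drop(crossprod(eg$vectors[, keep, drop = FALSE], s))^2 / lam
  n_contrast <- length(G) - null$rank
  R0 <- max(sum(null$residuals^2) - sum(z2), 0)
  negll <- function(log_phi) {
    phi <- exp(log_phi)
    v <- 1 + phi * lam
    s2 <- (sum(z2 / v) + R0) / n_contrast
    0.5 * (sum(log(v)) + n_contrast * log(s2))
  }
  grid <- log(exp(seq(log(1e-6), log(10), length.out = 21)))
  vals <- vapply(grid, negll, 0)
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(negll, c(lo, hi))
  if (negll(log(1e-12)) <= opt$objective + 1e-10) return(0)  # boundary
  phi <- exp(opt$minimum)
  v <- 1 + phi * lam
  s2 <- (sum(z2 / v) + R0) / n_contrast
  phi * s2
}
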