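## Survival-side models: plain Cox null fits (via the survival package),
## the kernel-machine total-effect score test, and the Cox mixed-effects fit
## with ridge-penalized CpG direct effects whose Wald test for the mediator
## effect beta is the second stage test.

#' Fit a Cox proportional hazards null model
#'
#' Thin wrapper around [survival::coxph()] (Efron ties by default) returning
#' the pieces the kernel-machine tests need: coefficients, martingale
#' residuals and the estimated cumulative hazard diagonal.
#'
#' @param outcome A [survival_outcome()].
#' @param X n x L covariate matrix; may have zero columns (null model with
#'   baseline hazard only, whose martingale residuals are
#'   \code{status - Nelson-Aalen cumulative hazard}).
#' @param ties Tie-handling method, \code{"efron"} (default) or
#'   \code{"breslow"}.
#' @return List with \code{coef}, \code{martingale_residuals},
#'   \code{information}, \code{loglik}, \code{cumhaz} (the per-subject
#'   \eqn{\hat\Lambda_0(t_i) e^{x_i'\hat w}} = status - residual) and
#'   \code{lp} (linear predictor).
#' @export
fit_cox_ph <- function(outcome, X = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(outcome, "survival_outcome"))
  if (sum(outcome$status) < 2) stop("need at least 2 events to fit a Cox model")
  n <- length(outcome$time)
  X <- if (is.null(X)) matrix(nrow = n, ncol = 0) else as.matrix(X)
  y <- survival::Surv(outcome$time, outcome$status)
  if (ncol(X) == 0) {
    fit <- survival::coxph(y ~ 1, ties = ties)
    coef <- numeric(0)
    info <- matrix(nrow = 0, ncol = 0)
    lp <- rep(0, n)
  } else {
    if (qr(cbind(1, X))$rank < ncol(X) + 1)
      stop("covariate design is rank deficient")
    fit <- survival::coxph(y ~ X, ties = ties,
                           control = survival::coxph.control(iter.max = 100))
    if (any(!is.finite(fit$coefficients)))
      stop("Cox null fit did not converge (possible separation)")
    coef <- unname(fit$coefficients)
    info <- solve(fit$var)
    lp <- drop(X %*% coef)
  }
  r <- unname(stats::residuals(fit, type = "martingale"))
  list(coef = coef, martingale_residuals = r, information = info,
       loglik = fit$loglik[length(fit$loglik)],
       cumhaz = outcome$status - r, lp = lp)
}

#' Kernel-machine total-effect test of methylation on survival
#'
#' Tests H0: tau1 = 0 (all CpG total effects zero) in the Cox model with
#' \eqn{\gamma^{TE}_k \sim N(0, \tau_1)} random effects, using the score
#' statistic \eqn{Q_T = r' M M' r} with \eqn{r} the martingale residuals of
#' the covariate-only null fit. The reference weights are the eigenvalues of
#' \eqn{M' V M} where \eqn{V = D - D\tilde X(\tilde X' D \tilde X)^{-1}\tilde X' D},
#' \eqn{D = diag(\hat\Lambda_0(t_i) e^{x_i'\hat w})} and \eqn{\tilde X} the
#' intercept-augmented null design; this null covariance is validated against
#' permutation references in the test suite.
#'
#' @inheritParams test_methylation_expression
#' @param outcome A [survival_outcome()] (when \code{gd} is a matrix).
#' @return List with \code{q}, \code{weights} and \code{p_value}.
#' @export
total_effect_test <- function(gd, outcome = NULL, X = NULL) {
  if (inherits(gd, "gene_dataset")) {
    M <- gd$methylation$values
    outcome <- gd$outcome
    X <- gd$covariates
  } else {
    M <- as.matrix(gd)
  }
  null <- fit_cox_ph(outcome, X)
  r <- null$martingale_residuals
  q <- score_statistic_q(M, r)
  d <- null$cumhaz
  n <- length(d)
  Xt <- cbind(1, if (is.null(X)) matrix(nrow = n, ncol = 0) else as.matrix(X))
  DM <- M * d
  DX <- Xt * d
  XDX <- crossprod(Xt, DX)
  ## M'VM = M'DM - (M'DX)(X'DX)^{-1}(X'DM)
  MVM <- crossprod(M, DM) - crossprod(DM, Xt) %*% solve(XDX, crossprod(DX, M))
  ev <- eigen((MVM + t(MVM)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10 * max(ev)]
  p <- if (length(ev) == 0) 1 else mixture_chisq_tail(q, ev)
  list(q = q, weights = ev, p_value = p)
}

#' Control parameters for the Cox mixed-effects fit
#'
#' @param tau3_grid Candidate values of the CpG random-effect variance tau3
#'   for the outer profile search (log-spaced over \code{[1e-6, 10]} by
#'   default).
#' @param refine Golden-section refinement of the grid optimum.
#' @param max_iter,tol,max_halving Inner Newton-Raphson settings (relative
#'   penalized log-likelihood tolerance, step-halving budget).
#' @return List of settings for [fit_coxlmm()].
#' @export
coxlmm_control <- function(tau3_grid = exp(seq(log(1e-6), log(10), length.out = 21)),
                           refine = TRUE, max_iter = 50, tol = 1e-9,
                           max_halving = 30) {
  list(tau3_grid = tau3_grid, refine = refine, max_iter = max_iter,
       tol = tol, max_halving = max_halving)
}

## Faster outer search used by the genome-wide scan: coarser grid, no
## refinement.  The Wald p-value for beta is insensitive to fine tau3 tuning.
coxlmm_control_fast <- function() {
  coxlmm_control(tau3_grid = exp(seq(log(1e-4), log(5), length.out = 10)),
                 refine = FALSE, tol = 1e-8)
}

#' Fit the Cox mixed-effects mediator-outcome model
#'
#' Maximizes the ridge-penalized partial log-likelihood
#' \eqn{\ell(\gamma, \beta, w) - \gamma'\gamma/(2\tau_3)} jointly in the CpG
#' direct effects \eqn{\gamma}, the expression effect \eqn{\beta} and the
#' covariate effects \eqn{w} (Newton-Raphson with step-halving, Efron ties).
#' Unless \code{tau3} is fixed, the random-effect variance is chosen by
#' maximizing the Laplace-approximate integrated partial likelihood
#' \eqn{\ell_{pen} - \frac{1}{2}\log\det(I + \tau_3 H_{\gamma\gamma})} over a
#' 1-D search in \eqn{\log\tau_3}.
#'
#' @param gd A [gene_dataset()], or an n x K methylation matrix with the
#'   remaining pieces given explicitly.
#' @param G,outcome,X Mediator vector, [survival_outcome()], covariate
#'   matrix (ignored when \code{gd} is a \code{gene_dataset}).
#' @param tau3 Fix the random-effect variance instead of estimating it.
#' @param control See [coxlmm_control()].
#' @return An object of class \code{coxlmm} with components
#'   \code{beta_hat}, \code{se_beta}, \code{gamma_hat}, \code{w3_hat},
#'   \code{tau3_hat}, \code{converged}, \code{loglik}, \code{boundary}.
#' @export
fit_coxlmm <- function(gd, G = NULL, outcome = NULL, X = NULL, tau3 = NULL,
                       control = coxlmm_control()) {
  if (inherits(gd, "gene_dataset")) {
    M <- gd$methylation$values
    G <- gd$expression
    outcome <- gd$outcome
    X <- gd$covariates
  } else {
    M <- as.matrix(gd)
  }
  n <- nrow(M)
  K <- ncol(M)
  X <- if (is.null(X)) matrix(nrow = n, ncol = 0) else as.matrix(X)
  L <- ncol(X)
  if (sum(outcome$status) < 2) stop("need at least 2 events")
  if (n <= L + 2) stop("need n > L + 2")
  Z <- cbind(M, G, X)
  ord <- order(outcome$time, outcome$status)   # deterministic tie order
  Zs <- Z[ord, , drop = FALSE]
  ts <- outcome$time[ord]
  ds <- outcome$status[ord]
  p <- ncol(Z)

  inner <- function(tau3, theta0) {
    pen <- c(rep(1 / tau3, K), rep(0, p - K))
    .cox_newton_cpp(Zs, ts, ds, pen, theta0, control$max_iter, control$tol,
                    control$max_halving)
  }
  crit <- function(fit, tau3) {
    Hgg <- fit$nhess[seq_len(K), seq_len(K), drop = FALSE]
    ld <- determinant(diag(K) + tau3 * Hgg, logarithm = TRUE)$modulus
    fit$ploglik - 0.5 * as.numeric(ld)
  }

  boundary <- FALSE
  if (!is.null(tau3)) {
    fit <- inner(tau3, rep(0, p))
    tau3_hat <- tau3
  } else {
    grid <- control$tau3_grid
    theta <- rep(0, p)
    fits <- vector("list", length(grid))
    vals <- numeric(length(grid))
    for (i in seq_along(grid)) {
      fits[[i]] <- inner(grid[i], theta)
      theta <- fits[[i]]$theta               # warm start along the path
      vals[i] <- crit(fits[[i]], grid[i])
    }
    i <- which.max(vals)
    fit <- fits[[i]]
    tau3_hat <- grid[i]
    boundary <- i == 1L || i == length(grid)
    if (control$refine && !boundary) {
      f <- function(lt) {
        ft <- inner(exp(lt), fit$theta)
        crit(ft, exp(lt))
      }
      opt <- stats::optimize(f, log(c(grid[i - 1], grid[i + 1])), maximum = TRUE,
                             tol = 1e-3)
      if (opt$objective > vals[i]) {
        tau3_hat <- exp(opt$maximum)
        fit <- inner(tau3_hat, fit$theta)
      }
    }
    if (boundary)
      warning("tau3 estimate lies at the search boundary (", signif(tau3_hat, 3), ")")
  }

  pen <- c(rep(1 / tau3_hat, K), rep(0, p - K))
  Hp <- fit$nhess
  diag(Hp) <- diag(Hp) + pen
  Vp <- tryCatch(solve(Hp), error = function(e) matrix(NA_real_, p, p))
  theta <- drop(fit$theta)
  nm <- c(colnames(M), "G", if (L) colnames(X) else NULL)
  structure(list(beta_hat = theta[K + 1],
                 se_beta = sqrt(Vp[K + 1, K + 1]),
                 gamma_hat = theta[seq_len(K)],
                 w3_hat = if (L) theta[(K + 2):p] else numeric(0),
                 tau3_hat = tau3_hat,
                 converged = isTRUE(fit$converged),
                 boundary = boundary,
                 loglik = fit$loglik,
                 ploglik = fit$ploglik,
                 vcov = Vp,
                 coef = stats::setNames(theta, nm),
                 n = n, K = K, L = L,
                 n_events = sum(outcome$status)),
            class = "coxlmm")
}

#' Wald test for the expression-survival effect
#'
#' \eqn{p = 2\Phi(-|\hat\beta/se(\hat\beta)|)} from a fitted [fit_coxlmm()]
#' model; this is the second stage p-value \eqn{P_\beta}.
#'
#' @param fit A \code{coxlmm} object.
#' @return P-value in \code{[0, 1]}.
#' @export
wald_test_beta <- function(fit) {
  stopifnot(inherits(fit, "coxlmm"))
  if (!fit$converged) stop("coxlmm fit did not converge; Wald test unavailable")
  if (!is.finite(fit$se_beta) || fit$se_beta <= 0)
    stop("standard error of beta is not finite")
  2 * stats::pnorm(-abs(fit$beta_hat / fit$se_beta))
}

#' @export
print.coxlmm <- function(x, ...) {
  cat("Cox mixed-effects mediator-outcome model\n")
  cat(sprintf("  n = %d (%d events), K = %d penalized CpG effects, %d covariate(s)\n",
              x$n, x$n_events, x$K, x$L))
  cat(sprintf("  beta (expression) = %.4f (se %.4f), tau3 = %.4g%s\n",
              x$beta_hat, x$se_beta, x$tau3_hat,
              if (x$boundary) " [boundary]" else ""))
  cat(sprintf("  Wald p = %.4g; penalized loglik = %.4f%s\n",
              wald_test_beta(x), x$ploglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.coxlmm <- function(object, ...) object$coef

#' @export
vcov.coxlmm <- function(object, ...) object$vcov

#' @export
summary.coxlmm <- function(object, ...) {
  z <- object$beta_hat / object$se_beta
  out <- list(fit = object,
              beta_table = data.frame(estimate = object$beta_hat,
                                      se = object$se_beta, z = z,
                                      p = 2 * stats::pnorm(-abs(z)),
                                      row.names = "G"),
              gamma_norm = sqrt(sum(object$gamma_hat^2)))
  class(out) <- "summary.coxlmm"
  out
}

#' @export
print.summary.coxlmm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  ||gamma|| = %.4f (shrunken CpG direct effects)\n", x$gamma_norm))
  invisible(x)
}
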