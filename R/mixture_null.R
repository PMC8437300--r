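## Calibration of the max-P intersection-union statistic against an
## estimated three-component mixture null.  Under the composite null of no
## mediation, Pmax = max(P_alpha, P_beta) is distributed as
##   Pr(Pmax <= u | H0) = k10 p10(u) u + k01 p01(u) u + k00 u^2
## (normalized by the null mass k10 + k01 + k00), where p10/p01 are the
## power curves of the stage tests under their alternatives.  Evaluating
## this CDF at each gene's Pmax replaces the conservative uniform reference
## of the naive intersection-union test.

#' Storey estimator of the null proportion
#'
#' \eqn{\hat\pi_0 = \#\{p > \lambda\} / ((1 - \lambda) S)}, truncated to
#' \code{[0, 1]}.
#'
#' @param pvalues P-value vector.
#' @param lambda Tuning threshold in (0, 1); default 0.5.
#' @return Estimated proportion of true nulls.
#' @export
estimate_pi0 <- function(pvalues, lambda = 0.5) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  if (length(lambda) != 1 || lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie in (0, 1)")
  if (length(pvalues) < 100)
    warning("fewer than 100 p-values; pi0 estimate will be unstable")
  min(max(mean(pvalues > lambda) / (1 - lambda), 0), 1)
}

#' Estimate the three-component mixture null proportions
#'
#' Combines per-series Storey null proportions under a working independence
#' assumption: with \eqn{\pi_{0\alpha}} and \eqn{\pi_{0\beta}} the null
#' proportions of the two stage-test p-value series,
#' \eqn{\kappa_{00} = \pi_{0\alpha}\pi_{0\beta}},
#' \eqn{\kappa_{10} = (1-\pi_{0\alpha})\pi_{0\beta}},
#' \eqn{\kappa_{01} = \pi_{0\alpha}(1-\pi_{0\beta})} and \eqn{\kappa_{11}}
#' the remainder; each is clipped to \code{[0, 1]} and the four are
#' renormalized to sum to one.
#'
#' @param p_alpha,p_beta Stage-test p-value vectors of equal length.
#' @param lambda Storey tuning threshold.
#' @return Object of class \code{null_proportions}: list with fields
#'   \code{k00}, \code{k01}, \code{k10}, \code{k11}.
#' @export
estimate_null_proportions <- function(p_alpha, p_beta, lambda = 0.5) {
  if (length(p_alpha) != length(p_beta)) stop("p-value vectors differ in length")
  pi0a <- estimate_pi0(p_alpha, lambda)
  pi0b <- estimate_pi0(p_beta, lambda)
  null_proportions(k00 = pi0a * pi0b,
                   k10 = (1 - pi0a) * pi0b,
                   k01 = pi0a * (1 - pi0b),
                   k11 = (1 - pi0a) * (1 - pi0b))
}

#' Construct mixture null proportions
#'
#' Values are clipped to \code{[0, 1]} then renormalized to sum to one.
#'
#' @param k00,k01,k10,k11 Component probabilities: \code{k00} both stage
#'   nulls true, \code{k10} exposures affect the mediator only, \code{k01}
#'   mediator affects the outcome only, \code{k11} mediation (the
#'   alternative).
#' @return Object of class \code{null_proportions}.
#' @export
null_proportions <- function(k00, k01 = 0, k10 = 0, k11 = 0) {
  k <- pmin(pmax(c(k00 = k00, k01 = k01, k10 = k10, k11 = k11), 0), 1)
  if (sum(k) <= 0) stop("proportions sum to zero")
  k <- k / sum(k)
  structure(as.list(k), class = "null_proportions")
}

#' @export
print.null_proportions <- function(x, ...) {
  cat(sprintf("mixture null proportions: k00 = %.3f, k01 = %.3f, k10 = %.3f, k11 = %.3f\n",
              x$k00, x$k01, x$k10, x$k11))
  invisible(x)
}

## Least concave majorant of the ECDF of p-values on [0, 1].
## Returns the hull knots (x, y); the Grenander density estimate is the
## (decreasing) sequence of hull slopes.
lcm_ecdf <- function(pvalues) {
  p <- sort(pmin(pmax(pvalues, 0), 1))
  S <- length(p)
  x <- c(0, unique(p))
  y <- c(0, cumsum(tabulate(match(p, unique(p)), nbins = length(unique(p)))) / S)
  if (x[length(x)] < 1) {
    x <- c(x, 1)
    y <- c(y, 1)
  } else {
    y[length(y)] <- 1
  }
  ## upper (concave) hull by monotone chain: slopes must be non-increasing
  hx <- numeric(length(x))
  hy <- numeric(length(x))
  k <- 0L
  for (i in seq_along(x)) {
    while (k >= 2L &&
           (hy[k] - hy[k - 1L]) * (x[i] - hx[k]) <= (y[i] - hy[k]) * (hx[k] - hx[k - 1L])) {
      k <- k - 1L
    }
    k <- k + 1L
    hx[k] <- x[i]
    hy[k] <- y[i]
  }
  list(x = hx[seq_len(k)], y = hy[seq_len(k)])
}

#' Grenander estimate of a stage test's alternative power curve
#'
#' Estimates \eqn{F_1(u) = Pr(P \le u \mid alternative)} from a pooled
#' p-value series by deconvolution: the pooled CDF is taken as the least
#' concave majorant (Grenander estimator) \eqn{\hat F} of the empirical CDF,
#' and \eqn{F_1(u) = (\hat F(u) - \pi_0 u) / (1 - \pi_0)}, clipped to
#' \code{[0, 1]} and made monotone. When \eqn{\pi_0 \ge 1 - 10^{-6}} the
#' alternative mass is negligible and the identity (uniform) curve is
#' returned.
#'
#' @param pvalues Pooled p-value series of one stage test.
#' @param pi0 Estimated null proportion of the series.
#' @return Function of class \code{alt_power_curve} mapping \code{[0, 1]} to
#'   \code{[0, 1]}, non-decreasing with \code{F1(0) = 0}, \code{F1(1) = 1}.
#' @export
grenander_alt_cdf <- function(pvalues, pi0) {
  if (pi0 < 0 || pi0 > 1) stop("'pi0' must lie in [0, 1]")
  if (pi0 >= 1 - 1e-6) {
    f <- function(u) u
  } else {
    hull <- lcm_ecdf(pvalues)
    v <- pmin(pmax((hull$y - pi0 * hull$x) / (1 - pi0), 0), 1)
    v <- cummax(v)
    v[1] <- 0
    v[length(v)] <- 1
    f <- stats::approxfun(hull$x, v, method = "linear", rule = 2)
  }
  structure(f, class = c("alt_power_curve", "function"))
}

#' Mixture-null CDF of the max-P statistic
#'
#' Evaluates \eqn{[\kappa_{10} p_{10}(u) u + \kappa_{01} p_{01}(u) u +
#' \kappa_{00} u^2] / (\kappa_{10} + \kappa_{01} + \kappa_{00})}. The
#' normalization by the null mass (default) keeps the CDF at or below one
#' when \eqn{\kappa_{11} > 0}; set \code{normalize = FALSE} for the raw
#' unnormalized mixture.
#'
#' @param u Evaluation points in \code{[0, 1]} (vectorized).
#' @param props A [null_proportions()] object.
#' @param p10,p01 Alternative power curves of the two stage tests
#'   ([grenander_alt_cdf()]); defaults are the uniform (identity) curves.
#' @param normalize Divide by the null mass (default \code{TRUE}).
#' @return Values in \code{[0, 1]}, non-decreasing in \code{u} and never
#'   exceeding \code{u}.
#' @export
pmax_null_cdf <- function(u, props, p10 = NULL, p01 = NULL, normalize = TRUE) {
  stopifnot(inherits(props, "null_proportions"))
  null_mass <- props$k10 + props$k01 + props$k00
  if (null_mass <= 0) stop("no null mass: kappa11 = 1")
  if (any(u < 0 | u > 1)) stop("'u' must lie in [0, 1]")
  f10 <- if (is.null(p10)) u else vapply(u, p10, 0)
  f01 <- if (is.null(p01)) u else vapply(u, p01, 0)
  v <- props$k10 * f10 * u + props$k01 * f01 * u + props$k00 * u^2
  if (normalize) v <- v / null_mass
  pmin(pmax(v, 0), 1)
}

#' Intersection-union survival mixture-adjusted mediation test
#'
#' Given the two stage-test p-value series across genes, computes the max-P
#' statistic per gene, estimates the three-component mixture null
#' (proportions via Storey's estimator under a product construction, stage
#' power curves via the Grenander estimator) and returns the
#' mixture-adjusted significance values \eqn{\Pr(P_{max} \le p_{max,j} \mid H_0)}.
#' The naive intersection-union p-value (Pmax itself, uniform reference) is
#' retained for comparison; adjusted values never exceed it.
#'
#' @param p_alpha,p_beta Stage p-value vectors of equal length S (one entry
#'   per gene).
#' @param lambda Storey tuning threshold (default 0.5).
#' @param normalize Normalize the mixture CDF by the null mass (default
#'   \code{TRUE}).
#' @return Object of class \code{iusmmt}: list with \code{p_max},
#'   \code{p_adjusted}, \code{p_iut} (= \code{p_max}), \code{proportions},
#'   \code{p10}, \code{p01}.
#' @seealso [iusmmt_pvalues()] for a flat table, [significance_control()]
#'   for FWER/FDR flags.
#' @export
iusmmt <- function(p_alpha, p_beta, lambda = 0.5, normalize = TRUE) {
  if (length(p_alpha) != length(p_beta)) stop("p-value vectors differ in length")
  props <- estimate_null_proportions(p_alpha, p_beta, lambda)
  pi0a <- estimate_pi0(p_alpha, lambda)
  pi0b <- estimate_pi0(p_beta, lambda)
  p10 <- grenander_alt_cdf(p_alpha, pi0a)
  p01 <- grenander_alt_cdf(p_beta, pi0b)
  pmax_v <- pmax(p_alpha, p_beta)
  adj <- pmax_null_cdf(pmax_v, props, p10, p01, normalize = normalize)
  structure(list(p_max = pmax_v, p_adjusted = adj, p_iut = pmax_v,
                 proportions = props, p10 = p10, p01 = p01,
                 pi0_alpha = pi0a, pi0_beta = pi0b,
                 lambda = lambda, normalize = normalize,
                 S = length(pmax_v)),
            class = "iusmmt")
}

#' @export
print.iusmmt <- function(x, level = 0.05, ...) {
  cat(sprintf("IUSMMT mediation test over %d genes\n", x$S))
  print(x$proportions)
  cat(sprintf("  adjusted p < %.3g: %d genes (naive max-P: %d)\n", level,
              sum(x$p_adjusted < level), sum(x$p_max < level)))
  invisible(x)
}

#' @export
summary.iusmmt <- function(object, method = c("fdr", "fwer"), level = 0.05, ...) {
  method <- match.arg(method)
  flags <- significance_control(object$p_adjusted, method, level)
  flags_iut <- significance_control(object$p_iut, method, level)
  out <- list(object = object, method = method, level = level,
              n_sig = sum(flags), n_sig_iut = sum(flags_iut))
  class(out) <- "summary.iusmmt"
  out
}

#' @export
print.summary.iusmmt <- function(x, ...) {
  print(x$object)
  cat(sprintf("  %s control at %.3g: %d genes significant (naive max-P: %d)\n",
              toupper(x$method), x$level, x$n_sig, x$n_sig_iut))
  invisible(x)
}

#' Diagnostic plot for an IUSMMT fit
#'
#' QQ plot of the adjusted and naive max-P values against the uniform on the
#' -log10 scale.
#'
#' @param x An \code{iusmmt} object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.iusmmt <- function(x, ...) {
  qa <- qq_data(x$p_adjusted)
  qi <- qq_data(x$p_max)
  lim <- range(0, qa$expected, qa$observed, qi$observed)
  graphics::plot(qa$expected, qa$observed, xlim = lim, ylim = lim,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 pch = 16, cex = 0.5, ...)
  graphics::points(qi$expected, qi$observed, pch = 1, cex = 0.5, col = "grey50")
  graphics::abline(0, 1, col = "red3")
  graphics::legend("topleft", bty = "n", pch = c(16, 1),
                   col = c("black", "grey50"),
                   legend = c("mixture-adjusted", "naive max-P"))
  invisible(x)
}

#' Per-gene mediation p-value table
#'
#' Convenience wrapper around [iusmmt()] returning a flat data frame.
#'
#' @inheritParams iusmmt
#' @param gene_id Optional gene identifiers.
#' @return Data frame with columns \code{gene_id}, \code{p_alpha},
#'   \code{p_beta}, \code{p_max}, \code{p_iut}, \code{p_iusmmt}.
#' @export
iusmmt_pvalues <- function(p_alpha, p_beta, gene_id = NULL, lambda = 0.5,
                           normalize = TRUE) {
  fit <- iusmmt(p_alpha, p_beta, lambda = lambda, normalize = normalize)
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_along(p_alpha))
  out <- data.frame(gene_id = gene_id, p_alpha = p_alpha, p_beta = p_beta,
                    p_max = fit$p_max, p_iut = fit$p_iut,
                    p_iusmmt = fit$p_adjusted, stringsAsFactors = FALSE)
  attr(out, "proportions") <- fit$proportions
  out
}

#' FWER or FDR significance flags
#'
#' Bonferroni (FWER) or Benjamini-Hochberg (FDR) control applied to the
#' mixture-adjusted significance values.
#'
#' @param adjusted Vector of adjusted p-values in \code{[0, 1]}.
#' @param method \code{"fdr"} (Benjamini-Hochberg) or \code{"fwer"}
#'   (Bonferroni).
#' @param level Target error rate in (0, 1).
#' @return Logical vector of rejection flags.
#' @export
significance_control <- function(adjusted, method = c("fdr", "fwer"),
                                 level = 0.05) {
  method <- match.arg(method)
  if (length(level) != 1 || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)")
  if (any(adjusted < 0 | adjusted > 1)) stop("adjusted values must lie in [0, 1]")
  corrected <- switch(method,
                      fdr = stats::p.adjust(adjusted, method = "BH"),
                      fwer = stats::p.adjust(adjusted, method = "bonferroni"))
  corrected < level
}
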