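## Tail probabilities of positive linear combinations of chi-square(1)
## variables, the reference distribution of every variance-component score
## statistic in the package.

#' Upper tail of a mixture of chi-square(1) variables
#'
#' Computes \eqn{P(\sum_j \lambda_j \chi^2_{1,j} > q)} for nonnegative
#' weights \eqn{\lambda_j} by exact numerical inversion of the
#' characteristic function (Davies' algorithm, via
#' \code{\link[mgcv]{psum.chisq}}, accuracy \code{acc}). When the inversion
#' fails or returns a value outside \eqn{[10^{-14}, 1]}, a moment-matching
#' (Liu-type) noncentral chi-square approximation is used instead.
#'
#' Weights below \code{1e-10} times the largest weight are dropped as
#' numerical zeros.
#'
#' @param q Observed statistic (scalar, nonnegative in typical use).
#' @param weights Nonnegative mixture weights; at least one must be positive.
#' @param acc Target accuracy of the inversion.
#' @return Tail probability in \code{[0, 1]}.
#' @examples
#' mixture_chisq_tail(qchisq(0.95, df = 1), 1)   # 0.05
#' @export
mixture_chisq_tail <- function(q, weights, acc = 1e-7) {
  weights <- as.numeric(weights)
  if (length(weights) == 0 || any(weights < 0) || all(weights == 0))
    stop("'weights' must contain at least one positive value and no negatives")
  weights <- weights[weights > 1e-10 * max(weights)]
  if (length(q) != 1L || !is.finite(q)) stop("'q' must be a finite scalar")
  if (q <= 0) return(1)

  davies <- function(tol, nlim) tryCatch(
    suppressWarnings(as.numeric(mgcv::psum.chisq(q, lb = weights, tol = tol,
                                                 nlim = nlim))),
    error = function(e) NA_real_)
  p <- davies(acc, 1e6)
  if (!is.finite(p) || p > 1) p <- davies(2e-5, 1e5)  # coarser, sturdier pass
  if (!is.finite(p) || p < 1e-14 || p > 1) p <- liu_tail(q, weights)
  min(max(p, 0), 1)
}

## Liu, Tang & Zhang (2009) four-moment noncentral chi-square approximation.
liu_tail <- function(q, lambda) {
  c1 <- sum(lambda)
  c2 <- sum(lambda^2)
  c3 <- sum(lambda^3)
  c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    df <- c2^3 / c3^2
  }
  mu_x <- df + delta
  sigma_x <- sqrt(2) * a
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sigma_x + mu_x, df = df, ncp = delta, lower.tail = FALSE)
}
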