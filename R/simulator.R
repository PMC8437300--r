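## Synthetic-data generator for the simulation design the tests and the
## acceptance study run on: correlated CpG blocks, a mixed-model mediator,
## Weibull inverse-probability survival times and random censoring at a
## fixed rate, with per-gene ground-truth component labels (00/01/10/11).

scenario_table <- list(
  complete_null      = c(k00 = 1.00, k01 = 0.00, k10 = 0.00, k11 = 0.00),
  dense_null         = c(k00 = 0.10, k01 = 0.85, k10 = 0.05, k11 = 0.00),
  sparse_null        = c(k00 = 0.99, k01 = 0.01, k10 = 0.00, k11 = 0.00),
  dense_alternative  = c(k00 = 0.10, k01 = 0.75, k10 = 0.05, k11 = 0.10),
  sparse_alternative = c(k00 = 0.90, k01 = 0.00, k10 = 0.00, k11 = 0.10)
)

#' Scenario configuration for a simulated mediation study
#'
#' The five named scenarios carry the component-label frequencies of the
#' simulation design: \code{complete_null} (1, 0, 0, 0), \code{dense_null}
#' (0.10, 0.85, 0.05, 0), \code{sparse_null} (0.99, 0.01, 0, 0),
#' \code{dense_alternative} (0.10, 0.75, 0.05, 0.10) and
#' \code{sparse_alternative} (0.90, 0, 0, 0.10), ordered
#' (k00, k01, k10, k11).
#'
#' @param name Scenario name (see above).
#' @param n Samples per gene dataset.
#' @param S Number of genes (independent datasets).
#' @param tau2 Methylation-expression variance component for active (10/11)
#'   genes.
#' @param beta Expression-survival effect for active (01/11) genes.
#' @param tau3 Variance of the CpG direct effects on survival (all genes).
#' @param lambda,rho Weibull shape and scale of the survival generator.
#' @param censor_rate Fraction of subjects censored (exact count).
#' @param ar_rho Lag-1 correlation of the CpG block.
#' @param seed RNG seed; the study is fully reproducible from the config.
#' @param proportions Optional [null_proportions()] overriding the named
#'   scenario's label frequencies.
#' @return List of class \code{scenario_config}.
#' @export
scenario_config <- function(name = c("complete_null", "dense_null", "sparse_null",
                                     "dense_alternative", "sparse_alternative"),
                            n = 400, S = 1000, tau2 = 0.04, beta = 0.25,
                            tau3 = 0.02, lambda = 1, rho = 0.01,
                            censor_rate = 0.5, ar_rho = 0.5, seed = 1,
                            proportions = NULL) {
  name <- match.arg(name)
  if (is.null(proportions)) {
    k <- scenario_table[[name]]
    proportions <- null_proportions(k["k00"], k["k01"], k["k10"], k["k11"])
  }
  stopifnot(inherits(proportions, "null_proportions"))
  if (n < 10) stop("need n >= 10")
  if (censor_rate < 0 || censor_rate >= 1) stop("'censor_rate' must lie in [0, 1)")
  if (tau2 < 0 || tau3 < 0 || lambda <= 0 || rho <= 0) stop("invalid parameters")
  active <- proportions$k10 + proportions$k11 > 0
  if (active && tau2 == 0)
    stop("scenario has genes with an exposure-mediator effect but tau2 = 0")
  if (proportions$k01 + proportions$k11 > 0 && beta == 0)
    stop("scenario has genes with a mediator-outcome effect but beta = 0")
  structure(list(name = name, proportions = proportions, n = n, S = S,
                 tau2 = tau2, beta = beta, tau3 = tau3, lambda = lambda,
                 rho = rho, censor_rate = censor_rate, ar_rho = ar_rho,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a correlated CpG methylation block
#'
#' K (drawn uniformly from \code{{10, ..., 30}} when \code{NULL}) columns of
#' an AR(1)-correlated Gaussian with \code{corr(i, j) = ar_rho^|i-j|}, then
#' column-standardized. A synthetic stand-in for real CpG blocks, which show
#' comparably high local inter-CpG correlation.
#'
#' @param n Sample count (>= 10).
#' @param K Number of CpGs; \code{NULL} draws from \code{{10, ..., 30}}.
#' @param ar_rho Lag-1 correlation (default 0.5).
#' @param gene_id Identifier for the block.
#' @return A [methylation_block()].
#' @export
simulate_methylation_block <- function(n, K = NULL, ar_rho = 0.5,
                                       gene_id = "gene") {
  if (n < 10) stop("need n >= 10")
  if (is.null(K)) K <- sample(10:30, 1)
  C <- ar_rho^abs(outer(seq_len(K), seq_len(K), "-"))
  Z <- matrix(stats::rnorm(n * K), n, K) %*% chol(C)
  methylation_block(gene_id, standardize(Z),
                    cpg_ids = paste0(gene_id, "_cpg", seq_len(K)))
}

#' Simulate the mediator from the linear mixed model
#'
#' \eqn{G = M\alpha + 0.5 x_1 + 0.5 x_2 + \epsilon} with
#' \eqn{\alpha_k \sim N(0, \tau_2)} and \eqn{\epsilon \sim N(0, 1)}.
#'
#' @param M Methylation matrix or [methylation_block()].
#' @param X n x 2 covariate matrix.
#' @param tau2 Variance of the CpG effects on expression (>= 0).
#' @param covar_effects Covariate effect sizes (default \code{c(0.5, 0.5)}).
#' @return Numeric mediator vector; the drawn \code{alpha} is attached as an
#'   attribute.
#' @export
simulate_expression <- function(M, X, tau2, covar_effects = c(0.5, 0.5)) {
  if (inherits(M, "methylation_block")) M <- M$values
  if (tau2 < 0) stop("'tau2' must be nonnegative")
  n <- nrow(M)
  alpha <- stats::rnorm(ncol(M), 0, sqrt(tau2))
  G <- drop(M %*% alpha) + drop(as.matrix(X) %*% covar_effects) + stats::rnorm(n)
  attr(G, "alpha") <- alpha
  G
}

#' Simulate Weibull survival times by inverse probability
#'
#' \eqn{t = (-\log u / (\lambda e^\eta))^{1/\rho}} with
#' \eqn{\eta = M\gamma^{DE} + G\beta + 0.5 x_1 + 0.5 x_2},
#' \eqn{\gamma^{DE}_k \sim N(0, \tau_3)} and \eqn{u \sim U(0, 1)}.
#' With very small \code{rho} the times span hundreds of orders of
#' magnitude; \code{log_time = TRUE} returns \eqn{\log t} exactly, avoiding
#' overflow (the Cox partial likelihood depends on times only through
#' ranks).
#'
#' @param M Methylation matrix or block.
#' @param G Mediator vector.
#' @param X n x 2 covariate matrix.
#' @param beta Expression effect on the log hazard.
#' @param tau3 Variance of the CpG direct effects.
#' @param lambda,rho Weibull shape and scale (both > 0).
#' @param covar_effects Covariate effect sizes.
#' @param log_time Return log survival times.
#' @return Vector of uncensored times (or log times).
#' @export
simulate_survival <- function(M, G, X, beta = 0, tau3 = 0.02, lambda = 1,
                              rho = 0.01, covar_effects = c(0.5, 0.5),
                              log_time = FALSE) {
  if (inherits(M, "methylation_block")) M <- M$values
  if (lambda <= 0 || rho <= 0) stop("'lambda' and 'rho' must be positive")
  n <- nrow(M)
  gamma <- stats::rnorm(ncol(M), 0, sqrt(tau3))
  eta <- drop(M %*% gamma) + beta * as.numeric(G) +
    drop(as.matrix(X) %*% covar_effects)
  u <- stats::runif(n)
  logt <- (log(-log(u)) - log(lambda) - eta) / rho
  if (log_time) logt else exp(logt)
}

#' Apply random censoring at an exact rate
#'
#' Exactly \code{round(rate * n)} subjects, chosen uniformly at random, are
#' censored; each censored subject's observed time is drawn uniformly on
#' \code{(0, t_i)}. The remaining subjects are observed events at \code{t_i}.
#'
#' @param times Uncensored event times (or log times, see \code{log_time}).
#' @param rate Censoring fraction in \code{[0, 1)}.
#' @param log_time Treat \code{times} as log times; the uniform truncation
#'   is then applied on the original scale via \code{log t + log U}.
#' @return A [survival_outcome()] when \code{log_time = FALSE}; otherwise a
#'   list with \code{time} (log scale) and \code{status}.
#' @export
apply_censoring <- function(times, rate, log_time = FALSE) {
  if (rate < 0 || rate >= 1) stop("'rate' must lie in [0, 1)")
  n <- length(times)
  status <- rep(1, n)
  obs <- as.numeric(times)
  m <- round(rate * n)
  if (m > 0) {
    idx <- sample.int(n, m)
    u <- stats::runif(m)
    obs[idx] <- if (log_time) obs[idx] + log(u) else obs[idx] * u
    status[idx] <- 0
  }
  if (log_time) list(time = obs, status = status)
  else survival_outcome(obs, status)
}

#' Simulate a full mediation study
#'
#' Draws per-gene component labels from the scenario proportions and, for
#' each gene, an independent dataset: CpG block, covariates
#' (\eqn{x_1 \sim N(0,1)} age-like, \eqn{x_2} ordinal 1-5 stage-like, both
#' standardized), mediator and censored Weibull survival outcome. Genes
#' labelled 10/11 get \code{tau2 > 0}; genes labelled 01/11 get
#' \code{beta != 0}; every gene carries CpG direct effects with variance
#' \code{tau3}.
#'
#' Survival times are generated exactly on the log scale (uniform(0, t)
#' censoring applied as \code{log t + log U}) and stored through the
#' monotone map \code{exp(rho * log t)}, which preserves all ranks and ties;
#' with very small \code{rho} the natural scale would overflow double
#' precision.
#'
#' @param config A [scenario_config()].
#' @return Object of class \code{simulated_study}: list with \code{genes}
#'   (named list of [gene_dataset()]), \code{truth} (per-gene labels
#'   \code{"00"/"01"/"10"/"11"}) and \code{config}.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  pr <- config$proportions
  labels <- sample(c("00", "01", "10", "11"), config$S, replace = TRUE,
                   prob = c(pr$k00, pr$k01, pr$k10, pr$k11))
  ids <- sprintf("g%05d", seq_len(config$S))
  genes <- vector("list", config$S)
  n <- config$n
  for (j in seq_len(config$S)) {
    blk <- simulate_methylation_block(n, ar_rho = config$ar_rho,
                                      gene_id = ids[j])
    x1 <- standardize(stats::rnorm(n))
    repeat {
      x2raw <- sample(1:5, n, replace = TRUE)
      if (length(unique(x2raw)) > 1) break
    }
    X <- cbind(x1 = x1, x2 = standardize(x2raw))
    tau2_j <- if (labels[j] %in% c("10", "11")) config$tau2 else 0
    beta_j <- if (labels[j] %in% c("01", "11")) config$beta else 0
    G <- simulate_expression(blk, X, tau2_j)
    logt <- simulate_survival(blk, G, X, beta = beta_j, tau3 = config$tau3,
                              lambda = config$lambda, rho = config$rho,
                              log_time = TRUE)
    cen <- apply_censoring(logt, config$censor_rate, log_time = TRUE)
    outcome <- survival_outcome(exp(config$rho * cen$time), cen$status)
    genes[[j]] <- gene_dataset(blk, as.numeric(G), outcome, X)
  }
  names(genes) <- ids
  structure(list(genes = genes, truth = stats::setNames(labels, ids),
                 config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated mediation study: scenario '%s', S = %d genes, n = %d\n",
              x$config$name, x$config$S, x$config$n))
  print(table(truth = x$truth))
  invisible(x)
}

#' Write a simulated study to the flat study layout
#'
#' Emits the TSV/BED files that [assemble_gene_datasets()] reads:
#' \code{methylation.tsv}, \code{expression.tsv}, \code{clinical.tsv},
#' \code{genes.bed}, \code{cpgs.bed} and (when the yaml package is
#' available) \code{config.yaml}. Synthetic coordinates place each gene on
#' chr1 with its CpGs inside the gene body.
#'
#' The flat layout shares a single clinical table across genes, whereas a
#' simulated study draws an independent outcome per gene; the first gene's
#' outcome and covariates are written. The layout is intended for exercising
#' the file readers and for real-data-shaped exports, not for losslessly
#' serializing multi-gene independent-replicate studies.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- study$config$n
  samples <- sprintf("s%04d", seq_len(n))

  meth <- do.call(rbind, lapply(study$genes, function(g) t(g$methylation$values)))
  colnames(meth) <- samples
  write_matrix_tsv(meth, file.path(dir, "methylation.tsv"), id_col = "cpg")

  expr <- do.call(rbind, lapply(study$genes, function(g) matrix(g$expression, 1)))
  rownames(expr) <- names(study$genes)
  colnames(expr) <- samples
  write_matrix_tsv(expr, file.path(dir, "expression.tsv"), id_col = "gene")

  g1 <- study$genes[[1]]
  clin <- data.frame(sample = samples,
                     time = sprintf("%.17g", g1$outcome$time),
                     status = g1$outcome$status,
                     apply(g1$covariates, 2, function(v) sprintf("%.17g", v)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  off <- 0L
  gene_rows <- cpg_rows <- vector("list", length(study$genes))
  for (j in seq_along(study$genes)) {
    blk <- study$genes[[j]]$methylation
    K <- length(blk$cpg_ids)
    body_len <- 1000L * (K + 1L)
    gene_rows[[j]] <- data.frame(chrom = "chr1", start = off,
                                 end = off + body_len, name = blk$gene_id,
                                 score = 0, strand = "+",
                                 stringsAsFactors = FALSE)
    cpg_rows[[j]] <- data.frame(chrom = "chr1",
                                start = off + 1000L * seq_len(K),
                                end = off + 1000L * seq_len(K) + 1L,
                                name = blk$cpg_ids, score = 0, strand = "+",
                                stringsAsFactors = FALSE)
    off <- off + body_len + 10000L
  }
  utils::write.table(do.call(rbind, gene_rows), file.path(dir, "genes.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(do.call(rbind, cpg_rows), file.path(dir, "cpgs.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- study$config
    cfg$proportions <- unclass(cfg$proportions)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
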