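#' Convert methylation beta values to M-values
#'
#' Applies the logit (base 2) transform \code{log2(beta / (1 - beta))}.
#' M-values are unbounded and better suited to linear modelling than beta
#' values, which live in (0, 1).
#'
#' @param beta Numeric vector of methylation beta values, strictly inside
#'   (0, 1).
#' @return Numeric vector of M-values.
#' @examples
#' beta_to_mvalue(c(0.2, 0.5, 0.8))
#' @export
beta_to_mvalue <- function(beta) {
  if (!is.numeric(beta)) stop("'beta' must be numeric")
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1))
    stop("beta values must lie strictly in (0, 1); clamp or drop boundary values first")
  log2(beta / (1 - beta))
}

#' Standardize columns to mean zero and unit variance
#'
#' Centers each column and scales it by its sample standard deviation
#' (denominator n - 1), so that \code{mean == 0} and \code{var == 1}
#' exactly. Constant columns are an error because they carry no signal and
#' cannot be scaled.
#'
#' @param x Numeric vector or matrix; matrices are standardized column-wise.
#' @return Object of the same shape as \code{x}.
#' @export
standardize <- function(x) {
  if (is.null(dim(x))) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
    return(as.numeric((x - mean(x)) / s))
  }
  x <- as.matrix(x)
  s <- apply(x, 2, stats::sd)
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("constant column(s) cannot be standardized: ", paste(nm, collapse = ", "))
  }
  out <- sweep(sweep(x, 2, colMeans(x)), 2, s, "/")
  dimnames(out) <- dimnames(x)
  out
}

#' Construct a methylation block
#'
#' One gene's CpG measurement matrix: n samples by K sites, M-value scale.
#'
#' @param gene_id Gene identifier.
#' @param values n x K numeric matrix (samples in rows).
#' @param cpg_ids Character vector of K CpG identifiers; defaults to the
#'   column names of \code{values}.
#' @return A \code{methylation_block} list with fields \code{gene_id},
#'   \code{cpg_ids} and \code{values}.
#' @export
methylation_block <- function(gene_id, values, cpg_ids = colnames(values)) {
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("a methylation block needs at least one CpG site")
  if (anyNA(values)) stop("methylation values must not contain missing values")
  if (is.null(cpg_ids)) cpg_ids <- paste0("cpg", seq_len(ncol(values)))
  if (length(cpg_ids) != ncol(values))
    stop("'cpg_ids' length must equal the number of columns")
  colnames(values) <- cpg_ids
  structure(list(gene_id = as.character(gene_id),
                 cpg_ids = as.character(cpg_ids),
                 values = values),
            class = "methylation_block")
}

#' Construct a survival outcome
#'
#' @param time Positive observed times (event or censoring).
#' @param status 0/1 event indicator (1 = event observed).
#' @return A \code{survival_outcome} list.
#' @export
survival_outcome <- function(time, status) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) != length(status)) stop("'time' and 'status' lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("'time' must be positive and finite")
  if (!all(status %in% c(0, 1))) stop("'status' must be 0/1")
  structure(list(time = time, status = status), class = "survival_outcome")
}

#' Assemble one gene's mediation dataset
#'
#' Bundles the methylation block (exposures), expression vector (mediator),
#' survival outcome and covariates for a single gene, enforcing a shared
#' sample count.
#'
#' @param methylation A [methylation_block()].
#' @param expression Numeric vector, length n.
#' @param outcome A [survival_outcome()].
#' @param covariates n x L numeric matrix (may have zero columns).
#' @return A \code{gene_dataset} list.
#' @export
gene_dataset <- function(methylation, expression, outcome, covariates) {
  stopifnot(inherits(methylation, "methylation_block"),
            inherits(outcome, "survival_outcome"))
  covariates <- as.matrix(covariates)
  n <- nrow(methylation$values)
  if (length(expression) != n || length(outcome$time) != n || nrow(covariates) != n)
    stop("all components of a gene dataset must share the sample count")
  structure(list(methylation = methylation,
                 expression = as.numeric(expression),
                 outcome = outcome,
                 covariates = covariates),
            class = "gene_dataset")
}

#' @export
print.gene_dataset <- function(x, ...) {
  cat(sprintf("gene_dataset '%s': n = %d samples, K = %d CpGs, %d covariate(s), %d events\n",
              x$methylation$gene_id, nrow(x$methylation$values),
              ncol(x$methylation$values), ncol(x$covariates),
              sum(x$outcome$status)))
  invisible(x)
}

## ---- file formats -----------------------------------------------------------
## Matrices: TSV, first column = feature id, header = sample ids.
## Clinical: TSV with sample, time, status, then covariates.
## Annotation: BED6, 0-based half-open.

#' Read a feature-by-sample matrix from TSV
#'
#' @param path TSV file; first column holds feature ids, header holds sample
#'   ids.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the doubles bit-for-bit.
#'
#' @param m Numeric matrix with rownames (feature ids) and colnames (samples).
#' @param path Output path.
#' @param id_col Header name for the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- data.frame(id = rownames(m),
                   apply(m, 2, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' @param path TSV with required columns \code{sample}, \code{time},
#'   \code{status}; any remaining columns are treated as covariates.
#' @return Data frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  df
}

#' Read a BED6 annotation file
#'
#' Coordinates follow the BED convention: 0-based, half-open intervals.
#'
#' @param path BED file with columns chrom, start, end, name, score, strand
#'   (score/strand optional; strand defaults to \code{"+"}).
#' @return Data frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED file needs at least 4 columns (chrom, start, end, name)")
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  if (ncol(df) >= 5) names(df)[5] <- "score" else df$score <- 0
  if (ncol(df) >= 6) names(df)[6] <- "strand" else df$strand <- "+"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$name <- as.character(df$name)
  df[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Map CpG sites to genes by position
#'
#' A CpG belongs to a gene when it falls inside the gene body or within
#' \code{promoter_bp} bases upstream of the transcription start site,
#' strand-aware: upstream is 5' of the TSS on the annotated strand. All
#' intervals are BED-style 0-based half-open; the CpG's \code{start}
#' coordinate is tested.
#'
#' @param genes BED data frame of gene bodies (name = gene id, strand used).
#' @param cpgs BED data frame of CpG positions (name = CpG id).
#' @param promoter_bp Promoter window length in bases (default 500).
#' @return Data frame with columns \code{cpg} and \code{gene}.
#' @export
map_cpgs_to_genes <- function(genes, cpgs, promoter_bp = 500) {
  out <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    if (identical(genes$strand[g], "-")) {
      lo <- genes$start[g]
      hi <- genes$end[g] + promoter_bp
    } else {
      lo <- genes$start[g] - promoter_bp
      hi <- genes$end[g]
    }
    hit <- cpgs$chrom == genes$chrom[g] & cpgs$start >= lo & cpgs$start < hi
    if (any(hit))
      out[[g]] <- data.frame(cpg = cpgs$name[hit], gene = genes$name[g],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(data.frame(cpg = character(), gene = character(),
                                        stringsAsFactors = FALSE))))
}

#' Assemble per-gene mediation datasets from study tables
#'
#' Intersects sample ids across the methylation, expression and clinical
#' tables, maps CpGs to genes by coordinate (gene body plus a promoter
#' window upstream of the TSS), standardizes methylation and expression, and
#' returns one [gene_dataset()] per gene with at least one mapped CpG and a
#' matching expression row. Genes are returned in lexicographic order.
#'
#' Missing values: clinical covariates are mean-imputed; methylation or
#' expression feature rows containing missing values are dropped (with a log
#' entry), not imputed. CpGs constant across the retained samples are also
#' dropped.
#'
#' @param methylation CpG x sample numeric matrix (M-values).
#' @param expression Gene x sample numeric matrix.
#' @param clinical Clinical data frame from [read_clinical_tsv()].
#' @param gene_annotation BED data frame of gene bodies.
#' @param cpg_positions BED data frame of CpG positions.
#' @param promoter_bp Promoter window upstream of the TSS (default 500).
#' @return Named list of \code{gene_dataset} objects; attribute \code{"log"}
#'   records skipped features/genes, attribute \code{"samples"} the sample
#'   ids used (sorted intersection).
#' @export
assemble_gene_datasets <- function(methylation, expression, clinical,
                                   gene_annotation, cpg_positions,
                                   promoter_bp = 500) {
  log <- character()
  samples <- sort(intersect(intersect(colnames(methylation), colnames(expression)),
                            clinical$sample))
  if (length(samples) == 0) stop("no samples shared across methylation, expression and clinical tables")

  drop_m <- rownames(methylation)[apply(methylation, 1, anyNA)]
  if (length(drop_m))
    log <- c(log, paste0("dropped CpG with missing values: ", drop_m))
  methylation <- methylation[setdiff(rownames(methylation), drop_m), samples, drop = FALSE]
  drop_e <- rownames(expression)[apply(expression, 1, anyNA)]
  if (length(drop_e))
    log <- c(log, paste0("dropped expression row with missing values: ", drop_e))
  expression <- expression[setdiff(rownames(expression), drop_e), samples, drop = FALSE]

  clinical <- clinical[match(samples, clinical$sample), , drop = FALSE]
  covar_cols <- setdiff(names(clinical), c("sample", "time", "status"))
  covariates <- as.matrix(clinical[, covar_cols, drop = FALSE])
  if (ncol(covariates)) {
    storage.mode(covariates) <- "double"
    for (j in seq_len(ncol(covariates))) {      # mean imputation of covariates
      na <- is.na(covariates[, j])
      if (any(na)) covariates[na, j] <- mean(covariates[!na, j])
    }
  }
  outcome <- survival_outcome(clinical$time, clinical$status)

  mapping <- map_cpgs_to_genes(gene_annotation, cpg_positions, promoter_bp)
  mapping <- mapping[mapping$cpg %in% rownames(methylation), , drop = FALSE]
  genes <- sort(unique(gene_annotation$name))

  out <- list()
  for (g in genes) {
    cpg <- mapping$cpg[mapping$gene == g]
    if (length(cpg) == 0) {
      log <- c(log, paste0("gene skipped (no mapped CpG): ", g))
      next
    }
    if (!g %in% rownames(expression)) {
      log <- c(log, paste0("gene skipped (no expression row): ", g))
      next
    }
    M <- t(methylation[cpg, , drop = FALSE])
    keep <- apply(M, 2, function(v) stats::sd(v) > 0)
    if (!all(keep))
      log <- c(log, paste0("dropped constant CpG in ", g, ": ",
                           colnames(M)[!keep]))
    M <- M[, keep, drop = FALSE]
    if (ncol(M) == 0) {
      log <- c(log, paste0("gene skipped (no usable CpG): ", g))
      next
    }
    G <- expression[g, ]
    if (stats::sd(G) == 0) {
      log <- c(log, paste0("gene skipped (constant expression): ", g))
      next
    }
    out[[g]] <- gene_dataset(methylation_block(g, standardize(M)),
                             standardize(G), outcome, covariates)
  }
  attr(out, "log") <- log
  attr(out, "samples") <- samples
  out
}
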