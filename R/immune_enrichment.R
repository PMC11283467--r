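# Single-sample rank-based gene-set enrichment (ssGSEA-style) for an immune
# signature, and the 60th-percentile high/low grouping of the scores.
#
# Scores are rank-based, hence invariant to any strictly increasing
# per-sample transform of expression, and comparable only within a cohort -
# which is all the quantile grouping requires.

#' Read a gene x sample expression matrix
#'
#' TSV/CSV with genes in rows and samples in columns; the first column holds
#' gene symbols. Values are expected on a non-negative abundance scale such
#' as TPM.
#'
#' @param path Path to the matrix file (delimiter inferred from extension:
#'   `.csv` is comma-separated, anything else tab-separated).
#' @return A numeric matrix with gene symbols as rownames.
#' @export
read_expression_matrix <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1])
  mode(m) <- "double"
  rownames(m) <- genes
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix")
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  m
}

#' Read a gene set (one symbol per line)
#'
#' @param path Path to the gene-set file.
#' @return Character vector of unique symbols.
#' @export
read_gene_set <- function(path) {
  g <- canon_gene(readLines(path))
  unique(g[nzchar(g)])
}

#' Single-sample gene-set enrichment score
#'
#' For each sample, genes are ranked by expression (average ranks for ties)
#' and walked in decreasing order; the score is the running-sum difference
#' between the weighted in-set empirical CDF (weights `rank^alpha`) and the
#' unweighted out-of-set ECDF, summed over the whole list. Positive scores
#' mean the set is expressed above the background. Ties in expression are
#' ordered by gene symbol so the score does not depend on the row order of
#' the input matrix.
#'
#' @param expr Numeric gene x sample matrix with gene symbols as rownames
#'   (see [read_expression_matrix()]).
#' @param gene_set Character vector of set symbols (at least 2 must be
#'   present in the matrix).
#' @param alpha Rank-weighting exponent (default 0.25, the conventional
#'   ssGSEA choice; 0 gives the unweighted rank statistic).
#' @return Named numeric vector, sample id -> enrichment score.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), alpha >= 0)
  genes <- rownames(expr)
  in_set <- genes %in% gene_set
  m <- sum(in_set)
  if (m < 2) {
    stop(sprintf("only %d gene(s) of the set found in the matrix; >= 2 required", m))
  }
  if (m == length(genes)) stop("gene set covers the whole matrix; no background")
  n_genes <- length(genes)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(-r, genes, method = "radix")
    inset_ord <- in_set[ord]
    w <- r[ord]^alpha
    w[!inset_ord] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inset_ord) / (n_genes - m)
    sum(p_in - p_out)
  }, 0)
  stats::setNames(scores, colnames(expr))
}

#' High/low immune-score groups at a quantile
#'
#' Delegates to [dichotomize_quantile()]: samples whose score strictly
#' exceeds the empirical `q`-quantile threshold are `"high"`.
#'
#' @param scores Named numeric vector of per-sample enrichment scores.
#' @param q Quantile (default 0.6).
#' @return As [dichotomize_quantile()].
#' @export
immune_groups <- function(scores, q = 0.6) {
  dichotomize_quantile(scores, q)
}
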