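# FPKM-threshold expression filtering and Spearman correlations between
# tissues and between lncRNAs and their host genes.

#' Validate an expression matrix (genes x tissues, FPKM >= 0)
#' @param m numeric matrix with unique rownames (gene ids) and colnames
#'   (tissue labels)
#' @return the matrix, invisibly, after validation
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m)))) {
    stop("expression matrix needs unique gene ids as rownames",
         call. = FALSE)
  }
  if (is.null(colnames(m))) {
    stop("expression matrix needs tissue labels as colnames", call. = FALSE)
  }
  if (any(m < 0, na.rm = TRUE)) {
    stop("FPKM values must be non-negative", call. = FALSE)
  }
  invisible(m)
}

#' Read an FPKM matrix from TSV (first column = gene id)
#' @param path file path
#' @return numeric matrix, genes x tissues
#' @export
read_fpkm_matrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab[[1]]
  validate_expression_matrix(m)
  m
}

#' Genes expressed across all tissues
#'
#' Genes with FPKM strictly greater than `threshold` in every tissue
#' (the FPKM > 1 detection rule). Monotone non-increasing in `threshold`.
#'
#' @param m expression matrix (genes x tissues)
#' @param threshold FPKM detection threshold (default 1.0, strict)
#' @return character vector of gene ids
#' @export
expressed_across_all <- function(m, threshold = 1.0) {
  validate_expression_matrix(m)
  if (ncol(m) < 1) stop("need at least one tissue column", call. = FALSE)
  rownames(m)[apply(m > threshold, 1L, all)]
}

#' Fraction of genes not detected in any tissue
#'
#' Genes with FPKM at or below `threshold` in every tissue.
#'
#' @inheritParams expressed_across_all
#' @return fraction in `[0, 1]`
#' @export
fraction_not_detected <- function(m, threshold = 1.0) {
  validate_expression_matrix(m)
  if (!nrow(m)) return(NA_real_)
  mean(apply(m <= threshold, 1L, all))
}

#' Spearman rank correlation
#'
#' Average ranks for ties, then the Pearson correlation of the ranks.
#' Invariant under any strictly monotone transform (e.g. log10) of either
#' argument.
#'
#' @param x,y paired numeric vectors, length >= 3, neither constant
#' @return list with `r_s` and `n`
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  list(r_s = cor(rx, ry), n = length(x))
}

#' Tissue-by-tissue Spearman correlation matrix
#'
#' Symmetric with unit diagonal; computed over genes.
#'
#' @param m expression matrix (genes x tissues)
#' @return tissues x tissues correlation matrix
#' @export
tissue_correlation_matrix <- function(m) {
  validate_expression_matrix(m)
  r <- cor(apply(m, 2L, rank, ties.method = "average"))
  diag(r) <- 1
  r
}

#' Spearman correlations between lncRNAs and their host genes
#'
#' One result per (lnc, gene) pair over the shared tissue columns; pairs
#' with a missing member (or an undefined correlation) are reported as
#' skipped, not dropped silently.
#'
#' @param m expression matrix (genes x tissues) containing both members of
#'   each pair
#' @param pairs data.frame with columns `lnc_id`, `gene_id`
#' @return list with `correlations` (data.frame: lnc_id, gene_id, r_s, n)
#'   and `skipped` (data.frame: lnc_id, gene_id, reason)
#' @export
host_lnc_correlations <- function(m, pairs) {
  validate_expression_matrix(m)
  res <- list(); skip <- list()
  for (k in seq_len(nrow(pairs))) {
    lnc <- pairs$lnc_id[k]; gene <- pairs$gene_id[k]
    if (!lnc %in% rownames(m) || !gene %in% rownames(m)) {
      skip[[length(skip) + 1L]] <- data.frame(
        lnc_id = lnc, gene_id = gene, reason = "missing from matrix")
      next
    }
    r <- tryCatch(spearman_correlation(m[lnc, ], m[gene, ]),
                  error = function(e) NULL)
    if (is.null(r)) {
      skip[[length(skip) + 1L]] <- data.frame(
        lnc_id = lnc, gene_id = gene, reason = "correlation undefined")
      next
    }
    res[[length(res) + 1L]] <- data.frame(lnc_id = lnc, gene_id = gene,
                                          r_s = r$r_s, n = r$n)
  }
  empty_c <- data.frame(lnc_id = character(0), gene_id = character(0),
                        r_s = numeric(0), n = integer(0))
  empty_s <- data.frame(lnc_id = character(0), gene_id = character(0),
                        reason = character(0))
  list(correlations = if (length(res)) do.call(rbind, res) else empty_c,
       skipped = if (length(skip)) do.call(rbind, skip) else empty_s)
}
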