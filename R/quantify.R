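#' Transcripts per million from raw counts
#'
#' Length-normalizes a raw count matrix to TPM: per sample,
#' \eqn{TPM_i = 10^6 (c_i/\ell_i) / \sum_j (c_j/\ell_j)} where \eqn{\ell_i}
#' is the effective length of feature \eqn{i} in bp. Every column of the
#' result sums to 1e6, so TPM values are comparable across libraries of
#' different depth.
#'
#' @param counts numeric matrix, features x samples, non-negative; rownames
#'   are feature ids.
#' @param lengths numeric vector of effective lengths (bp), one per feature,
#'   positive. Recycled by name if named, else by position.
#' @return matrix of TPM values with the same dimnames as `counts`.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    if (!all(rownames(counts) %in% names(lengths)))
      stop("lengths missing for some features")
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    stop("lengths must have one entry per feature")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("effective lengths must be positive and finite")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(rate, 2, tot, "/") * 1e6
}

#' Sum isoform-level expression to gene level
#'
#' Collapses an expression matrix (typically TPM) to gene level by summing
#' the member isoforms of each gene, e.g. the multiple zinc-finger isoforms
#' of *broad*. Column sums are preserved because the annotation partitions
#' the features.
#'
#' @param x numeric matrix, features x samples.
#' @param annotation data.frame with columns `feature_id` and `gene_id`;
#'   every row of `x` must be annotated exactly once.
#' @return matrix with one row per gene, same columns as `x`.
#' @export
sum_isoforms <- function(x, annotation) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("x must have feature ids as rownames")
  if (!all(c("feature_id", "gene_id") %in% names(annotation)))
    stop("annotation needs columns feature_id and gene_id")
  if (anyDuplicated(annotation$feature_id))
    stop("duplicate feature ids in annotation")
  miss <- setdiff(rownames(x), annotation$feature_id)
  if (length(miss))
    stop("unannotated feature(s): ", paste(utils::head(miss, 5), collapse = ", "))
  gene <- annotation$gene_id[match(rownames(x), annotation$feature_id)]
  out <- rowsum(x, group = gene, reorder = TRUE)
  out[unique(sort(gene)), , drop = FALSE]
}

#' Log2 fold change between two sample groups
#'
#' `log2((mean_A + pseudocount) / (mean_B + pseudocount))` per feature.
#' The pseudocount stabilizes display values near zero; screening criteria
#' elsewhere in the package use raw TPM because their thresholds are absolute.
#'
#' @param x numeric matrix, features x samples (counts or TPM).
#' @param group_a,group_b character vectors of column names (or integer
#'   indices); disjoint, non-empty.
#' @param pseudocount value added to both group means (default 0.1 TPM).
#' @return named numeric vector of log2 fold changes (A over B).
#' @export
log2fc <- function(x, group_a, group_b, pseudocount = 0.1) {
  x <- as.matrix(x)
  ia <- if (is.character(group_a)) match(group_a, colnames(x)) else group_a
  ib <- if (is.character(group_b)) match(group_b, colnames(x)) else group_b
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id in group")
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  ma <- rowMeans(x[, ia, drop = FALSE])
  mb <- rowMeans(x[, ib, drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}
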