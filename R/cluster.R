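#' Distance matrix between expression profiles
#'
#' Euclidean distance or correlation distance (1 - Pearson r) between the
#' rows of a profile matrix (typically log2 fold changes).
#'
#' @param x numeric matrix, items x variables; no missing values.
#' @param metric `"euclidean"` or `"correlation"`.
#' @return `dist` object.
#' @export
profile_distance <- function(x, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (anyNA(x)) stop("profiles contain missing values; impute upstream")
  if (metric == "euclidean") return(stats::dist(x))
  if (any(apply(x, 1, stats::sd) == 0))
    stop("constant profile(s): correlation distance undefined")
  stats::as.dist(1 - stats::cor(t(x)))
}

#' Agglomerative hierarchical clustering of profiles
#'
#' Thin wrapper over [stats::hclust()] with the linkage vocabulary used for
#' expression heatmaps (`ward` maps to `ward.D2`).
#'
#' @param d `dist` object (e.g. from [profile_distance()]), >= 2 items.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @return an `hclust` tree.
#' @export
cluster_profiles <- function(d, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distances")
  if (attr(d, "Size") < 2) stop("need at least 2 items")
  stats::hclust(d, method = c(average = "average", complete = "complete",
                              ward = "ward.D2")[[linkage]])
}

#' Export a clustered heatmap and its ordered matrix
#'
#' Writes the matrix reordered by the row/column dendrograms as TSV (the
#' numeric artifact) and optionally draws a heatmap with a diverging
#' magenta/green palette centered at 0 (magenta = high, green = low, the
#' convention for log2 fold-change displays here).
#'
#' @param x numeric matrix.
#' @param row_clust,col_clust optional `hclust` objects whose labels match
#'   the dimnames of `x`; unclustered axes keep their input order.
#' @param tsv optional path for the ordered TSV.
#' @param image optional path for a PNG heatmap (via pheatmap).
#' @return the reordered matrix, invisibly.
#' @export
heatmap_export <- function(x, row_clust = NULL, col_clust = NULL,
                           tsv = NULL, image = NULL) {
  x <- as.matrix(x)
  ord <- function(cl, labs, axis) {
    if (is.null(cl)) return(seq_along(labs))
    if (!setequal(cl$labels, labs))
      stop("dendrogram labels do not match matrix ", axis, " names")
    match(cl$labels[cl$order], labs)
  }
  xo <- x[ord(row_clust, rownames(x), "row"),
          ord(col_clust, colnames(x), "column"), drop = FALSE]
  if (!is.null(tsv)) {
    df <- data.frame(feature_id = rownames(xo), xo, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(image)) {
    lim <- max(abs(x), 1e-9)
    pheatmap::pheatmap(
      x,
      cluster_rows = if (is.null(row_clust)) FALSE else row_clust,
      cluster_cols = if (is.null(col_clust)) FALSE else col_clust,
      color = grDevices::colorRampPalette(
        c("green3", "black", "magenta"))(101),
      breaks = seq(-lim, lim, length.out = 102),
      filename = image, silent = TRUE)
  }
  invisible(xo)
}

#' Log2 fold-change profile matrix for RNAi heatmaps
#'
#' One column per RNAi pair, `log2((RNAi TPM + pc)/(control TPM + pc))`,
#' plus a final `adult_vs_nymph` column contrasting the untreated adult and
#' final-instar abdominal-epidermis means — the display matrix behind the
#' NES/AES clustering heatmaps.
#'
#' @param tpm features x samples TPM matrix.
#' @param design sample table.
#' @param features optional subset of feature ids (e.g. the NES set).
#' @param pseudocount added inside the ratio (default 0.1 TPM).
#' @return numeric matrix, features x (pairs + 1).
#' @export
build_fc_matrix <- function(tpm, design, features = NULL, pseudocount = 0.1) {
  tpm <- as.matrix(tpm)
  if (is.null(features)) features <- rownames(tpm)
  pairs <- pair_samples(design)
  cols <- list()
  for (i in seq_len(nrow(pairs))) {
    cols[[paste0(pairs$target[i], ".", pairs$individual[i])]] <-
      log2((tpm[features, pairs$rnai_id[i]] + pseudocount) /
           (tpm[features, pairs$control_id[i]] + pseudocount))
  }
  ny <- design$sample_id[untreated(design) & design$stage_class == "final" &
                         design$region == "abdomen"]
  ad <- design$sample_id[untreated(design) & design$stage_class == "adult" &
                         design$region == "abdomen"]
  if (length(ny) && length(ad))
    cols[["adult_vs_nymph"]] <- log2fc(tpm[features, , drop = FALSE],
                                       ad, ny, pseudocount)
  do.call(cbind, cols)
}
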