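# TSV dialect: tab-separated, UTF-8, header row required, explicit "NA"
# tokens; feature ids must match ^[A-Za-z0-9_.-]+$.

check_feature_ids <- function(ids) {
  bad <- ids[!grepl("^[A-Za-z0-9_.-]+$", ids)]
  if (length(bad))
    stop("invalid feature id(s): ", paste(utils::head(bad, 5), collapse = ", "))
  if (anyDuplicated(ids)) stop("duplicate feature ids")
  invisible(ids)
}

#' Write a count matrix with effective lengths as TSV
#'
#' Layout: `feature_id`, `length` (effective length, bp), then one column per
#' sample.
#'
#' @param counts features x samples matrix.
#' @param lengths named effective lengths (bp).
#' @param path output file.
#' @export
write_counts_tsv <- function(counts, lengths, path) {
  check_feature_ids(rownames(counts))
  df <- data.frame(feature_id = rownames(counts),
                   length = lengths[rownames(counts)],
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV written by [write_counts_tsv()]
#'
#' @param path input file.
#' @return list with `counts` (integer matrix) and `lengths` (named vector).
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || names(df)[1] != "feature_id" || names(df)[2] != "length")
    stop("malformed counts TSV (expect feature_id, length, samples...): ",
         path)
  check_feature_ids(df$feature_id)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$feature_id
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and complete")
  lengths <- stats::setNames(df$length, df$feature_id)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("effective lengths must be positive")
  list(counts = counts, lengths = lengths)
}

#' Write / read a sample design table
#'
#' @param design design data.frame.
#' @param path file path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "stage_class", "region", "individual",
            "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design TSV missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Check that a count matrix and a design table describe the same samples
#'
#' @param counts features x samples matrix.
#' @param design design table.
#' @return invisibly TRUE; errors name the offending samples.
#' @export
validate_counts_design <- function(counts, design) {
  extra <- setdiff(colnames(counts), design$sample_id)
  if (length(extra))
    stop("sample(s) in matrix but not in design: ",
         paste(extra, collapse = ", "))
  missing_s <- setdiff(design$sample_id, colnames(counts))
  if (length(missing_s))
    stop("sample(s) in design but not in matrix: ",
         paste(missing_s, collapse = ", "))
  invisible(TRUE)
}

#' Read a feature annotation table (isoform -> gene, optional domain)
#'
#' @param path TSV with columns feature_id, gene_id, optionally domain.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "gene_id") %in% names(df)))
    stop("annotation TSV needs feature_id and gene_id columns")
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature ids in annotation")
  df
}
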