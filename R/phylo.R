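#' Read an aligned amino-acid FASTA
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return named character vector of aligned sequences (upper case).
#' @export
read_domain_alignment <- function(path) {
  x <- ape::read.FASTA(path, type = "AA")
  m <- toupper(vapply(as.character(x), paste, character(1), collapse = ""))
  if (length(unique(nchar(m))) != 1)
    stop("sequences are not aligned (unequal lengths)")
  m
}

# named character vector / matrix -> character matrix (seqs x sites)
aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is.null(names(aln))) stop("alignment must be named")
  if (length(unique(nchar(aln))) != 1) stop("unequal alignment lengths")
  m <- t(vapply(aln, function(s) strsplit(toupper(s), "")[[1]],
                character(nchar(aln[[1]]))))
  rownames(m) <- names(aln)
  m
}

#' Pairwise p-distance with pairwise gap deletion
#'
#' Proportion of differing sites over the columns where neither sequence has
#' a gap (`-` or `.`), computed per pair. Optional Poisson correction
#' `-log(1 - p)` for multiple hits.
#'
#' @param aln named character vector of aligned sequences, or a character
#'   matrix (sequences x sites).
#' @param correction `"none"` (default) or `"poisson"`.
#' @return `dist` object.
#' @export
pdistance <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("no comparable (non-gap) columns between ", rownames(m)[i],
           " and ", rownames(m)[j])
    p <- mean(m[i, ok] != m[j, ok])
    if (correction == "poisson") {
      if (p >= 1) stop("saturated distance; Poisson correction undefined")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; negative branch lengths are
#' clamped to zero (topology unaffected) and flagged through the
#' `"negative_clamped"` attribute.
#'
#' @param d `dist` object or symmetric matrix, n >= 3, finite.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3) stop("neighbor joining needs >= 3 taxa")
  if (any(!is.finite(dm))) stop("non-finite distances")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- tr$edge.length < 0
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "negative_clamped") <- sum(neg)
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' p-distances for each replicate, and reports the percentage of replicates
#' containing each internal bipartition of the full-data tree. Values below
#' 50% are flagged (the figure convention of printing an asterisk).
#'
#' @param aln alignment as in [pdistance()].
#' @param reps bootstrap replicates (>= 1; default 1000).
#' @param seed integer seed for the resampling.
#' @param correction distance correction, as in [pdistance()].
#' @return list of class `"bootstrap_support"`: `tree` (node labels set to
#'   rounded support), `support` (data.frame node, support, low), `reps`,
#'   `seed`.
#' @export
bootstrap_support <- function(aln, reps = 1000, seed = 1L,
                              correction = "none") {
  if (reps < 1) stop("reps must be >= 1")
  m <- aln_matrix(aln)
  set.seed(as.integer(seed))
  base <- nj_tree(pdistance(m, correction))
  boots <- vector("list", reps)
  for (b in seq_len(reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    boots[[b]] <- nj_tree(pdistance(m[, cols, drop = FALSE], correction))
  }
  cnt <- ape::prop.clades(base, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  sup <- 100 * cnt / reps
  base$node.label <- as.character(round(sup))
  out <- list(tree = base,
              support = data.frame(node = seq_along(sup) + ape::Ntip(base),
                                   support = sup, low = sup < 50),
              reps = reps, seed = as.integer(seed))
  class(out) <- "bootstrap_support"
  out
}

# does the unrooted tree contain a bipartition separating exactly `tips`?
has_split <- function(tree, tips) {
  labs <- tree$tip.label
  k <- length(tips)
  if (!all(tips %in% labs)) stop("unknown tip(s)")
  if (k == 0) return(FALSE)
  if (k == 1 || k >= length(labs) - 1) return(TRUE)
  parts <- ape::prop.part(tree)
  for (p in parts) {
    side <- labs[p]
    if (setequal(side, tips) || setequal(setdiff(labs, side), tips))
      return(TRUE)
  }
  FALSE
}

#' Assign query leaves to reference clades
#'
#' A query is assigned to a reference clade when, after pruning all other
#' queries, the clade's reference leaves plus the query form a bipartition of
#' the tree while the references alone no longer do — i.e. the query attaches
#' strictly inside the clade. A query sitting at the clade's stem (sister to
#' all of it) or outside every clade is unassigned (NA). Reference clades
#' that are not monophyletic among the references alone are reported as
#' unresolvable.
#'
#' @param tree `phylo` tree containing all reference and query leaves.
#' @param clades named list: clade label -> character vector of reference
#'   leaf ids (>= 1 each).
#' @return named character vector query id -> clade label (NA = unassigned);
#'   attribute `"unresolvable"` lists non-monophyletic reference clades.
#' @export
assign_clade <- function(tree, clades) {
  refs <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(refs)) stop("a leaf appears in more than one clade")
  if (!all(refs %in% tree$tip.label)) stop("reference leaf missing from tree")
  queries <- setdiff(tree$tip.label, refs)
  ref_tree <- ape::keep.tip(tree, refs)
  resolvable <- vapply(clades, function(cl) has_split(ref_tree, cl),
                       logical(1))
  out <- setNames(rep(NA_character_, length(queries)), queries)
  for (q in queries) {
    tq <- ape::keep.tip(tree, c(refs, q))
    hits <- names(clades)[resolvable & vapply(clades, function(cl)
      has_split(tq, c(cl, q)) &&
        (length(cl) == 1 || !has_split(tq, cl)), logical(1))]
    if (length(hits) == 1) out[q] <- hits
  }
  attr(out, "unresolvable") <- names(clades)[!resolvable]
  out
}

#' Write a tree with support labels as Newick
#'
#' @param x a `phylo` tree or a [bootstrap_support()] result.
#' @param path output file.
#' @export
write_newick <- function(x, path) {
  tr <- if (inherits(x, "bootstrap_support")) x$tree else x
  ape::write.tree(tr, file = path)
  invisible(path)
}
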