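#' Pair RNAi-region and control-region samples within individuals
#'
#' The electroporation RNAi design yields, for each treated individual, one
#' abdominal-epidermis sample from the RNAi region and one from the
#' contralateral control region. This pairs them by (individual, target);
#' individuals missing one member are dropped with a warning.
#'
#' @param design sample table as from [gen_design()].
#' @return data.frame: individual, target, rnai_id, control_id.
#' @export
pair_samples <- function(design) {
  is_r <- startsWith(design$treatment, "rnai:")
  is_c <- startsWith(design$treatment, "control-region:")
  tg <- ifelse(is_r, sub("^rnai:", "", design$treatment),
        ifelse(is_c, sub("^control-region:", "", design$treatment), NA))
  treated <- is_r | is_c
  keys <- unique(paste(design$individual[treated], tg[treated], sep = "\r"))
  rows <- list(); dropped <- character(0)
  for (k in keys) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    ind <- parts[1]; target <- parts[2]
    ri <- design$sample_id[is_r & design$individual == ind & tg == target]
    ci <- design$sample_id[is_c & design$individual == ind & tg == target]
    if (length(ri) > 1)
      stop("individual ", ind, " has ", length(ri),
           " RNAi samples for target ", target)
    if (length(ci) > 1)
      stop("individual ", ind, " has multiple control samples for ", target)
    if (length(ri) == 1 && length(ci) == 1) {
      rows[[k]] <- data.frame(individual = ind, target = target,
                              rnai_id = ri, control_id = ci,
                              stringsAsFactors = FALSE)
    } else dropped <- c(dropped, ind)
  }
  if (length(dropped))
    warning("unpaired individual(s) excluded: ",
            paste(unique(dropped), collapse = ", "))
  if (!length(rows))
    return(data.frame(individual = character(), target = character(),
                      rnai_id = character(), control_id = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the response of each feature to each RNAi target
#'
#' Implements the paper-style two-part rule per feature and target:
#' direction `up` requires the ratio of average expression
#' (mean over RNAi-region samples / mean over control-region samples, the
#' default `ratio = "mean_of_means"`) above `fold_threshold` AND every
#' individual's own RNAi/control ratio above 1 (same tendency in all
#' individuals); `down` requires the mean ratio below `down_threshold`
#' (default 2/3) and unanimity below 1. Anything else is `none`. Pairs where
#' both members are 0 are dropped from the unanimity check; a zero control
#' mean with expressed RNAi regions gives an infinite ratio (direction up
#' when unanimous). A two-sided paired t-test on the pair values is reported
#' alongside (the classification itself never uses p-values).
#'
#' @param tpm features x samples TPM matrix.
#' @param pairs pairing table from [pair_samples()]; >= 2 pairs per target.
#' @param fold_threshold up-regulation threshold on the mean ratio.
#' @param down_threshold down-regulation threshold (default `2/3`).
#' @param ratio `"mean_of_means"` (ratio of group averages, default) or
#'   `"mean_of_ratios"`.
#' @return data.frame of class `"rnai_effect"`: feature_id, target,
#'   mean_ratio, unanimous, direction, n_pairs, paired_t, paired_t_p.
#' @export
classify_effect <- function(tpm, pairs, fold_threshold = 1.5,
                            down_threshold = 2 / 3,
                            ratio = c("mean_of_means", "mean_of_ratios")) {
  ratio <- match.arg(ratio)
  tpm <- as.matrix(tpm)
  stopifnot(all(c("target", "rnai_id", "control_id") %in% names(pairs)))
  res <- list()
  for (target in unique(pairs$target)) {
    pp <- pairs[pairs$target == target, , drop = FALSE]
    if (nrow(pp) < 2) stop("need >= 2 pairs per target (", target, ")")
    r <- tpm[, pp$rnai_id, drop = FALSE]
    cc <- tpm[, pp$control_id, drop = FALSE]
    pr <- r / cc                                  # per-individual ratios
    both0 <- r == 0 & cc == 0
    mr <- if (ratio == "mean_of_means") rowMeans(r) / rowMeans(cc)
          else rowMeans(ifelse(both0, NA, pr), na.rm = TRUE)
    mr[rowMeans(cc) == 0 & rowMeans(r) > 0] <- Inf
    mr[rowMeans(cc) == 0 & rowMeans(r) == 0] <- NaN
    up_all <- rowSums(!both0 & !(pr > 1), na.rm = TRUE) == 0 &
              rowSums(!both0) > 0
    dn_all <- rowSums(!both0 & !(pr < 1), na.rm = TRUE) == 0 &
              rowSums(!both0) > 0
    up <- !is.nan(mr) & mr > fold_threshold & up_all
    dn <- !is.nan(mr) & mr < down_threshold & dn_all
    tt <- t(vapply(seq_len(nrow(tpm)), function(i) {
      pt <- paired_t(r[i, ], cc[i, ])
      c(pt$statistic, pt$p_value)
    }, numeric(2)))
    res[[target]] <- data.frame(
      feature_id = if (is.null(rownames(tpm)))
        as.character(seq_len(nrow(tpm))) else rownames(tpm),
      target = target, mean_ratio = mr,
      unanimous = up_all | dn_all,
      direction = ifelse(up, "up", ifelse(dn, "down", "none")),
      n_pairs = nrow(pp),
      paired_t = tt[, 1], paired_t_p = tt[, 2],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("rnai_effect", "data.frame")
  out
}

#' Paired t-test
#'
#' One-sample t on the differences `x - y` against 0, two-sided p from the t
#' distribution with n-1 degrees of freedom. All differences 0 gives
#' t = 0, p = 1; zero variance with a nonzero mean difference gives
#' t = +-Inf, p = 0 with `degenerate = TRUE`.
#'
#' @param x,y paired observations, equal length >= 2.
#' @return list: statistic, p_value, df, degenerate.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(statistic = 0, p_value = 1, df = n - 1,
                            degenerate = FALSE))
    return(list(statistic = sign(m) * Inf, p_value = 0, df = n - 1,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), n - 1), df = n - 1,
       degenerate = FALSE)
}

#' Student's two-sample t-test (pooled variance)
#'
#' Classical equal-variance two-sample t, two-sided. Zero pooled variance
#' with equal means gives t = 0, p = 1; with unequal means it is an error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list: statistic, p_value, df.
#' @export
student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  df <- na + nb - 2
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p_value = 1, df = df))
    stop("zero pooled variance with unequal means")
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
}

#' Venn regulatory partition of features by RNAi response
#'
#' Assigns every feature the subset of RNAi targets that affected it
#' (direction not `none` in [classify_effect()] output); the empty subset is
#' `"unaffected"`. Per-target directions are retained, and when the expected
#' direction pattern of the feature class is supplied (NES: down under
#' Kr-h1/broad, up under E93; AES mirrored), a concordance flag is added.
#'
#' @param effects long table from [classify_effect()]; all `targets` must be
#'   present.
#' @param targets the three RNAi targets.
#' @param expected optional named character vector of expected directions per
#'   target (see [grn_spec()] wiring), e.g. from the planted class.
#' @return data.frame of class `"venn_partition"`: feature_id, subset, one
#'   `dir_<target>` column per target (and `concordant` when `expected`
#'   given).
#' @export
venn_partition <- function(effects, targets = c("Kr-h1", "broad", "E93"),
                           expected = NULL) {
  missing_t <- setdiff(targets, unique(effects$target))
  if (length(missing_t))
    stop("effects missing for target(s): ", paste(missing_t, collapse = ", "))
  ids <- unique(effects$feature_id)
  dm <- matrix("none", length(ids), length(targets),
               dimnames = list(ids, targets))
  for (tg in targets) {
    e <- effects[effects$target == tg, ]
    dm[e$feature_id, tg] <- e$direction
  }
  subset <- apply(dm, 1, function(d) subset_key(targets[d != "none"], targets))
  out <- data.frame(feature_id = ids, subset = unname(subset),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (tg in targets) out[[paste0("dir_", tg)]] <- unname(dm[, tg])
  if (!is.null(expected)) {
    conc <- rep(TRUE, length(ids))
    for (tg in targets)
      conc <- conc & (dm[, tg] == "none" | dm[, tg] == expected[[tg]])
    out$concordant <- unname(conc)
  }
  class(out) <- c("venn_partition", "data.frame")
  out
}

#' Build a Venn partition from printed region counts
#'
#' Convenience constructor for summary arithmetic on published Venn-diagram
#' counts: a named vector of subset sizes (names are [subset_key()] strings,
#' plus `"unaffected"`) is expanded into a partition with placeholder ids.
#'
#' @param counts named non-negative integer vector.
#' @param targets the three RNAi targets.
#' @return `"venn_partition"` data.frame.
#' @export
as_venn_partition <- function(counts, targets = c("Kr-h1", "broad", "E93")) {
  valid <- c(unlist(lapply(seq_along(targets), function(k)
    vapply(utils::combn(targets, k, simplify = FALSE), subset_key,
           character(1), all_targets = targets))), "unaffected")
  bad <- setdiff(names(counts), valid)
  if (is.null(names(counts)) || length(bad))
    stop("counts must be named by canonical subset keys; offending: ",
         paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative subset count")
  out <- data.frame(
    feature_id = paste0("f", seq_len(sum(counts))),
    subset = rep(names(counts), counts),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("venn_partition", "data.frame")
  out
}

#' Summary statistics of a Venn regulatory partition
#'
#' Counts features per Venn region (seven non-empty subsets of
#' \{Kr-h1, broad, E93\} plus `unaffected`) and derives the totals discussed
#' for the NES/AES sets: `broad_involved` (features in any subset containing
#' broad), `non_broad_affected` (affected features in subsets without broad),
#' `affected` and the affected percentage.
#'
#' @param partition a `"venn_partition"`.
#' @param targets the three RNAi targets.
#' @return list of class `"venn_summary"`: `region_counts` (named, 8
#'   regions), `n`, `affected`, `broad_involved`, `non_broad_affected`,
#'   `affected_pct`.
#' @export
venn_summary <- function(partition, targets = c("Kr-h1", "broad", "E93")) {
  keys <- c(unlist(lapply(seq_along(targets), function(k)
    vapply(utils::combn(targets, k, simplify = FALSE), subset_key,
           character(1), all_targets = targets))), "unaffected")
  counts <- setNames(integer(length(keys)), keys)
  tb <- table(partition$subset)
  counts[names(tb)] <- as.integer(tb)
  n <- sum(counts)
  has_broad <- vapply(names(counts), function(k)
    "broad" %in% strsplit(k, "+", fixed = TRUE)[[1]], logical(1))
  affected <- n - counts[["unaffected"]]
  out <- list(region_counts = counts, n = n, affected = affected,
              broad_involved = sum(counts[has_broad &
                                          names(counts) != "unaffected"]),
              non_broad_affected = sum(counts[!has_broad &
                                              names(counts) != "unaffected"]),
              affected_pct = if (n > 0) 100 * affected / n else NA_real_)
  class(out) <- "venn_summary"
  out
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("Venn partition of", x$n, "features\n")
  print(x$region_counts)
  cat(sprintf("affected: %d (%.1f%%); broad-involved: %d; affected without broad: %d\n",
              x$affected, x$affected_pct, x$broad_involved,
              x$non_broad_affected))
  invisible(x)
}
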