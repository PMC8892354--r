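#' Screening configuration
#'
#' Thresholds of the two screening procedures. The stage screen combines a
#' differential-expression gate (NB exact test, FDR below `fdr_threshold`)
#' with three absolute TPM criteria: (1) minimum TPM of the high group at
#' least `tpm_floor_high`; (2) maximum TPM of the low group strictly below
#' `tpm_ceiling_low`; (3) min(high)/max(low) at least `ratio_min`
#' (non-strict, "is 1.5 times higher"). The epidermis screen uses the DE gate
#' plus only the ratio criterion, strict ("more than 1.5 times higher").
#' Criteria are evaluated on individual sample TPMs by default
#' (`extremes = "sample"`); `"mean"` applies them to group means instead.
#'
#' @param fdr_threshold BH-FDR cut-off for the DE gate.
#' @param tpm_floor_high,tpm_ceiling_low,ratio_min TPM criteria thresholds.
#' @param stage_ratio_strict,epi_ratio_strict strictness of the ratio
#'   comparison in each screen.
#' @param extremes `"sample"` or `"mean"`.
#' @param region_pairs named list mapping each required region to
#'   `c(nymph_region, adult_region)`; wing buds pair with adult wings.
#' @return list of class `"screen_config"`.
#' @export
screen_config <- function(fdr_threshold = 0.01, tpm_floor_high = 2,
                          tpm_ceiling_low = 2, ratio_min = 1.5,
                          stage_ratio_strict = FALSE, epi_ratio_strict = TRUE,
                          extremes = c("sample", "mean"),
                          region_pairs = list(
                            head = c("head", "head"),
                            thorax = c("thorax", "thorax"),
                            abdomen = c("abdomen", "abdomen"),
                            wings = c("wing_buds", "wings"))) {
  stopifnot(fdr_threshold > 0, tpm_floor_high > 0, tpm_ceiling_low > 0,
            ratio_min > 1)
  structure(list(fdr_threshold = fdr_threshold,
                 tpm_floor_high = tpm_floor_high,
                 tpm_ceiling_low = tpm_ceiling_low,
                 ratio_min = ratio_min,
                 stage_ratio_strict = isTRUE(stage_ratio_strict),
                 epi_ratio_strict = isTRUE(epi_ratio_strict),
                 extremes = match.arg(extremes),
                 region_pairs = region_pairs),
            class = "screen_config")
}

#' Evaluate the three TPM screening criteria
#'
#' For each feature: c1 — minimum TPM over the high group is at least
#' `tpm_floor_high`; c2 — maximum TPM over the low group is strictly below
#' `tpm_ceiling_low`; c3 — min(high)/max(low) reaches `ratio_min`
#' (strict or non-strict per `strict`; if max(low) is 0, c3 is TRUE whenever
#' min(high) > 0).
#'
#' @param tpm features x samples TPM matrix.
#' @param high_group,low_group column ids/indices; non-empty, disjoint.
#' @param config a [screen_config()].
#' @param strict strict ratio comparison? Defaults to the stage-screen rule.
#' @return data.frame: feature_id, c1, c2, c3, ratio.
#' @export
apply_tpm_criteria <- function(tpm, high_group, low_group,
                               config = screen_config(),
                               strict = config$stage_ratio_strict) {
  tpm <- as.matrix(tpm)
  ih <- if (is.character(high_group)) match(high_group, colnames(tpm)) else high_group
  il <- if (is.character(low_group)) match(low_group, colnames(tpm)) else low_group
  if (anyNA(ih) || anyNA(il)) stop("unknown sample id in group")
  if (!length(ih) || !length(il)) stop("both groups must be non-empty")
  if (length(intersect(ih, il))) stop("groups must be disjoint")
  hi <- tpm[, ih, drop = FALSE]; lo <- tpm[, il, drop = FALSE]
  if (config$extremes == "mean") {
    mn_hi <- rowMeans(hi); mx_lo <- rowMeans(lo)
  } else {
    mn_hi <- apply(hi, 1, min); mx_lo <- apply(lo, 1, max)
  }
  c1 <- mn_hi >= config$tpm_floor_high
  c2 <- mx_lo < config$tpm_ceiling_low
  ratio <- ifelse(mx_lo > 0, mn_hi / mx_lo, ifelse(mn_hi > 0, Inf, 0))
  c3 <- if (strict) ratio > config$ratio_min else ratio >= config$ratio_min
  data.frame(feature_id = if (is.null(rownames(tpm)))
               as.character(seq_len(nrow(tpm))) else rownames(tpm),
             c1 = c1, c2 = c2, c3 = c3, ratio = ratio,
             row.names = NULL, stringsAsFactors = FALSE)
}

untreated <- function(design) design$treatment == "untreated"

#' Four-region stage-specificity screen
#'
#' Reproduces the screen for nymph-specific and adult-specific genes:
#' in each required body region, penultimate-instar nymph samples are
#' compared against adult samples with (i) the NB exact-test gate at
#' FDR < `fdr_threshold` and (ii) the three TPM criteria; a feature is called
#' nymph-specific (adult-specific) only if the gate and all criteria hold in
#' **every** required region with the same direction. Direction conflicts
#' yield the label `none`, not an error.
#'
#' @param counts features x samples count matrix (may be NULL when `tpm` is
#'   supplied and `de_gate = FALSE`).
#' @param lengths effective lengths for [compute_tpm()] (ignored when `tpm`
#'   is supplied).
#' @param design sample table as from [gen_design()].
#' @param config a [screen_config()].
#' @param tpm optional precomputed TPM matrix.
#' @param de_gate apply the differential-expression gate? (Disable for
#'   noise-free criteria fixtures.)
#' @return data.frame of class `"specificity_call"`: feature_id, label, and
#'   per-region columns `de_<r>`, `c1_<r>`, `c2_<r>`, `c3_<r>`, `dir_<r>`.
#'   Criteria flags are reported in the orientation of the region's call, or
#'   nymph-high orientation when the region makes no call.
#' @export
screen_stage_specific <- function(counts = NULL, lengths = NULL, design,
                                  config = screen_config(), tpm = NULL,
                                  de_gate = TRUE) {
  if (is.null(tpm)) {
    if (is.null(counts) || is.null(lengths))
      stop("provide counts + lengths, or a tpm matrix")
    tpm <- compute_tpm(counts, lengths)
  }
  if (de_gate && is.null(counts)) stop("the DE gate requires counts")
  nf <- nrow(tpm)
  ids <- rownames(tpm)
  out <- data.frame(feature_id = ids, label = rep("none", nf),
                    row.names = NULL, stringsAsFactors = FALSE)
  dir_mat <- matrix("none", nf, length(config$region_pairs),
                    dimnames = list(NULL, names(config$region_pairs)))
  ok_mat <- matrix(FALSE, nf, length(config$region_pairs))
  for (k in seq_along(config$region_pairs)) {
    r <- names(config$region_pairs)[k]
    pr <- config$region_pairs[[k]]
    a <- design$sample_id[untreated(design) &
                          design$stage_class == "penultimate" &
                          design$region == pr[1]]
    b <- design$sample_id[untreated(design) & design$stage_class == "adult" &
                          design$region == pr[2]]
    if (!length(a) || !length(b))
      stop("missing samples for region pair ", r)
    if (de_gate) {
      de <- run_de(counts[, c(a, b), drop = FALSE],
                   groups = rep(c("nymph", "adult"), c(length(a), length(b))),
                   contrast = c("nymph", "adult"))
      gate <- de$fdr < config$fdr_threshold
    } else gate <- rep(TRUE, nf)
    fn <- apply_tpm_criteria(tpm, a, b, config)   # nymph-high orientation
    fa <- apply_tpm_criteria(tpm, b, a, config)   # adult-high orientation
    pass_n <- gate & fn$c1 & fn$c2 & fn$c3
    pass_a <- gate & fa$c1 & fa$c2 & fa$c3
    dirs <- ifelse(pass_n, "nymph", ifelse(pass_a, "adult", "none"))
    dir_mat[, k] <- dirs
    ok_mat[, k] <- dirs != "none"
    flags <- fn
    flags[dirs == "adult", c("c1", "c2", "c3", "ratio")] <-
      fa[dirs == "adult", c("c1", "c2", "c3", "ratio")]
    out[[paste0("de_", r)]] <- gate
    out[[paste0("c1_", r)]] <- flags$c1
    out[[paste0("c2_", r)]] <- flags$c2
    out[[paste0("c3_", r)]] <- flags$c3
    out[[paste0("dir_", r)]] <- dirs
  }
  all_n <- rowSums(dir_mat == "nymph") == ncol(dir_mat)
  all_a <- rowSums(dir_mat == "adult") == ncol(dir_mat)
  out$label[all_n] <- "nymph-specific"
  out$label[all_a] <- "adult-specific"
  class(out) <- c("specificity_call", "data.frame")
  out
}

#' Epidermis-specificity screen (NES/AES)
#'
#' Identifies nymphal-epidermis-specific (NES) and adult-epidermis-specific
#' (AES) transcripts from untreated final-instar nymph and adult
#' abdominal-epidermis samples using two criteria: the NB exact-test gate at
#' FDR < `fdr_threshold`, and the strict ratio rule — the minimum TPM of one
#' group more than `ratio_min` times the maximum of the other. Deliberately
#' no absolute-TPM criteria.
#'
#' @inheritParams screen_stage_specific
#' @param nymph_samples,adult_samples explicit sample ids; default to the
#'   untreated final-instar and adult abdomen samples of `design`.
#' @return data.frame of class `"specificity_call"`: feature_id, label
#'   (`NES`/`AES`/`none`), de, ratio_nymph, ratio_adult.
#' @export
screen_epidermis_specific <- function(counts = NULL, lengths = NULL, design,
                                      config = screen_config(), tpm = NULL,
                                      de_gate = TRUE,
                                      nymph_samples = NULL,
                                      adult_samples = NULL) {
  if (is.null(tpm)) {
    if (is.null(counts) || is.null(lengths))
      stop("provide counts + lengths, or a tpm matrix")
    tpm <- compute_tpm(counts, lengths)
  }
  if (is.null(nymph_samples))
    nymph_samples <- design$sample_id[untreated(design) &
      design$stage_class == "final" & design$region == "abdomen"]
  if (is.null(adult_samples))
    adult_samples <- design$sample_id[untreated(design) &
      design$stage_class == "adult" & design$region == "abdomen"]
  if (!length(nymph_samples) || !length(adult_samples))
    stop("empty epidermis group")
  if (de_gate) {
    if (is.null(counts)) stop("the DE gate requires counts")
    de <- run_de(counts[, c(nymph_samples, adult_samples), drop = FALSE],
                 groups = rep(c("nymph", "adult"),
                              c(length(nymph_samples), length(adult_samples))),
                 contrast = c("nymph", "adult"))
    gate <- de$fdr < config$fdr_threshold
  } else gate <- rep(TRUE, nrow(tpm))
  fn <- apply_tpm_criteria(tpm, nymph_samples, adult_samples, config,
                           strict = config$epi_ratio_strict)
  fa <- apply_tpm_criteria(tpm, adult_samples, nymph_samples, config,
                           strict = config$epi_ratio_strict)
  label <- ifelse(gate & fn$c3, "NES", ifelse(gate & fa$c3, "AES", "none"))
  out <- data.frame(feature_id = fn$feature_id, label = label,
                    de = gate, ratio_nymph = fn$ratio, ratio_adult = fa$ratio,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("specificity_call", "data.frame")
  out
}
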