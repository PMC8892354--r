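#' Default pipeline configuration
#'
#' All tunables of a full run in one validated list; unknown keys are
#' rejected. `overrides` may be a list or a path to a JSON file with the same
#' structure.
#'
#' @param overrides list or JSON path.
#' @return config list.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    n_features = 2000,
    phi = 0.05,
    seed = 1L,
    fdr_threshold = 0.01,
    tpm_floor_high = 2,
    tpm_ceiling_low = 2,
    ratio_min = 1.5,
    fold_threshold = 1.5,
    down_threshold = 2 / 3,
    cluster_metric = "euclidean",
    cluster_linkage = "average",
    heatmap = FALSE,
    counts_tsv = NULL,
    design_tsv = NULL)
  if (is.character(overrides)) overrides <- jsonlite::read_json(
    overrides, simplifyVector = TRUE)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  cfg
}

log_stage <- function(log, stage, n_in, n_out, params = list()) {
  log[[length(log) + 1L]] <- list(
    stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    n_in = n_in, n_out = n_out, params = params)
  log
}

#' Run the full screening and RNAi-response pipeline
#'
#' Simulates (or reads) a count matrix and design, computes TPM, runs the
#' four-region stage-specificity screen and the epidermis NES/AES screen,
#' classifies the RNAi response of the NES/AES features, builds the Venn
#' partitions and summaries, clusters the log2 fold-change profiles, and
#' writes every stage's output plus a run log into `out_dir`.
#'
#' @param config from [pipeline_config()] (list or JSON path accepted).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with all intermediate results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config) || is.null(config$n_features))
    config <- pipeline_config(config)
  if (missing(out_dir) || !nzchar(out_dir)) stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runlog <- list()

  if (!is.null(config$counts_tsv)) {
    cm <- read_counts_tsv(config$counts_tsv)
    design <- read_design_tsv(config$design_tsv)
    validate_counts_design(cm$counts, design)
    sim <- list(counts = cm$counts, lengths = cm$lengths, design = design,
                truth = NULL)
  } else {
    design <- gen_design(design_spec(seed = config$seed))
    sim <- gen_counts(design, grn_spec(), n_features = config$n_features,
                      phi = config$phi, seed = config$seed)
    write_counts_tsv(sim$counts, sim$lengths, file.path(out_dir, "counts.tsv"))
    write_design_tsv(design, file.path(out_dir, "design.tsv"))
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  runlog <- log_stage(runlog, "simulate", config$n_features,
                      ncol(sim$counts),
                      list(seed = config$seed, phi = config$phi))

  scfg <- screen_config(fdr_threshold = config$fdr_threshold,
                        tpm_floor_high = config$tpm_floor_high,
                        tpm_ceiling_low = config$tpm_ceiling_low,
                        ratio_min = config$ratio_min)
  tpm <- compute_tpm(sim$counts, sim$lengths)
  stage <- screen_stage_specific(sim$counts, sim$lengths, sim$design,
                                 scfg, tpm = tpm)
  utils::write.table(stage, file.path(out_dir, "stage_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  runlog <- log_stage(runlog, "stage_screen", nrow(tpm),
                      sum(stage$label != "none"),
                      list(fdr = config$fdr_threshold,
                           tpm_floor_high = config$tpm_floor_high,
                           tpm_ceiling_low = config$tpm_ceiling_low,
                           ratio_min = config$ratio_min))

  epi <- screen_epidermis_specific(sim$counts, sim$lengths, sim$design,
                                   scfg, tpm = tpm)
  utils::write.table(epi, file.path(out_dir, "epidermis_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  runlog <- log_stage(runlog, "epidermis_screen", nrow(tpm),
                      sum(epi$label != "none"),
                      list(fdr = config$fdr_threshold,
                           ratio_min = config$ratio_min, strict = TRUE))

  pairs <- pair_samples(sim$design)
  nes_ids <- epi$feature_id[epi$label == "NES"]
  aes_ids <- epi$feature_id[epi$label == "AES"]
  result <- list(design = sim$design, truth = sim$truth, tpm = tpm,
                 stage_screen = stage, epidermis_screen = epi, pairs = pairs)
  if (nrow(pairs)) {
    eff <- classify_effect(tpm, pairs,
                           fold_threshold = config$fold_threshold,
                           down_threshold = config$down_threshold)
    utils::write.table(eff, file.path(out_dir, "rnai_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaries <- list()
    for (set in c("NES", "AES")) {
      ids <- if (set == "NES") nes_ids else aes_ids
      if (!length(ids)) next
      part <- venn_partition(eff[eff$feature_id %in% ids, ],
                             expected = expected_direction(set))
      utils::write.table(part,
                         file.path(out_dir, paste0("venn_", set, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      vs <- venn_summary(part)
      summaries[[set]] <- list(
        region_counts = as.list(vs$region_counts), n = vs$n,
        affected = vs$affected, broad_involved = vs$broad_involved,
        non_broad_affected = vs$non_broad_affected,
        affected_pct = vs$affected_pct)
      result[[paste0("venn_", set)]] <- part
      result[[paste0("venn_summary_", set)]] <- vs
    }
    jsonlite::write_json(summaries, file.path(out_dir, "venn_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    result$effects <- eff
    runlog <- log_stage(runlog, "rnai", nrow(pairs),
                        length(nes_ids) + length(aes_ids),
                        list(fold_threshold = config$fold_threshold,
                             down_threshold = config$down_threshold))
  }

  feat <- c(nes_ids, aes_ids)
  if (length(feat) >= 3 && nrow(pairs)) {
    fc <- build_fc_matrix(tpm, sim$design, features = feat)
    hc <- cluster_profiles(profile_distance(fc,
                                            metric = config$cluster_metric),
                           linkage = config$cluster_linkage)
    heatmap_export(fc, row_clust = hc,
                   tsv = file.path(out_dir, "fc_matrix_ordered.tsv"),
                   image = if (isTRUE(config$heatmap))
                     file.path(out_dir, "heatmap.png") else NULL)
    result$fc_matrix <- fc
    result$fc_clustering <- hc
    runlog <- log_stage(runlog, "cluster", length(feat), length(feat),
                        list(metric = config$cluster_metric,
                             linkage = config$cluster_linkage))
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))],
                       cfg_path, auto_unbox = TRUE, digits = NA)
  runlog <- log_stage(runlog, "config",
                      0, 0, list(md5 = unname(tools::md5sum(cfg_path))))
  jsonlite::write_json(runlog, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  result$run_log <- runlog
  invisible(result)
}
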