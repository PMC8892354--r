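#' Specification of the sampling design to simulate
#'
#' Describes the study layout the generator emulates: 13 whole-body
#' developmental stages from egg to seventh instar, 45 nymph samples
#' (9 penultimate/final-instar substages x 5 body regions: head, thorax,
#' abdomen, wing buds, caudal gills), 24 adult samples (6 individuals x
#' 4 regions: head, thorax, abdomen, wings), and paired RNAi/control-region
#' abdominal-epidermis samples for the three metamorphic transcription
#' factors (defaults: Kr-h1 n = 3, broad n = 4, E93 n = 3). The defaults
#' reproduce the 82-sample layout plus 20 paired RNAi samples.
#'
#' @param whole_body_stages ordered stage labels for the whole-body series.
#' @param penultimate_stages,final_stages substage labels of the
#'   penultimate and final nymphal instars (9 in total by default).
#' @param nymph_regions,adult_regions body-region labels.
#' @param adult_individuals number of adult individuals (default 6: immature
#'   and mature males, gynochrome and androchrome females).
#' @param n_rnai_pairs named integer vector: paired RNAi individuals per
#'   target gene.
#' @param library_size_mean,library_size_cv log-normal sequencing depth per
#'   sample (mean reads and coefficient of variation).
#' @param seed integer seed recorded with the design.
#' @return object of class `"design_spec"`.
#' @export
design_spec <- function(whole_body_stages = c(paste0("egg_", 1:6),
                                              paste0("instar_", 1:7)),
                        penultimate_stages = paste0("penult_", 1:4),
                        final_stages = c("final_s1", "final_s2a", "final_s2b",
                                         "final_s2c", "final_s3"),
                        nymph_regions = c("head", "thorax", "abdomen",
                                          "wing_buds", "caudal_gills"),
                        adult_regions = c("head", "thorax", "abdomen", "wings"),
                        adult_individuals = 6,
                        n_rnai_pairs = c("Kr-h1" = 3, "broad" = 4, "E93" = 3),
                        library_size_mean = 2e7,
                        library_size_cv = 0.2,
                        seed = 1L) {
  stopifnot(length(whole_body_stages) >= 1,
            length(penultimate_stages) >= 1, length(final_stages) >= 1,
            length(nymph_regions) >= 1, length(adult_regions) >= 1,
            adult_individuals >= 1,
            library_size_mean > 0, library_size_cv >= 0)
  if (is.null(names(n_rnai_pairs)) || any(!nzchar(names(n_rnai_pairs))))
    stop("n_rnai_pairs must be a named vector (one entry per RNAi target)")
  if (any(n_rnai_pairs < 1)) stop("replicate counts must be >= 1")
  spec <- list(
    whole_body_stages = whole_body_stages,
    penultimate_stages = penultimate_stages,
    final_stages = final_stages,
    nymph_regions = nymph_regions,
    adult_regions = adult_regions,
    adult_individuals = as.integer(adult_individuals),
    n_rnai_pairs = n_rnai_pairs,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    seed = as.integer(seed))
  spec$n_whole_body <- length(whole_body_stages)
  spec$n_nymph_region_samples <-
    (length(penultimate_stages) + length(final_stages)) * length(nymph_regions)
  spec$n_adult_region_samples <- spec$adult_individuals * length(adult_regions)
  class(spec) <- "design_spec"
  spec
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design specification:\n",
      " whole-body samples:  ", x$n_whole_body, "\n",
      " nymph region samples:", x$n_nymph_region_samples, "\n",
      " adult region samples:", x$n_adult_region_samples, "\n",
      " RNAi pairs:          ",
      paste(names(x$n_rnai_pairs), x$n_rnai_pairs, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Expand a design specification into a per-sample table
#'
#' One row per sample with stage, stage class, body region, sex, individual
#' id and treatment (`untreated`, `rnai:<target>` or
#' `control-region:<target>`). RNAi and control-region samples of one
#' individual share the individual id, which drives downstream pairing.
#' Kr-h1 and broad knockdowns are sampled in the final nymphal instar (dsRNA
#' injected in the penultimate instar), E93 knockdowns in adults. The
#' function is deterministic: the same spec always yields the same table.
#'
#' @param spec a [design_spec()].
#' @return data.frame of class `"sample_design"`; the library-size parameters
#'   and seed of `spec` are carried along as attributes.
#' @export
gen_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  rows <- list()
  rows$wb <- data.frame(
    sample_id = paste0("wb_", spec$whole_body_stages),
    stage = spec$whole_body_stages,
    stage_class = ifelse(grepl("^egg", spec$whole_body_stages),
                         "egg", "nymph_whole"),
    region = "whole_body", sex = "mixed",
    individual = paste0("pool_", spec$whole_body_stages),
    treatment = "untreated", stringsAsFactors = FALSE)
  nst <- c(spec$penultimate_stages, spec$final_stages)
  ncl <- rep(c("penultimate", "final"),
             c(length(spec$penultimate_stages), length(spec$final_stages)))
  gr <- expand.grid(region = spec$nymph_regions, stage = nst,
                    stringsAsFactors = FALSE)
  rows$nymph <- data.frame(
    sample_id = paste0("n_", gr$stage, "_", gr$region),
    stage = gr$stage,
    stage_class = ncl[match(gr$stage, nst)],
    region = gr$region, sex = "mixed",
    individual = paste0("nymph_", gr$stage),
    treatment = "untreated", stringsAsFactors = FALSE)
  sexes <- rep(c("male", "gyn_female", "andro_female"),
               length.out = spec$adult_individuals)
  mat <- rep(c("immature", "mature"), length.out = spec$adult_individuals)
  ga <- expand.grid(region = spec$adult_regions,
                    ind = seq_len(spec$adult_individuals),
                    stringsAsFactors = FALSE)
  rows$adult <- data.frame(
    sample_id = paste0("a_", ga$ind, "_", ga$region),
    stage = paste0("adult_", mat[ga$ind]),
    stage_class = "adult",
    region = ga$region, sex = sexes[ga$ind],
    individual = paste0("adult_", ga$ind),
    treatment = "untreated", stringsAsFactors = FALSE)
  rnai_stage <- function(target)
    if (target == "E93") c("adult_rnai", "adult") else c("final_s1", "final")
  rr <- lapply(names(spec$n_rnai_pairs), function(tg) {
    st <- rnai_stage(tg)
    k <- spec$n_rnai_pairs[[tg]]
    data.frame(
      sample_id = c(paste0("r_", tg, "_", seq_len(k)),
                    paste0("c_", tg, "_", seq_len(k))),
      stage = st[1], stage_class = st[2],
      region = "abdomen", sex = "mixed",
      individual = rep(paste0("rnai_", tg, "_", seq_len(k)), 2),
      treatment = rep(c(paste0("rnai:", tg), paste0("control-region:", tg)),
                      each = k),
      stringsAsFactors = FALSE)
  })
  design <- do.call(rbind, c(rows, rr))
  rownames(design) <- NULL
  if (anyDuplicated(design$sample_id)) stop("duplicated sample ids in design")
  attr(design, "library_size_mean") <- spec$library_size_mean
  attr(design, "library_size_cv") <- spec$library_size_cv
  attr(design, "seed") <- spec$seed
  class(design) <- c("sample_design", "data.frame")
  design
}
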