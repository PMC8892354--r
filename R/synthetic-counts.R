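#' Canonical key for a subset of RNAi targets
#'
#' Orders targets as Kr-h1, broad, E93 and joins them with `+`; the empty
#' subset is `"unaffected"`.
#'
#' @param targets character vector of target names (possibly empty).
#' @param all_targets the canonical ordering.
#' @return single string.
#' @export
subset_key <- function(targets, all_targets = c("Kr-h1", "broad", "E93")) {
  targets <- unique(targets)
  bad <- setdiff(targets, all_targets)
  if (length(bad)) stop("unknown target(s): ", paste(bad, collapse = ", "))
  if (!length(targets)) return("unaffected")
  paste(all_targets[all_targets %in% targets], collapse = "+")
}

#' Planted regulatory truth for the synthetic generator
#'
#' Declares what the generator plants: how many nymph-specific and
#' adult-specific features (defaults 8 and 7, the study's headline counts;
#' three of them are the regulators themselves, planted as `N4_Kr-h1`,
#' `N7_broad` and `A3_E93`), how many nymphal- and adult-epidermis-specific
#' (NES/AES) features per Venn subset of \{Kr-h1, broad, E93\}, and the
#' RNAi-effect model. A knocked-down regulator changes a regulated feature by
#' a mosaic linear mixture of affected and unaffected cells:
#' up-effects multiply the baseline by `1 + m*e*(effect_fold - 1)` and
#' down-effects by `1 - m*e*(1 - 1/effect_fold)`, where `e` is the
#' knockdown efficiency and `m` the fraction of cells reached by
#' electroporation. Expected directions encode the regulatory wiring:
#' NES features fall under Kr-h1 or broad RNAi and rise under E93 RNAi;
#' AES features are mirrored. Regulator cross-edges follow
#' Kr-h1 -| E93, Kr-h1 -> broad, E93 -| broad.
#'
#' @param n_nymph_specific,n_adult_specific planted stage-specific features
#'   (>= 2 and >= 1; regulators are placed among them).
#' @param nes_subsets,aes_subsets named integer vectors: number of NES/AES
#'   features planted in each Venn subset (names are [subset_key()] strings).
#' @param effect_fold fold change in fully affected cells (>= 1).
#' @param knockdown_efficiency,mosaic_fraction `e` and `m` in \[0, 1\].
#' @param individual_share fraction of the biological variance (phi) shared
#'   between the two regions of one RNAi individual; the paired design's
#'   reason to exist. In \[0, 1).
#' @param tpm_stage_high,tpm_stage_low planted TPM of stage-specific features
#'   in their high/low stages (defaults 10 and 0.4: 25-fold separation and
#'   safely on either side of the TPM = 2 screening thresholds).
#' @param tpm_epi_high,tpm_epi_low planted TPM of NES/AES features in the
#'   epidermis where they are on/off (defaults 42 and 6; the epidermis screen
#'   has no absolute-TPM criterion, only the strict 1.5x ratio).
#' @param plant_failure_modes also plant one feature per screening-criterion
#'   failure mode (c1, c2, c3)?
#' @return object of class `"grn_spec"`.
#' @export
grn_spec <- function(n_nymph_specific = 8, n_adult_specific = 7,
                     nes_subsets = c("Kr-h1" = 2, "broad" = 2, "E93" = 2,
                                     "Kr-h1+broad" = 3, "Kr-h1+E93" = 3,
                                     "broad+E93" = 2, "Kr-h1+broad+E93" = 3),
                     aes_subsets = c("Kr-h1" = 2, "broad" = 2, "E93" = 2,
                                     "Kr-h1+broad" = 3, "Kr-h1+E93" = 3,
                                     "broad+E93" = 2, "Kr-h1+broad+E93" = 3),
                     effect_fold = 8, knockdown_efficiency = 0.9,
                     mosaic_fraction = 0.8, individual_share = 0.8,
                     tpm_stage_high = 10, tpm_stage_low = 0.4,
                     tpm_epi_high = 42, tpm_epi_low = 6,
                     plant_failure_modes = TRUE) {
  stopifnot(n_nymph_specific >= 2, n_adult_specific >= 1,
            effect_fold >= 1,
            knockdown_efficiency >= 0, knockdown_efficiency <= 1,
            mosaic_fraction >= 0, mosaic_fraction <= 1,
            individual_share >= 0, individual_share < 1,
            tpm_stage_high > tpm_stage_low, tpm_stage_low > 0,
            tpm_epi_high > tpm_epi_low, tpm_epi_low > 0)
  for (v in list(nes_subsets, aes_subsets)) {
    if (length(v) && (is.null(names(v)) ||
        !all(names(v) %in% c("Kr-h1", "broad", "E93", "Kr-h1+broad",
                             "Kr-h1+E93", "broad+E93", "Kr-h1+broad+E93"))))
      stop("subset names must be canonical subset_key() strings")
    if (any(v < 0)) stop("subset counts must be >= 0")
  }
  structure(list(
    targets = c("Kr-h1", "broad", "E93"),
    n_nymph_specific = as.integer(n_nymph_specific),
    n_adult_specific = as.integer(n_adult_specific),
    nes_subsets = nes_subsets, aes_subsets = aes_subsets,
    effect_fold = effect_fold,
    knockdown_efficiency = knockdown_efficiency,
    mosaic_fraction = mosaic_fraction,
    individual_share = individual_share,
    tpm_stage_high = tpm_stage_high, tpm_stage_low = tpm_stage_low,
    tpm_epi_high = tpm_epi_high, tpm_epi_low = tpm_epi_low,
    plant_failure_modes = isTRUE(plant_failure_modes)),
    class = "grn_spec")
}

# Multiplier applied to a regulated feature's mean in an RNAi-region sample.
# sign "+": feature rises when the regulator is depleted; "-": it falls.
# Mixture of affected (fraction m*e) and unaffected cells; never negative.
mosaic_factor <- function(sign, fold, m, e) {
  me <- m * e
  if (sign == "+") 1 + me * (fold - 1) else 1 - me * (1 - 1 / fold)
}

# expected direction of a feature class under RNAi of each target
expected_direction <- function(class) {
  switch(class,
         NES = c("Kr-h1" = "down", "broad" = "down", "E93" = "up"),
         AES = c("Kr-h1" = "up", "broad" = "up", "E93" = "down"),
         stop("no expected directions for class ", class))
}

# Build the planted feature table (ids, classes, Venn subsets, failure modes)
planted_features <- function(grn) {
  ns <- grn$n_nymph_specific; na <- grn$n_adult_specific
  nid <- paste0("N", seq_len(ns))
  kr_pos <- min(4L, ns - 1L); br_pos <- min(7L, ns)
  nid[kr_pos] <- paste0("N", kr_pos, "_Kr-h1")
  nid[br_pos] <- paste0("N", br_pos, "_broad")
  aid <- paste0("A", seq_len(na))
  e_pos <- min(3L, na)
  aid[e_pos] <- paste0("A", e_pos, "_E93")
  reg <- setNames(rep("", ns + na), c(nid, aid))
  reg[nid[kr_pos]] <- "Kr-h1"; reg[nid[br_pos]] <- "broad"
  reg[aid[e_pos]] <- "E93"
  tab <- data.frame(
    feature_id = c(nid, aid),
    class = rep(c("nymph-specific", "adult-specific"), c(ns, na)),
    venn_subset = "unaffected",
    failure_mode = "none",
    regulator = reg[c(nid, aid)],
    stringsAsFactors = FALSE)
  # regulators respond to RNAi (self-knockdown + cross-wiring); they are not
  # part of the NES/AES Venn sets but their planted subsets are recorded
  tab$venn_subset[tab$regulator == "Kr-h1"] <- subset_key("Kr-h1")
  tab$venn_subset[tab$regulator == "broad"] <-
    subset_key(c("Kr-h1", "broad", "E93"))
  tab$venn_subset[tab$regulator == "E93"] <- subset_key(c("Kr-h1", "E93"))
  for (cls in c("NES", "AES")) {
    sub <- if (cls == "NES") grn$nes_subsets else grn$aes_subsets
    sub <- sub[sub > 0]
    if (!length(sub)) next
    ids <- sprintf("%s%03d", cls, seq_len(sum(sub)))
    tab <- rbind(tab, data.frame(
      feature_id = ids, class = cls,
      venn_subset = rep(names(sub), sub),
      failure_mode = "none", regulator = "", stringsAsFactors = FALSE))
  }
  if (grn$plant_failure_modes) {
    tab <- rbind(tab, data.frame(
      feature_id = paste0("FAIL_", c("c1", "c2", "c3")),
      class = "background",
      venn_subset = "unaffected",
      failure_mode = c("c1", "c2", "c3"),
      regulator = "", stringsAsFactors = FALSE))
  }
  tab
}

# edge list (regulator, feature, sign) implied by the planted truth
planted_edges <- function(truth, targets = c("Kr-h1", "broad", "E93")) {
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    cls <- truth$class[i]
    if (truth$regulator[i] != "") {
      # self-edge: own transcript drops in its RNAi region
      rg <- truth$regulator[i]
      sgn <- c("-")
      regs <- rg
      if (rg == "E93") { regs <- c("E93", "Kr-h1"); sgn <- c("-", "+") }
      if (rg == "broad") { regs <- c("broad", "Kr-h1", "E93")
                           sgn <- c("-", "-", "+") }
      rows[[length(rows) + 1L]] <- data.frame(
        regulator = regs, feature_id = truth$feature_id[i], sign = sgn,
        stringsAsFactors = FALSE)
    } else if (cls %in% c("NES", "AES") &&
               truth$venn_subset[i] != "unaffected") {
      tg <- strsplit(truth$venn_subset[i], "+", fixed = TRUE)[[1]]
      dirs <- expected_direction(cls)[tg]
      rows[[length(rows) + 1L]] <- data.frame(
        regulator = tg, feature_id = truth$feature_id[i],
        sign = ifelse(dirs == "up", "+", "-"), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(regulator = character(), feature_id = character(),
                      sign = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# planted TPM profile of one feature across the design (vector over samples)
profile_tpm <- function(class, regulator, failure_mode, design, grn) {
  n <- nrow(design)
  penult <- design$stage_class == "penultimate"
  final <- design$stage_class == "final"
  adult <- design$stage_class == "adult"
  nymph_wb <- design$stage_class == "nymph_whole"
  abdomen <- design$region == "abdomen"
  hi_s <- grn$tpm_stage_high; lo_s <- grn$tpm_stage_low
  hi_e <- grn$tpm_epi_high; lo_e <- grn$tpm_epi_low
  if (failure_mode == "c1") {            # expressed, but never reaches TPM 2
    x <- rep(0.05, n); x[penult | nymph_wb] <- 1.5; return(x)
  }
  if (failure_mode == "c2") {            # clear in nymphs, not off in adults
    x <- rep(2.5, n); x[penult | nymph_wb] <- 10; return(x)
  }
  if (failure_mode == "c3") {            # separated by less than 1.5-fold
    x <- rep(1.9, n); x[penult | nymph_wb] <- 2.5; return(x)
  }
  switch(class,
    "nymph-specific" = {                 # penultimate-high, off thereafter
      x <- rep(lo_s, n); x[penult | nymph_wb] <- hi_s; x
    },
    "adult-specific" = {                 # adult-high with final-abdomen rise
      x <- rep(lo_s, n); x[adult] <- hi_s; x[final & abdomen] <- hi_s; x
    },
    NES = { x <- rep(lo_e, n); x[final & abdomen] <- hi_e; x },
    AES = { x <- rep(lo_e, n); x[adult & abdomen] <- hi_e; x },
    stop("unknown class ", class))
}

#' Generate a synthetic count matrix with a planted regulatory truth
#'
#' Draws negative-binomial counts (variance `mu + phi * mu^2`) for every
#' sample of a design, with feature means set so that planted features
#' realize their target TPM profiles: nymph-specific features are high in
#' penultimate-instar samples and below TPM 2 in adults (and vice versa,
#' with an E93-like final-abdomen rise for adult-specific features), NES/AES
#' features switch between the final-instar and adult abdominal epidermis,
#' and mosaic RNAi effects are applied to the RNAi-region member of each
#' sample pair. The two samples of one RNAi individual share a log-normal
#' individual effect carrying `individual_share` of the biological variance.
#' The feature engineered to fail screening criterion 3 is planted
#' deterministically so its realized min(high)/max(low) TPM ratio lands in
#' (1, 1.5).
#'
#' @param design a [gen_design()] table.
#' @param grn a [grn_spec()].
#' @param n_features total number of features (>= number planted).
#' @param phi biological dispersion of the NB noise (default 0.05, a typical
#'   bulk CV^2); 0 gives the Poisson limit.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with `counts` (integer matrix, features x samples),
#'   `lengths` (named effective lengths, bp), `truth` (the truth table:
#'   feature_id, class, venn_subset, failure_mode, regulator), `edges`
#'   (planted regulator->feature effects) and `design`.
#' @export
gen_counts <- function(design, grn = grn_spec(), n_features = 2000,
                       phi = 0.05, seed = 1L) {
  stopifnot(inherits(design, "data.frame"), phi >= 0)
  set.seed(as.integer(seed))
  truth <- planted_features(grn)
  n_plant <- nrow(truth)
  if (n_features < n_plant)
    stop("n_features (", n_features, ") below number of planted features (",
         n_plant, ")")
  n_bg <- n_features - n_plant
  ids <- c(truth$feature_id,
           if (n_bg) sprintf("bg%04d", seq_len(n_bg)))
  truth <- rbind(truth, if (n_bg) data.frame(
    feature_id = ids[n_plant + seq_len(n_bg)], class = "background",
    venn_subset = "unaffected", failure_mode = "none", regulator = "",
    stringsAsFactors = FALSE))
  edges <- planted_edges(truth)

  lengths <- c(round(stats::runif(n_plant, 1500, 3000)),
               if (n_bg) pmin(9000, pmax(300, round(
                 stats::rlnorm(n_bg, log(1500), 0.45)))))
  names(lengths) <- ids
  ns <- nrow(design)

  # target TPM profiles
  tpm <- matrix(0, n_features, ns, dimnames = list(ids, design$sample_id))
  for (i in seq_len(n_plant))
    tpm[i, ] <- profile_tpm(truth$class[i], truth$regulator[i],
                            truth$failure_mode[i], design, grn)
  if (n_bg) {
    base <- stats::rlnorm(n_bg, 0, 1.2)
    base <- base / sum(base) * max(0, 1e6 - sum(rowMeans(
      tpm[seq_len(n_plant), , drop = FALSE])))
    tpm[n_plant + seq_len(n_bg), ] <- base
  }

  # mosaic RNAi effects on the rnai-region samples
  is_rnai <- startsWith(design$treatment, "rnai:")
  rnai_target <- sub("^rnai:", "", design$treatment)
  for (k in seq_len(nrow(edges))) {
    j <- which(is_rnai & rnai_target == edges$regulator[k])
    if (!length(j)) next
    fac <- mosaic_factor(edges$sign[k], grn$effect_fold,
                         grn$mosaic_fraction, grn$knockdown_efficiency)
    if (fac < 0) stop("infeasible plant: negative mean for ",
                      edges$feature_id[k])
    tpm[edges$feature_id[k], j] <- tpm[edges$feature_id[k], j] * fac
  }

  # library sizes and NB sampling
  lsm <- attr(design, "library_size_mean"); if (is.null(lsm)) lsm <- 2e7
  lcv <- attr(design, "library_size_cv"); if (is.null(lcv)) lcv <- 0.2
  sig <- sqrt(log(1 + lcv^2))
  libs <- stats::rlnorm(ns, log(lsm) - sig^2 / 2, sig)

  # shared individual effect for the two regions of one RNAi individual
  rho <- grn$individual_share
  paired <- is_rnai | startsWith(design$treatment, "control-region:")
  g <- matrix(1, n_features, ns)
  if (phi > 0 && rho > 0 && any(paired)) {
    sh2 <- log(1 + rho * phi)
    for (ind in unique(design$individual[paired])) {
      j <- which(design$individual == ind)
      g[, j] <- exp(stats::rnorm(n_features, -sh2 / 2, sqrt(sh2)))
    }
  }
  counts <- matrix(0L, n_features, ns, dimnames = dimnames(tpm))
  for (j in seq_len(ns)) {
    mu <- libs[j] * tpm[, j] * lengths / sum(tpm[, j] * lengths) * g[, j]
    phr <- if (paired[j]) (1 - rho) * phi else phi
    counts[, j] <- if (phr > 0)
      stats::rnbinom(n_features, mu = mu, size = 1 / phr)
    else stats::rpois(n_features, mu)
  }

  # deterministic c3 plant: realized TPM 2.5 (penultimate) / 1.9 (adult)
  i3 <- which(truth$failure_mode == "c3")
  if (length(i3)) {
    grp_hi <- which(design$stage_class %in% c("penultimate", "nymph_whole"))
    grp_lo <- which(!seq_len(ns) %in% grp_hi)
    for (j in seq_len(ns)) {
      t3 <- if (j %in% grp_hi) 2.5 else 1.9
      s0 <- sum(counts[-i3, j] / lengths[-i3])
      counts[i3, j] <- as.integer(round(
        lengths[i3] * s0 * t3 / (1e6 - t3)))
    }
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, lengths = lengths, truth = truth, edges = edges,
       design = design)
}

#' Noise-free screening-rule fixture
#'
#' A deterministic TPM matrix with one feature per pass/fail/boundary mode of
#' the three stage-screen TPM criteria, replicated across the four region
#' pairs (2 penultimate-nymph + 2 adult samples per region). The accompanying
#' truth table states, per feature, the expected criteria flags (in the
#' nymph-high orientation), the expected stage-screen label, and the expected
#' epidermis-screen outcome under the strict ratio rule.
#'
#' @return list with `tpm`, `design` (a minimal [gen_design()]-like table)
#'   and `truth`.
#' @export
plant_screen_cases <- function() {
  regions <- list(head = c("head", "head"), thorax = c("thorax", "thorax"),
                  abdomen = c("abdomen", "abdomen"),
                  wings = c("wing_buds", "wings"))
  # per feature: high-group (nymph) and low-group (adult) TPM duplicates
  cases <- list(
    nymph_clear  = list(h = c(5, 6),    l = c(0.1, 0.2),
                        c = c(TRUE, TRUE, TRUE),  lab = "nymph-specific",
                        tag = "pass"),
    adult_clear  = list(h = c(0.1, 0.2), l = c(5, 6),
                        c = c(FALSE, FALSE, FALSE), lab = "adult-specific",
                        tag = "pass_adult"),
    fail_c1      = list(h = c(1.9, 10), l = c(0, 0),
                        c = c(FALSE, TRUE, TRUE), lab = "none", tag = "c1"),
    fail_c2      = list(h = c(5, 6),    l = c(0.5, 2.1),
                        c = c(TRUE, FALSE, TRUE), lab = "none", tag = "c2"),
    fail_c3      = list(h = c(2.5, 3),  l = c(1.7, 1.9),
                        c = c(TRUE, TRUE, FALSE), lab = "none", tag = "c3"),
    boundary_c1  = list(h = c(2, 5),    l = c(0.1, 0.2),
                        c = c(TRUE, TRUE, TRUE),  lab = "nymph-specific",
                        tag = "boundary_c1"),
    boundary_c2  = list(h = c(5, 6),    l = c(1, 2),
                        c = c(TRUE, FALSE, TRUE), lab = "none",
                        tag = "boundary_c2"),
    boundary_c3  = list(h = c(2.7, 3),  l = c(1.5, 1.8),
                        c = c(TRUE, TRUE, TRUE),  lab = "nymph-specific",
                        tag = "boundary_c3"),
    background   = list(h = c(1, 1),    l = c(1, 1),
                        c = c(FALSE, TRUE, FALSE), lab = "none", tag = "bg"))
  ids <- names(cases)
  samp <- list()
  for (r in names(regions)) {
    samp[[r]] <- data.frame(
      sample_id = c(paste0("p_", r, "_", 1:2), paste0("a_", r, "_", 1:2)),
      stage = rep(c("penult_1", "adult_1"), each = 2),
      stage_class = rep(c("penultimate", "adult"), each = 2),
      region = rep(regions[[r]], each = 2),
      sex = "mixed",
      individual = c(paste0("pn_", r, "_", 1:2), paste0("ad_", r, "_", 1:2)),
      treatment = "untreated", stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, samp)
  rownames(design) <- NULL
  class(design) <- c("sample_design", "data.frame")
  tpm <- matrix(0, length(cases), nrow(design),
                dimnames = list(ids, design$sample_id))
  for (i in seq_along(cases)) {
    hl <- cases[[i]]
    for (r in names(regions)) {
      jp <- design$region == regions[[r]][1] &
            design$stage_class == "penultimate"
      ja <- design$region == regions[[r]][2] & design$stage_class == "adult"
      tpm[i, jp] <- hl$h
      tpm[i, ja] <- hl$l
    }
  }
  # fourth-region dropout case: passes everywhere except the wing pair
  tpm <- rbind(tpm, region_dropout = tpm["nymph_clear", ])
  wings <- design$region %in% c("wing_buds", "wings")
  tpm["region_dropout", wings] <- 1
  flags <- t(vapply(cases, function(x) x$c, logical(3)))
  truth <- data.frame(
    feature_id = rownames(tpm),
    stage_label = c(vapply(cases, function(x) x$lab, character(1)), "none"),
    c1 = c(flags[, 1], TRUE), c2 = c(flags[, 2], TRUE),
    c3 = c(flags[, 3], TRUE),
    # epidermis rule: strict ratio only (no absolute criteria)
    # the epidermis screen looks at abdomen samples only, so the
    # region-dropout feature (separated everywhere except wings) is still NES
    epi_label = c("NES", "AES", "NES", "NES", "none", "NES", "NES", "none",
                  "none", "NES"),
    failure_mode = c(vapply(cases, function(x) x$tag, character(1)),
                     "region_dropout"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(tpm = tpm, design = design, truth = truth)
}

#' Simulate an aligned set of zinc-finger domain sequences
#'
#' Generates reference amino-acid domains in well-separated clades (each
#' clade from its own random ancestor, members lightly mutated) plus query
#' domains mutated from randomly chosen clade members — a stand-in for the
#' alternatively spliced C2H2 zinc-finger domains of *broad* and their
#' insect reference clades.
#'
#' @param n_clades number of reference clades (default 5).
#' @param refs_per_clade reference sequences per clade.
#' @param n_queries query sequences to plant.
#' @param len alignment length in residues.
#' @param within_mut per-site mutation probability inside a clade.
#' @param query_mut per-site mutation probability for a query relative to its
#'   seed reference.
#' @param seed integer seed.
#' @return list with `alignment` (named character vector of equal-length
#'   strings), `clades` (named list of reference ids per clade) and `truth`
#'   (query id -> clade).
#' @export
sim_domain_alignment <- function(n_clades = 5, refs_per_clade = 3,
                                 n_queries = 7, len = 60,
                                 within_mut = 0.06, query_mut = 0.04,
                                 seed = 1L) {
  stopifnot(n_clades >= 2, refs_per_clade >= 2, len >= 10)
  set.seed(as.integer(seed))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mutate <- function(s, p) {
    hit <- stats::runif(len) < p
    s[hit] <- sample(aa, sum(hit), replace = TRUE)
    s
  }
  aln <- list(); clades <- list()
  for (k in seq_len(n_clades)) {
    anc <- sample(aa, len, replace = TRUE)
    cl <- paste0("ZF", k)
    ids <- paste0(cl, "_ref", seq_len(refs_per_clade))
    for (id in ids) aln[[id]] <- mutate(anc, within_mut)
    clades[[cl]] <- ids
  }
  truth <- character(0)
  if (n_queries > 0) {
    src <- rep(seq_len(n_clades), length.out = n_queries)
    for (q in seq_len(n_queries)) {
      cl <- paste0("ZF", src[q])
      seed_id <- sample(clades[[cl]], 1)
      id <- paste0("query", q)
      aln[[id]] <- mutate(aln[[seed_id]], query_mut)
      truth[id] <- cl
    }
  }
  list(alignment = vapply(aln, paste, character(1), collapse = ""),
       clades = clades, truth = truth)
}
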