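test_that("default design reproduces the 82-sample layout plus 20 RNAi rows", {
  spec <- design_spec()
  expect_equal(spec$n_whole_body, 13)
  expect_equal(spec$n_nymph_region_samples, 45)
  expect_equal(spec$n_adult_region_samples, 24)
  d <- gen_design(spec)
  expect_equal(sum(d$treatment == "untreated"), 82)
  expect_equal(sum(d$treatment != "untreated"), 20)  # 2 * (3 + 4 + 3)
  expect_false(anyDuplicated(d$sample_id) > 0)
  # RNAi and control-region samples pair within individuals
  pr <- pair_samples(d)
  expect_equal(nrow(pr), 10)
  expect_equal(sort(unique(pr$target)), sort(c("Kr-h1", "broad", "E93")))
  expect_equal(unname(table(pr$target)[c("Kr-h1", "broad", "E93")]),
               c(3L, 4L, 3L), ignore_attr = TRUE)
  # deterministic: same spec, same table
  expect_identical(d, gen_design(spec))
})

test_that("singleton design has no duplicated sample ids", {
  spec <- design_spec(whole_body_stages = "egg_1",
                      penultimate_stages = "penult_1",
                      final_stages = "final_s1",
                      nymph_regions = "abdomen", adult_regions = "abdomen",
                      adult_individuals = 1,
                      n_rnai_pairs = c("Kr-h1" = 1, "broad" = 1, "E93" = 1))
  d <- gen_design(spec)
  expect_false(anyDuplicated(d$sample_id) > 0)
  expect_error(design_spec(adult_individuals = 0))
  expect_error(design_spec(n_rnai_pairs = c("Kr-h1" = 0)), ">= 1")
})

test_that("gen_counts is byte-identical under a fixed seed", {
  d <- gen_design(design_spec())
  a <- gen_counts(d, grn_spec(), n_features = 120, phi = 0.05, seed = 99)
  b <- gen_counts(d, grn_spec(), n_features = 120, phi = 0.05, seed = 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$lengths, b$lengths)
  expect_identical(a$truth, b$truth)
  c2 <- gen_counts(d, grn_spec(), n_features = 120, phi = 0.05, seed = 100)
  expect_false(identical(a$counts, c2$counts))
})

test_that("truth table covers every feature once and every failure mode", {
  d <- gen_design(design_spec())
  sim <- gen_counts(d, grn_spec(), n_features = 150, seed = 1)
  expect_equal(nrow(sim$truth), 150)
  expect_false(anyDuplicated(sim$truth$feature_id) > 0)
  expect_setequal(rownames(sim$counts), sim$truth$feature_id)
  expect_true(all(c("c1", "c2", "c3") %in% sim$truth$failure_mode))
  expect_error(gen_counts(d, grn_spec(), n_features = 10), "below number")
})

test_that("generated counts match NB moments (and Poisson in the phi=0 limit)", {
  # ~1000 equal adult replicates: background features are iid NB per sample
  spec <- design_spec(whole_body_stages = "egg_1",
                      penultimate_stages = "penult_1",
                      final_stages = "final_s1",
                      adult_individuals = 250,
                      library_size_mean = 2e6, library_size_cv = 0,
                      n_rnai_pairs = c("Kr-h1" = 1, "broad" = 1, "E93" = 1))
  d <- gen_design(spec)
  adult <- d$sample_id[d$stage_class == "adult" & d$treatment == "untreated"]
  expect_equal(length(adult), 1000)

  phi <- 0.05
  sim <- gen_counts(d, grn_spec(), n_features = 80, phi = phi, seed = 12)
  bg <- sim$truth$feature_id[sim$truth$class == "background"]
  y <- sim$counts[bg, adult, drop = FALSE]
  m <- rowMeans(y); v <- apply(y, 1, var)
  keep <- m > 50
  phi_hat <- (v[keep] - m[keep]) / m[keep]^2
  se <- sd(phi_hat) / sqrt(sum(keep))
  expect_lt(abs(mean(phi_hat) - phi), 3 * se)     # NB variance recovered

  sim0 <- gen_counts(d, grn_spec(), n_features = 80, phi = 0, seed = 13)
  y0 <- sim0$counts[bg, adult, drop = FALSE]
  ratio <- apply(y0, 1, var) / rowMeans(y0)
  se0 <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se0)        # Poisson limit var = mean
})

test_that("full knockdown with fold 10 realizes a ~0.1 TPM ratio over 100 pairs", {
  spec <- design_spec(n_rnai_pairs = c("Kr-h1" = 100, "broad" = 2, "E93" = 2))
  d <- gen_design(spec)
  grn <- grn_spec(effect_fold = 10, knockdown_efficiency = 1,
                  mosaic_fraction = 1)
  sim <- gen_counts(d, grn, n_features = 200, phi = 0.05, seed = 14)
  tpm <- compute_tpm(sim$counts, sim$lengths)
  pairs <- pair_samples(d)
  pk <- pairs[pairs$target == "Kr-h1", ]
  # a NES feature with a Kr-h1 "down" edge, measured where it is highly
  # expressed (final-instar abdomen)
  feat <- sim$edges$feature_id[sim$edges$regulator == "Kr-h1" &
                               sim$edges$sign == "-" &
                               startsWith(sim$edges$feature_id, "NES")][1]
  ratios <- tpm[feat, pk$rnai_id] / tpm[feat, pk$control_id]
  expect_equal(mean(ratios), 0.1, tolerance = 0.3)  # 0.1 within sampling error
  expect_lt(abs(mean(ratios) - 0.1), 0.03)
})

test_that("engineered criterion-3 failure lands in the (1, 1.5) ratio band", {
  d <- recovery_design(n = 3)
  sim <- gen_counts(d, grn_spec(), n_features = 400, phi = 0.05, seed = 15)
  tpm <- compute_tpm(sim$counts, sim$lengths)
  f3 <- sim$truth$feature_id[sim$truth$failure_mode == "c3"]
  hi <- d$sample_id[d$stage_class == "penultimate"]
  lo <- d$sample_id[d$stage_class == "adult" & d$treatment == "untreated"]
  r <- min(tpm[f3, hi]) / max(tpm[f3, lo])
  expect_gt(r, 1); expect_lt(r, 1.5)
})

test_that("infeasible mosaic factors are rejected up front", {
  expect_error(grn_spec(effect_fold = 0.5), ">= 1")
  expect_error(grn_spec(mosaic_fraction = 1.2))
})
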