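mk_pairs <- function(n, target = "Kr-h1") {
  data.frame(individual = paste0("ind", seq_len(n)), target = target,
             rnai_id = paste0("r", seq_len(n)),
             control_id = paste0("c", seq_len(n)), stringsAsFactors = FALSE)
}

mk_pair_tpm <- function(rnai, control, target = "Kr-h1", id = "f") {
  n <- length(rnai)
  m <- matrix(c(rnai, control), 1,
              dimnames = list(id, c(paste0("r", 1:n), paste0("c", 1:n))))
  list(tpm = m, pairs = mk_pairs(n, target))
}

test_that("pair_samples pairs by individual and drops unpaired ones", {
  d <- gen_design(design_spec())
  pr <- pair_samples(d)
  expect_equal(nrow(pr), 10)
  expect_true(all(startsWith(pr$rnai_id, "r_")))
  expect_true(all(startsWith(pr$control_id, "c_")))
  # control-only individual is excluded with a warning
  d2 <- d[!(d$sample_id == "r_E93_3"), ]
  expect_warning(pr2 <- pair_samples(d2), "unpaired")
  expect_equal(nrow(pr2), 9)
  # duplicate RNAi sample for one individual is an error
  d3 <- rbind(d, within(d[d$sample_id == "r_E93_1", ],
                        sample_id <- "r_E93_1b"))
  expect_error(pair_samples(d3), "RNAi samples")
  # empty design gives an empty pairing
  expect_equal(nrow(pair_samples(d[d$treatment == "untreated", ])), 0)
})

test_that("classify_effect applies the fold + unanimity rule", {
  x <- mk_pair_tpm(rnai = c(2.0, 1.8, 1.6), control = c(1, 1, 1))
  e <- classify_effect(x$tpm, x$pairs)
  expect_equal(e$direction, "up")            # mean ratio 1.8, unanimous
  expect_equal(e$mean_ratio, 1.8)

  x <- mk_pair_tpm(rnai = c(2.0, 0.5, 2.0), control = c(1, 1, 1))
  expect_equal(classify_effect(x$tpm, x$pairs)$direction, "none")  # not unanimous

  x <- mk_pair_tpm(rnai = c(1.2, 1.3, 1.4), control = c(1, 1, 1))
  expect_equal(classify_effect(x$tpm, x$pairs)$direction, "none")  # ratio 1.3

  x <- mk_pair_tpm(rnai = c(0.5, 0.6, 0.7), control = c(1, 1, 1))
  expect_equal(classify_effect(x$tpm, x$pairs)$direction, "down")  # < 2/3

  x <- mk_pair_tpm(rnai = c(0.7, 0.6, 0.7), control = c(1, 1, 1))
  expect_equal(classify_effect(x$tpm, x$pairs)$direction, "none")  # 2/3 rule
})

test_that("classify_effect zero handling and pair-rescaling invariance", {
  x <- mk_pair_tpm(rnai = c(3, 4, 5), control = c(0, 0, 0))
  e <- classify_effect(x$tpm, x$pairs)
  expect_equal(e$mean_ratio, Inf)
  expect_equal(e$direction, "up")

  x <- mk_pair_tpm(rnai = c(0, 0, 0), control = c(0, 0, 0))
  expect_equal(classify_effect(x$tpm, x$pairs)$direction, "none")

  # scaling both members of a pair leaves the classification unchanged
  x <- mk_pair_tpm(rnai = c(4, 5, 6), control = c(2, 2, 2))
  y <- x
  sc <- c(10, 0.5, 3)
  y$tpm[1, ] <- x$tpm[1, ] * rep(sc, 2)
  ex <- classify_effect(x$tpm, x$pairs)
  ey <- classify_effect(y$tpm, y$pairs)
  expect_equal(ey$direction, ex$direction)
  expect_equal(ey$unanimous, ex$unanimous)

  expect_error(classify_effect(x$tpm, mk_pairs(1)), ">= 2 pairs")
})

test_that("paired_t matches the hand example and stats::t.test", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)        # differences 1, 2, 3
  pt_ <- paired_t(x, y)
  expect_equal(pt_$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(pt_$p_value, 0.0742, tolerance = 1e-3)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(pt_$statistic, unname(tt$statistic))
  expect_equal(pt_$p_value, tt$p.value)

  sym <- paired_t(c(1, -1), c(0, 0))      # differences +d, -d
  expect_equal(sym$statistic, 0); expect_equal(sym$p_value, 1)

  expect_equal(paired_t(c(5, 5), c(5, 5))$p_value, 1)   # all differences 0
  deg <- paired_t(c(2, 3), c(1, 2))       # constant nonzero difference
  expect_equal(deg$p_value, 0); expect_true(deg$degenerate)

  # scale invariance of p
  a <- c(3, 5, 9); b <- c(1, 2, 4)
  expect_equal(paired_t(7 * a, 7 * b)$p_value, paired_t(a, b)$p_value)
})

test_that("student_t matches the pooled-variance formula and t.test", {
  a <- c(1, 2, 3); b <- c(4, 6, 8)
  st <- student_t(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(st$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(st$p_value, tt$p.value, tolerance = 1e-12)

  same <- student_t(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)

  sep <- student_t(c(0, 0, 1e-9), c(1, 1, 1 + 1e-9))
  expect_lt(sep$p_value, 0.01)

  expect_equal(student_t(c(1, 1), c(1, 1))$p_value, 1)
  expect_error(student_t(c(1, 1), c(2, 2)), "pooled variance")
})

test_that("paired_t equals student_t of differences against zeros", {
  set.seed(30)
  x <- rnorm(5, 1); y <- rnorm(5)
  # identical t statistics (pooled variance of d and zeros halves, the
  # standard error doubles back); only the degrees of freedom differ
  pt_ <- paired_t(x, y)
  st <- student_t(x - y, rep(0, 5))
  expect_equal(pt_$statistic, st$statistic, tolerance = 1e-12)
})

test_that("venn_partition assigns subsets and retains directions", {
  eff <- rbind(
    data.frame(feature_id = "nes1", target = c("Kr-h1", "broad", "E93"),
               direction = c("down", "down", "up")),
    data.frame(feature_id = "quiet", target = c("Kr-h1", "broad", "E93"),
               direction = "none"))
  vp <- venn_partition(eff, expected = c("Kr-h1" = "down", "broad" = "down",
                                         "E93" = "up"))
  expect_equal(vp$subset[vp$feature_id == "nes1"], "Kr-h1+broad+E93")
  expect_equal(vp$subset[vp$feature_id == "quiet"], "unaffected")
  expect_true(all(vp$concordant))
  expect_error(venn_partition(eff[eff$target != "E93", ]), "missing")
})

test_that("venn_summary reproduces the printed NES/AES arithmetic", {
  nes <- as_venn_partition(c("Kr-h1" = 9, "broad" = 11, "E93" = 30,
                             "Kr-h1+broad" = 27, "Kr-h1+E93" = 47,
                             "broad+E93" = 6, "Kr-h1+broad+E93" = 24,
                             "unaffected" = 12))
  vs <- venn_summary(nes)
  expect_equal(vs$n, 166)
  expect_equal(vs$broad_involved, 68)        # 24 + 27 + 6 + 11
  expect_equal(vs$non_broad_affected, 86)    # 9 + 47 + 30
  expect_equal(vs$affected, sum(vs$region_counts) - 12)
  # completeness: regions + unaffected partition the set
  expect_equal(sum(vs$region_counts), vs$n)

  empty <- as_venn_partition(c("unaffected" = 5))
  expect_equal(venn_summary(empty)$affected_pct, 0)
  expect_error(as_venn_partition(c(foo = 1)), "canonical")
})
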