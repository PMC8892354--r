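test_that("p-distance counts differing sites with pairwise gap deletion", {
  aln <- c(a = "AAAA", b = "AAAT", c = "A-AA", d = "ATAA")
  d <- as.matrix(pdistance(aln))
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["c", "d"], 0)        # the gapped column is excluded
  expect_equal(d["a", "a"], 0)
  expect_error(pdistance(c(a = "--AA", b = "AA--")), "comparable")

  # Poisson correction
  dp <- as.matrix(pdistance(aln, correction = "poisson"))
  expect_equal(dp["a", "b"], -log(1 - 0.25))
})

test_that("p-distance agrees with ape on gap-free alignments", {
  set.seed(50)
  sim <- sim_domain_alignment(n_clades = 3, refs_per_clade = 2,
                              n_queries = 0, len = 40, seed = 50)
  d1 <- as.matrix(pdistance(sim$alignment))
  m <- t(vapply(sim$alignment, function(s) strsplit(s, "")[[1]],
                character(40)))
  d2 <- as.matrix(ape::dist.aa(ape::as.AAbin(m), scaled = TRUE))
  expect_equal(d1, d2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("3-taxon NJ has the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(as.dist(d))
  expect_equal(ape::Ntip(tr), 3)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(0, 2, 4))
})

test_that("NJ recovers additive 4-taxon structure with exact lengths", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 5
  dm["A", "D"] <- dm["D", "A"] <- 6
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 7
  dm["C", "D"] <- dm["D", "C"] <- 7
  tr <- nj_tree(as.dist(dm))
  # four-point condition: AB|CD is the split
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(dm), rownames(dm)],
               dm, tolerance = 1e-12)
})

test_that("NJ is consistent on tree-derived distances (random trees, n <= 8)", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(tr0), tr), 0, ignore_attr = TRUE)
  }
})

test_that("negative branch lengths are clamped and flagged", {
  # frozen non-additive matrix for which plain NJ yields a negative length
  d <- matrix(c(0.000, 1.011, 2.639, 2.686, 2.038,
                1.011, 0.000, 1.349, 1.333, 1.545,
                2.639, 1.349, 0.000, 2.528, 1.686,
                2.686, 1.333, 2.528, 0.000, 2.410,
                2.038, 1.545, 1.686, 2.410, 0.000), 5,
              dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  expect_true(any(ape::nj(as.dist(d))$edge.length < 0))
  tr <- nj_tree(as.dist(d))
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "negative_clamped"), 1)
})

test_that("bootstrap support saturates for clear clades and is reproducible", {
  sim <- sim_domain_alignment(n_clades = 2, refs_per_clade = 3, n_queries = 0,
                              len = 80, within_mut = 0.03, seed = 52)
  bs1 <- bootstrap_support(sim$alignment, reps = 100, seed = 7)
  bs2 <- bootstrap_support(sim$alignment, reps = 100, seed = 7)
  expect_identical(bs1$support, bs2$support)
  expect_true(all(bs1$support$support >= 0 & bs1$support$support <= 100))
  # the two clades are separated by many diagnostic columns
  clade_tips <- sim$clades[["ZF1"]]
  part <- ape::prop.part(bs1$tree)
  labs <- bs1$tree$tip.label
  node <- which(vapply(part, function(p)
    setequal(labs[p], clade_tips) || setequal(setdiff(labs, labs[p]),
                                              clade_tips), logical(1)))
  expect_gte(bs1$support$support[node], 95)

  # a signal-free alignment (iid columns, no tree structure) supports its
  # arbitrary base bipartitions far less than genuine clades
  set.seed(58)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  noise <- setNames(vapply(1:6, function(i)
    paste(sample(aa, 100, replace = TRUE), collapse = ""), character(1)),
    paste0("t", 1:6))
  bsn <- bootstrap_support(noise, reps = 100, seed = 3)
  internal <- bsn$support$support[-1]     # drop the trivial root partition
  expect_lt(mean(internal), 70)
  expect_error(bootstrap_support(noise, reps = 0), "reps")
})

test_that("queries are assigned to their planted clades", {
  sim <- sim_domain_alignment(n_clades = 5, refs_per_clade = 3, n_queries = 7,
                              len = 90, seed = 53)
  tr <- nj_tree(pdistance(sim$alignment))
  got <- assign_clade(tr, sim$clades)
  # every assignment is correct (stem-sitters may stay NA under the strict
  # nesting rule), and the 5 planted source clades all appear
  assigned <- !is.na(got)
  expect_true(all(got[assigned] == sim$truth[names(got)[assigned]]))
  expect_equal(sort(unique(got[assigned])), sort(paste0("ZF", 1:5)))
  expect_equal(length(attr(got, "unresolvable")), 0)
})

test_that("a query equidistant from all clades stays unassigned", {
  set.seed(54)
  sim <- sim_domain_alignment(n_clades = 3, refs_per_clade = 3, n_queries = 0,
                              len = 60, seed = 55)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  outlier <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  aln <- c(sim$alignment, stranger = outlier)
  tr <- nj_tree(pdistance(aln))
  got <- assign_clade(tr, sim$clades)
  expect_true(is.na(got[["stranger"]]))
})

test_that("alignment FASTA round-trips through ape and newick export works", {
  sim <- sim_domain_alignment(n_clades = 2, refs_per_clade = 2, n_queries = 1,
                              len = 30, seed = 56)
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(sim$alignment), "\n", sim$alignment), fa)
  back <- read_domain_alignment(fa)
  expect_equal(back, sim$alignment)
  bs <- bootstrap_support(back, reps = 20, seed = 2)
  nwk <- tempfile(fileext = ".nwk")
  write_newick(bs, nwk)
  reread <- ape::read.tree(nwk)
  expect_setequal(reread$tip.label, names(sim$alignment))
})
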