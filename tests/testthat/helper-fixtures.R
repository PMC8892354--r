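# shared fixtures built in code

# minimal two-group count matrix with optional planted fold changes
make_counts <- function(n_genes = 100, n_per_group = 3, mu = 200, phi = 0.1,
                        fold = 1, n_de = 0, seed = 1) {
  set.seed(seed)
  base <- exp(rnorm(n_genes, log(mu), 1))
  muA <- base; muB <- base
  if (n_de > 0) muB[seq_len(n_de)] <- muB[seq_len(n_de)] * fold
  draw <- function(m) if (phi > 0) rnbinom(length(m), mu = m, size = 1 / phi)
                      else rpois(length(m), m)
  y <- cbind(vapply(seq_len(n_per_group), function(i) draw(muA),
                    numeric(n_genes)),
             vapply(seq_len(n_per_group), function(i) draw(muB),
                    numeric(n_genes)))
  rownames(y) <- sprintf("g%03d", seq_len(n_genes))
  colnames(y) <- c(paste0("A", seq_len(n_per_group)),
                   paste0("B", seq_len(n_per_group)))
  list(counts = y, groups = rep(c("A", "B"), each = n_per_group))
}

# design with a chosen number of replicates per screen group, for the
# planted-recovery runs (n penultimate substages = n adult individuals = n)
recovery_design <- function(n = 3, lib = 2e7) {
  gen_design(design_spec(
    penultimate_stages = paste0("penult_", seq_len(n)),
    adult_individuals = n,
    library_size_mean = lib, library_size_cv = 0.2))
}

# brute-force average-linkage agglomeration (independent oracle for hclust)
brute_average_linkage <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- mean(dm[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}
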