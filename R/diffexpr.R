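#' TMM normalization factors
#'
#' Trimmed mean of M-values (Robinson & Oshlack): composition-robust
#' per-sample scaling factors for count data. M-values (log2 ratios of
#' library-size-normalized counts against a reference sample) are trimmed by
#' 30% on each side, A-values (average log2 abundance) by 5%, and the
#' remaining M-values averaged with inverse-asymptotic-variance weights.
#' Factors are renormalized so their geometric mean is 1.
#'
#' @param counts features x samples count matrix, >= 2 samples.
#' @param reference column name/index of the reference sample, or `"auto"`
#'   (default): the sample whose 75th count percentile (scaled by library
#'   size) is closest to the mean across samples.
#' @param logratio_trim,sum_trim tail fractions trimmed from M and A.
#' @return numeric vector of factors, one per sample, geometric mean 1.
#' @export
tmm_factors <- function(counts, reference = "auto",
                        logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  ns <- ncol(counts)
  if (ns < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero total count")
  if (identical(reference, "auto")) {
    q75 <- apply(counts, 2, function(y) stats::quantile(y / sum(y), 0.75))
    ref <- which.min(abs(q75 - mean(q75)))
  } else {
    ref <- if (is.character(reference)) match(reference, colnames(counts)) else reference
    if (is.na(ref) || ref < 1 || ref > ns) stop("unknown reference sample")
  }
  yr <- counts[, ref] / lib[ref]
  f <- vapply(seq_len(ns), function(k) {
    yk <- counts[, k] / lib[k]
    keep <- yk > 0 & yr > 0
    if (!any(keep))
      stop("sample ", k, " shares no expressed features with the reference")
    m <- log2(yk[keep] / yr[keep])
    a <- 0.5 * log2(yk[keep] * yr[keep])
    w <- (1 - counts[keep, k] / lib[k]) / counts[keep, k] +
         (1 - counts[keep, ref] / lib[ref]) / counts[keep, ref]
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * sum_trim) + 1;      hi_a <- n + 1 - lo_a
    rm_ <- rank(m); ra <- rank(a)
    use <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(use)) return(1)
    2^(sum(m[use] / w[use]) / sum(1 / w[use]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Method-of-moments common dispersion
#'
#' Estimates the common negative-binomial dispersion phi in the edgeR-style
#' parameterization `var = mu + phi * mu^2`. Counts are first scaled to a
#' common effective library size; each gene's moment estimate
#' `(s^2 - mu)/mu^2` is formed within every group that has replicates and
#' combined with degree-of-freedom weights; the common value summarizes genes
#' with mean > 1 by their (default) mean. The per-gene estimates are returned
#' for diagnostics.
#'
#' The default `center = "mean"` is deliberate: the median of the per-gene
#' moment estimates is biased low at small replicate numbers (the sampling
#' distribution of s^2 is right-skewed), which makes the downstream exact
#' test anticonservative; the df-weighted mean is near-unbiased.
#'
#' @param counts features x samples count matrix.
#' @param groups factor/vector of group labels, one per sample.
#' @param norm_factors optional per-sample normalization factors (e.g. from
#'   [tmm_factors()]); default all 1.
#' @param center `"mean"` (default) or `"median"` summary over genes.
#' @return list with `common` (scalar phi >= 0) and `per_gene` (diagnostic
#'   vector, unclamped), class `"dispersion_estimate"`.
#' @export
estimate_dispersion <- function(counts, groups, norm_factors = NULL,
                                center = c("mean", "median")) {
  center <- match.arg(center)
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) stop("one group label per sample required")
  lib <- colSums(counts)
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  eff <- lib * norm_factors
  y <- sweep(counts, 2, exp(mean(log(eff))) / eff, "*")
  tab <- table(groups)
  rep_groups <- names(tab)[tab >= 2]
  if (!length(rep_groups)) stop("no group with replication")
  num <- 0; den <- 0
  for (g in rep_groups) {
    yy <- y[, groups == g, drop = FALSE]
    m <- rowMeans(yy)
    v <- apply(yy, 1, stats::var)
    est <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    w <- ncol(yy) - 1
    num <- num + ifelse(is.na(est), 0, est * w)
    den <- den + ifelse(is.na(est), 0, w)
  }
  per_gene <- ifelse(den > 0, num / den, NA_real_)
  names(per_gene) <- rownames(counts)
  keep <- rowMeans(y) > 1 & is.finite(per_gene)
  common <- if (!any(keep)) 0 else switch(center,
    mean   = max(0, mean(per_gene[keep])),
    median = max(0, stats::median(per_gene[keep])))
  structure(list(common = common, per_gene = per_gene, center = center),
            class = "dispersion_estimate")
}

#' Conditional negative-binomial exact test for two group sums
#'
#' Two-sided exact test of equal means between two groups of i.i.d.
#' NB(mu, phi) counts, conditional on the total. With counts pre-equalized to
#' a common library size, the group sums are NB with sizes `nA/phi`, `nB/phi`
#' and shared success probability, so the conditional distribution of the
#' group-A sum given the total does not depend on mu. The two-sided p-value
#' sums all partitions whose conditional probability is at most that of the
#' observed one (minimum-likelihood rule, ties included with relative
#' tolerance 1 + 1e-7, the stats::binom.test convention). At `phi = 0` the
#' test reduces to the exact binomial test of `yA` out of `yA + yB` with
#' success probability `nA/(nA+nB)`.
#'
#' @param y_a,y_b non-negative group sums of equalized counts.
#' @param n_a,n_b number of samples in each group.
#' @param phi common dispersion, >= 0.
#' @return two-sided p-value in \[0, 1\].
#' @export
nb_exact_test <- function(y_a, y_b, n_a, n_b, phi) {
  if (phi < 0) stop("phi must be >= 0")
  if (y_a < 0 || y_b < 0) stop("negative counts")
  s <- y_a + y_b
  if (s == 0) return(1)
  if (phi == 0) {
    lo <- 0; hi <- s
  } else {
    # window holding conditional mass > 1 - 1e-12 (plus the observed value)
    mu <- s / (n_a + n_b)
    lo <- max(0, min(stats::qnbinom(1e-14, size = n_a / phi, mu = n_a * mu),
                     s - stats::qnbinom(1e-14, size = n_b / phi, mu = n_b * mu,
                                        lower.tail = FALSE)))
    hi <- min(s, max(stats::qnbinom(1e-14, size = n_a / phi, mu = n_a * mu,
                                    lower.tail = FALSE),
                     s - stats::qnbinom(1e-14, size = n_b / phi, mu = n_b * mu)))
    lo <- min(lo, y_a); hi <- max(hi, y_a)
  }
  a <- lo:hi
  if (phi == 0) {
    lp <- stats::dbinom(a, s, n_a / (n_a + n_b), log = TRUE)
  } else {
    # log P(A=a)P(B=s-a) along the window via the NB pmf-ratio recurrence:
    # both sums share the success probability mu*phi/(1 + mu*phi), so the
    # ratio lp(a+1) - lp(a) reduces to a single log term
    mu <- s / (n_a + n_b)
    size_a <- n_a / phi; size_b <- n_b / phi
    lp0 <- stats::dnbinom(lo, size = size_a, mu = n_a * mu, log = TRUE) +
           stats::dnbinom(s - lo, size = size_b, mu = n_b * mu, log = TRUE)
    if (hi > lo) {
      aa <- lo:(hi - 1)
      inc <- log(((aa + size_a) * (s - aa)) /
                 ((aa + 1) * (s - aa - 1 + size_b)))
      lp <- c(lp0, lp0 + cumsum(inc))
    } else lp <- lp0
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[y_a - lo + 1]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `p_(i) * m / i` with enforced monotonicity from
#' the largest p downward, capped at 1. Invariant to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\]; NAs propagate.
#' @return vector of adjusted values (q-values), same order as input.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m) {
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(pp[o] * (m / (m:1))))[ro]
  }
  q
}

#' Two-group differential expression by the conditional NB exact test
#'
#' Composes the self-contained DE pipeline: TMM normalization, equalization of
#' all samples to the common (geometric-mean) effective library size,
#' method-of-moments common dispersion, per-gene conditional NB exact test on
#' the equalized group sums, and Benjamini-Hochberg adjustment. Genes with
#' zero counts everywhere get p = FDR = 1.
#'
#' @param counts features x samples count matrix.
#' @param groups vector of group labels, one per sample; must contain both
#'   contrast levels.
#' @param contrast character(2): `(groupA, groupB)`; logFC is A over B.
#' @param pseudocount added to normalized group means for the logFC (display
#'   only; default 0.5 equalized counts).
#' @param dispersion optional fixed common dispersion; estimated when NULL.
#' @param norm_factors optional fixed normalization factors; TMM when NULL.
#' @return data.frame (class `"de_result"`) with feature_id, logFC, pvalue,
#'   fdr; attribute `"dispersion"` holds the common phi used.
#' @export
run_de <- function(counts, groups, contrast = NULL, pseudocount = 0.5,
                   dispersion = NULL, norm_factors = NULL) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) stop("one group label per sample required")
  if (is.null(contrast)) contrast <- unique(groups)[1:2]
  if (!all(contrast %in% groups)) stop("both contrast groups must be present")
  use <- groups %in% contrast
  counts <- counts[, use, drop = FALSE]
  groups <- groups[use]
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, groups, norm_factors)$common
  }
  eff <- colSums(counts) * norm_factors
  common_lib <- exp(mean(log(eff)))
  yeq <- round(sweep(counts, 2, common_lib / eff, "*"))
  ia <- groups == contrast[1]; ib <- groups == contrast[2]
  y_a <- rowSums(yeq[, ia, drop = FALSE])
  y_b <- rowSums(yeq[, ib, drop = FALSE])
  n_a <- sum(ia); n_b <- sum(ib)
  pv <- vapply(seq_along(y_a), function(i)
    nb_exact_test(y_a[i], y_b[i], n_a, n_b, dispersion), numeric(1))
  lfc <- log2((y_a / n_a + pseudocount) / (y_b / n_b + pseudocount))
  out <- data.frame(
    feature_id = if (is.null(rownames(counts))) as.character(seq_along(pv))
                 else rownames(counts),
    logFC = lfc, pvalue = pv, fdr = bh_adjust(pv),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- dispersion
  class(out) <- c("de_result", "data.frame")
  out
}
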