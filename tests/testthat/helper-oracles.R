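# Independent oracles used across the suite.  Each deliberately avoids the
# package's own code paths: brute-force enumeration, grid search, or
# closed forms only.

# build a small genotype_matrix from a list of "X/Y" call strings
tiny_gm <- function(calls, snp_defs) {
  # calls: list of character vectors (one per subject), "X/Y" or "./."
  n <- length(calls)
  a1 <- t(vapply(calls, function(x) {
    v <- substr(x, 1, 1); v[v == "."] <- NA; v
  }, character(nrow(snp_defs))))
  a2 <- t(vapply(calls, function(x) {
    v <- substr(x, 3, 3); v[v == "."] <- NA; v
  }, character(nrow(snp_defs))))
  if (nrow(snp_defs) == 1) { a1 <- t(a1); a2 <- t(a2) }
  genotype_matrix(sprintf("T%02d", seq_len(n)), snp_defs, a1, a2)
}

# log-likelihood of two-locus haplotype frequencies for unphased genotype
# data, by direct summation over phase configurations; vectorized over a
# matrix F (rows = candidate frequency vectors over `haps`)
hap_loglik_2locus <- function(F, geno_a, geno_b, haps) {
  ll <- rep(0, nrow(F))
  for (i in seq_along(geno_a)) {
    ga <- sort(strsplit(geno_a[i], "")[[1]])
    gb <- sort(strsplit(geno_b[i], "")[[1]])
    pr <- rep(0, nrow(F))
    for (h1 in seq_along(haps)) for (h2 in seq_along(haps)) {
      al_a <- sort(c(substr(haps[h1], 1, 1), substr(haps[h2], 1, 1)))
      al_b <- sort(c(substr(haps[h1], 2, 2), substr(haps[h2], 2, 2)))
      if (identical(al_a, ga) && identical(al_b, gb))
        pr <- pr + F[, h1] * F[, h2]
    }
    ll <- ll + log(pr)
  }
  ll
}

# simplex grid of frequency vectors at resolution `by`; with a centre the
# grid is built locally (per-dimension window) instead of globally
.simplex_grid <- function(by, centre = NULL, window = NULL) {
  gdim <- function(k) {
    if (is.null(centre)) seq(0, 1, by = by)
    else seq(max(0, centre[k] - window), min(1, centre[k] + window),
             by = by)
  }
  F <- as.matrix(expand.grid(f1 = gdim(1), f2 = gdim(2), f3 = gdim(3)))
  F <- cbind(F, f4 = 1 - rowSums(F))
  F <- F[F[, 4] > -1e-12, , drop = FALSE]
  F[, 4] <- pmax(F[, 4], 0)
  F
}

# exhaustive grid maximization of the two-locus haplotype likelihood on
# the 3-simplex: coarse pass at 0.01, local refinement to `by`
grid_max_haplik <- function(geno_a, geno_b, haps, by = 1e-3) {
  F <- .simplex_grid(0.01)
  ll <- suppressWarnings(hap_loglik_2locus(F, geno_a, geno_b, haps))
  best <- F[which.max(ll), ]
  Ff <- .simplex_grid(by, centre = best, window = 0.015)
  llf <- suppressWarnings(hap_loglik_2locus(Ff, geno_a, geno_b, haps))
  list(loglik = max(llf, na.rm = TRUE),
       freqs = stats::setNames(Ff[which.max(llf), ], haps))
}

# two-sided Fisher exact p by full enumeration over the hypergeometric
# support (point-probability method)
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUROC by exhaustive pair counting
auroc_pairs <- function(scores, y) {
  cases <- scores[y == 1]; ctrls <- scores[y == 0]
  tot <- 0
  for (s1 in cases) for (s0 in ctrls)
    tot <- tot + (s1 > s0) + 0.5 * (s1 == s0)
  tot / (length(cases) * length(ctrls))
}

# 1-parameter (no intercept) logistic log-likelihood grid maximizer
logistic1_grid <- function(x, y, lo = -10, hi = 10, by = 1e-4) {
  b <- seq(lo, hi, by = by)
  ll <- vapply(b, function(bb) {
    p <- stats::plogis(bb * x)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }, numeric(1))
  b[which.max(ll)]
}

# two SNPs used by small fixtures
two_snp_defs <- function() {
  rbind(snp_def("snpA", "G1", "A", "a", "a", 0.3, "carrier_dominant"),
        snp_def("snpB", "G1", "B", "b", "b", 0.3, "carrier_dominant"))
}
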