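#' Pairwise linkage disequilibrium (D-prime and r-squared)
#'
#' Two-locus haplotype frequencies are estimated by
#' [em_haplotype_frequencies()] on the SNP pair, then the classical
#' normalized statistics are computed with A/B the variant alleles of the
#' two SNPs:
#' \deqn{D = f(AB) - f(A) f(B)}
#' \deqn{D' = D / D_{max}, \quad D_{max} = \min(f(A)f(b), f(a)f(B))
#'   \textrm{ if } D > 0 \textrm{ else } \min(f(A)f(B), f(a)f(b))}
#' \deqn{r^2 = D^2 / (f(A)f(a)f(B)f(b))}
#' `|D'| = 1` whenever at most three of the four two-locus haplotypes
#' have positive frequency.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @return Object of class `ld_stats`: `snp_a`, `snp_b`, `d`, `d_prime`
#'   (absolute value), `r2`, `hap_freqs_2locus`, `n_subjects`.
#' @export
pairwise_ld <- function(gm, snp_a, snp_b) {
  hs <- em_haplotype_frequencies(gm, c(snp_a, snp_b))
  f <- stats::setNames(hs$freqs, hs$haplotypes)
  defs <- gm$snps
  va <- defs$var_allele[defs$snp_id == snp_a]
  vb <- defs$var_allele[defs$snp_id == snp_b]
  al_a <- unique(substr(hs$haplotypes, 1, 1))
  al_b <- unique(substr(hs$haplotypes, 2, 2))
  if (length(al_a) < 2 || length(al_b) < 2)
    stop("LD undefined: monomorphic SNP (",
         if (length(al_a) < 2) snp_a else snp_b, ")")
  pA <- sum(f[substr(names(f), 1, 1) == va])
  pB <- sum(f[substr(names(f), 2, 2) == vb])
  fAB <- sum(f[names(f) == paste0(va, vb)])
  D <- fAB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else       min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax == 0) 0 else abs(D / dmax)
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(snp_a = snp_a, snp_b = snp_b, d = D,
                 d_prime = d_prime, r2 = r2,
                 hap_freqs_2locus = f, n_subjects = hs$n_subjects),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD %s-%s: D' = %.3f, r2 = %.3f (n = %d)\n",
              x$snp_a, x$snp_b, x$d_prime, x$r2, x$n_subjects))
  invisible(x)
}
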