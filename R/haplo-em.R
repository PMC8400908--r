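#' EM estimation of multi-locus haplotype frequencies
#'
#' Standard expectation-maximization over phase ambiguity for unphased
#' diploid genotypes at a small set of biallelic loci.  The E-step
#' distributes each subject's genotype mass over all phase-consistent
#' haplotype pairs in proportion to the current pair probabilities
#' (`2*f_i*f_j` off-diagonal, `f_i^2` diagonal, i.e. random mating); the
#' M-step re-estimates frequencies from the expected haplotype counts.
#' Initialization is the product of observed allele frequencies
#' (deterministic — no seed dependence); iteration stops when the maximum
#' absolute frequency change falls below `tol`.
#'
#' Subjects with a missing call at any of the loci are excluded
#' (complete-case).  Computation is aggregated over unique multi-locus
#' genotypes, so cohort size only affects the counting step.
#'
#' @param gm a [genotype_matrix()].
#' @param loci SNP ids forming the haplotype block (<= 8; the haplotype
#'   space is exponential in the number of loci).
#' @param tol convergence tolerance on the frequency change.
#' @param max_iter maximum EM iterations; if reached, the result is
#'   returned with `converged = FALSE` and a warning.
#' @return An object of class `haplotype_set`: `loci`, `haplotypes`
#'   (allele strings), `freqs` (summing to one), `loglik_trace`,
#'   `n_iter`, `converged`, `n_subjects` (complete cases used).
#' @export
em_haplotype_frequencies <- function(gm, loci = ace_loci(), tol = 1e-8,
                                     max_iter = 1000L) {
  jj <- match(loci, gm$snps$snp_id)
  if (anyNA(jj)) stop("loci not in genotype matrix: ",
                      paste(loci[is.na(jj)], collapse = ", "))
  if (length(loci) > 8) stop("haplotype block too long (> 8 loci)")
  a1 <- gm$a1[, jj, drop = FALSE]; a2 <- gm$a2[, jj, drop = FALSE]
  complete <- rowSums(is.na(a1) | is.na(a2)) == 0
  if (!any(complete)) stop("no subjects with complete genotypes at loci")
  a1 <- a1[complete, , drop = FALSE]; a2 <- a2[complete, , drop = FALSE]

  geno_key <- apply(matrix(paste0(pmin(a1, a2), pmax(a1, a2)),
                           nrow = nrow(a1)), 1, paste, collapse = "|")
  counts <- table(geno_key)
  uniq <- names(counts); nct <- as.numeric(counts)

  # per unique genotype, enumerate phase-consistent haplotype pairs
  pair_list <- lapply(uniq, function(g) {
    gl <- strsplit(strsplit(g, "|", fixed = TRUE)[[1]], "")
    het <- vapply(gl, function(x) x[1] != x[2], logical(1))
    nh <- sum(het)
    if (nh <= 1) {
      h1 <- vapply(gl, `[`, "", 1); h2 <- vapply(gl, `[`, "", 2)
      return(matrix(c(paste(h1, collapse = ""),
                      paste(h2, collapse = "")), ncol = 2))
    }
    het_idx <- which(het)
    # fix the first het locus's assignment to kill the mirror duplicates
    combos <- as.matrix(expand.grid(rep(list(0:1), nh - 1)))
    t(apply(combos, 1, function(flip) {
      h1 <- vapply(gl, `[`, "", 1); h2 <- vapply(gl, `[`, "", 2)
      fl <- het_idx[-1][flip == 1]
      tmp <- h1[fl]; h1[fl] <- h2[fl]; h2[fl] <- tmp
      c(paste(h1, collapse = ""), paste(h2, collapse = ""))
    }))
  })
  haps <- sort(unique(unlist(pair_list)))
  idx_list <- lapply(pair_list, function(m)
    cbind(match(m[, 1], haps), match(m[, 2], haps)))

  # init: product of observed allele frequencies
  f <- vapply(haps, function(h) {
    al <- strsplit(h, "")[[1]]
    prod(vapply(seq_along(al), function(k)
      mean(c(a1[, k], a2[, k]) == al[k]), numeric(1)))
  }, numeric(1))
  if (sum(f) == 0) f <- rep(1 / length(haps), length(haps))
  f <- f / sum(f)

  n2 <- 2 * sum(nct)
  loglik_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    newf <- numeric(length(haps))
    ll <- 0
    for (u in seq_along(uniq)) {
      idx <- idx_list[[u]]
      w <- ifelse(idx[, 1] == idx[, 2], f[idx[, 1]]^2,
                  2 * f[idx[, 1]] * f[idx[, 2]])
      tot <- sum(w)
      ll <- ll + nct[u] * log(tot)
      w <- w / tot
      inc <- nct[u] * w
      for (r in seq_len(nrow(idx))) {
        newf[idx[r, 1]] <- newf[idx[r, 1]] + inc[r]
        newf[idx[r, 2]] <- newf[idx[r, 2]] + inc[r]
      }
    }
    newf <- newf / n2
    loglik_trace <- c(loglik_trace, ll)
    delta <- max(abs(newf - f))
    f <- newf
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  keep <- f > 0
  structure(list(loci = loci, haplotypes = haps[keep],
                 freqs = unname(f[keep]) / sum(f[keep]),
                 loglik_trace = loglik_trace, n_iter = length(loglik_trace),
                 converged = converged, n_subjects = sum(nct)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d loci (%s), %d haplotypes, n = %d, %s\n",
              length(x$loci), paste(x$loci, collapse = "-"),
              length(x$haplotypes), x$n_subjects,
              if (x$converged) sprintf("converged in %d iterations", x$n_iter)
              else "NOT converged"))
  ord <- order(x$freqs, decreasing = TRUE)
  print(data.frame(haplotype = x$haplotypes[ord],
                   freq = round(x$freqs[ord], 4)), row.names = FALSE)
  invisible(x)
}

#' Drop haplotypes below a reporting frequency
#'
#' Removes haplotypes with estimated frequency below `min_freq` and
#' renormalizes the remainder for reporting; the unfiltered set is kept
#' in the `provenance` element.
#'
#' @param hs a `haplotype_set`.
#' @param min_freq frequency threshold (e.g. `0.01` to keep haplotypes
#'   above 1%).
#' @return The filtered `haplotype_set`.
#' @export
filter_haplotypes <- function(hs, min_freq) {
  keep <- hs$freqs >= min_freq
  if (!any(keep)) stop("no haplotype reaches frequency ", min_freq)
  out <- hs
  out$haplotypes <- hs$haplotypes[keep]
  out$freqs <- hs$freqs[keep] / sum(hs$freqs[keep])
  out$provenance <- list(unfiltered_haplotypes = hs$haplotypes,
                         unfiltered_freqs = hs$freqs,
                         min_freq = min_freq)
  out
}

#' Maximum-posterior diplotype assignment
#'
#' For each subject with complete genotypes at the block's loci, the most
#' probable phase-consistent haplotype pair under the estimated
#' frequencies (posterior proportional to `2*f_i*f_j`, or `f_i^2` for a
#' homozygous pair).  Ties are broken lexicographically on the
#' concatenated haplotype strings.  Subjects whose genotype is
#' incompatible with every retained haplotype are called against the
#' unfiltered set (with a warning) when provenance is available.
#'
#' @param hs a converged `haplotype_set`.
#' @param gm the [genotype_matrix()].
#' @return A data frame (class `diplotype_calls`): `subject_id`, `hap1`,
#'   `hap2` (sorted pair), `posterior`, `is_hom_for` (the haplotype
#'   string when the best pair is homozygous, else `NA`).  Subjects with
#'   missing calls at the block get `NA` rows.
#' @export
assign_diplotypes <- function(hs, gm) {
  jj <- match(hs$loci, gm$snps$snp_id)
  a1 <- gm$a1[, jj, drop = FALSE]; a2 <- gm$a2[, jj, drop = FALSE]
  complete <- rowSums(is.na(a1) | is.na(a2)) == 0
  key <- rep(NA_character_, length(gm$subjects))
  key[complete] <- apply(matrix(
    paste0(pmin(a1[complete, , drop = FALSE], a2[complete, , drop = FALSE]),
           pmax(a1[complete, , drop = FALSE], a2[complete, , drop = FALSE])),
    nrow = sum(complete)), 1, paste, collapse = "|")

  full_f <- stats::setNames(hs$freqs, hs$haplotypes)
  unfiltered <- !is.null(hs$provenance)
  if (unfiltered)
    backup_f <- stats::setNames(hs$provenance$unfiltered_freqs,
                                hs$provenance$unfiltered_haplotypes)

  best_for_key <- function(g) {
    gl <- strsplit(strsplit(g, "|", fixed = TRUE)[[1]], "")
    het <- vapply(gl, function(x) x[1] != x[2], logical(1))
    nh <- sum(het)
    pairs <- if (nh <= 1) {
      matrix(c(paste(vapply(gl, `[`, "", 1), collapse = ""),
               paste(vapply(gl, `[`, "", 2), collapse = "")), ncol = 2)
    } else {
      het_idx <- which(het)
      combos <- as.matrix(expand.grid(rep(list(0:1), nh - 1)))
      t(apply(combos, 1, function(flip) {
        h1 <- vapply(gl, `[`, "", 1); h2 <- vapply(gl, `[`, "", 2)
        fl <- het_idx[-1][flip == 1]
        tmp <- h1[fl]; h1[fl] <- h2[fl]; h2[fl] <- tmp
        c(paste(h1, collapse = ""), paste(h2, collapse = ""))
      }))
    }
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
    score_with <- function(fmap) {
      f1 <- fmap[pairs[, 1]]; f2 <- fmap[pairs[, 2]]
      w <- ifelse(pairs[, 1] == pairs[, 2], f1^2, 2 * f1 * f2)
      w[is.na(w)] <- 0
      w
    }
    w <- score_with(full_f)
    fellback <- FALSE
    if (sum(w) == 0 && unfiltered) {
      w <- score_with(backup_f)
      fellback <- TRUE
    }
    if (sum(w) == 0)
      return(list(hap1 = NA, hap2 = NA, post = NA, fellback = fellback))
    post <- w / sum(w)
    ord <- order(-post, pairs[, 1], pairs[, 2])   # lexicographic tie-break
    b <- ord[1]
    list(hap1 = pairs[b, 1], hap2 = pairs[b, 2], post = post[b],
         fellback = fellback)
  }

  uniq <- unique(key[!is.na(key)])
  lookup <- lapply(stats::setNames(uniq, uniq), best_for_key)
  if (any(vapply(lookup, `[[`, logical(1), "fellback")))
    warning("some genotypes incompatible with retained haplotypes; ",
            "called against the unfiltered set")
  get <- function(fld, mode) {
    v <- rep(if (identical(mode, "c")) NA_character_ else NA_real_,
             length(key))
    ok <- !is.na(key)
    v[ok] <- vapply(lookup[key[ok]], function(z) {
      val <- z[[fld]]
      if (identical(mode, "c")) as.character(val) else as.numeric(val)
    }, if (identical(mode, "c")) NA_character_ else NA_real_)
    v
  }
  out <- data.frame(subject_id = gm$subjects,
                    hap1 = get("hap1", "c"), hap2 = get("hap2", "c"),
                    posterior = get("post", "n"),
                    stringsAsFactors = FALSE)
  out$is_hom_for <- ifelse(!is.na(out$hap1) & out$hap1 == out$hap2,
                           out$hap1, NA_character_)
  class(out) <- c("diplotype_calls", class(out))
  out
}

#' Homozygote indicator for a named haplotype
#'
#' @param calls output of [assign_diplotypes()].
#' @param haplotype allele string (default the protective ACE H2, `TCG`).
#' @return Integer 0/1 vector (NA where the diplotype is uncalled).
#' @export
diplotype_indicator <- function(calls, haplotype = ace_h2()) {
  ifelse(is.na(calls$hap1), NA_integer_,
         as.integer(!is.na(calls$is_hom_for) &
                      calls$is_hom_for == haplotype))
}
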