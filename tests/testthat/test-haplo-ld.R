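test_that("single-locus EM equals observed allele frequencies at once", {
  defs <- ras_snp_defs()[ras_snp_defs()$snp_id == "rs5050", ]
  gm <- tiny_gm(list("T/T", "T/G", "G/G", "T/G", "T/T"), defs)
  hs <- em_haplotype_frequencies(gm, "rs5050")
  f <- stats::setNames(hs$freqs, hs$haplotypes)
  expect_equal(unname(f["G"]), 4 / 10)
  expect_equal(unname(f["T"]), 6 / 10)
  expect_true(hs$converged)
})

test_that("phase-unambiguous cohorts reduce EM to direct counting", {
  defs <- two_snp_defs()
  # nobody heterozygous at more than one site -> phase known
  gm <- tiny_gm(list(c("A/A", "B/B"), c("A/a", "B/B"),
                     c("A/A", "B/b"), c("a/a", "b/b")), defs)
  hs <- em_haplotype_frequencies(gm, c("snpA", "snpB"))
  f <- stats::setNames(hs$freqs, hs$haplotypes)
  # direct haplotype counts: AB x5, aB x1, Ab x1, ab x2 (wait: count)
  # S1: AB,AB; S2: AB,aB; S3: AB,Ab; S4: ab,ab
  expect_equal(unname(f["AB"]), 4 / 8)
  expect_equal(unname(f["aB"]), 1 / 8)
  expect_equal(unname(f["Ab"]), 1 / 8)
  expect_equal(unname(f["ab"]), 2 / 8)
})

test_that("EM fixed point matches the exhaustive-likelihood grid oracle", {
  defs <- two_snp_defs()
  cases <- list(
    # three subjects incl. one double heterozygote
    list(c("A/a", "B/b"), c("A/A", "B/B"), c("a/a", "B/b")),
    # two double heterozygotes pull toward coupling
    list(c("A/a", "B/b"), c("A/a", "B/b"), c("A/A", "B/B"),
         c("a/a", "b/b")),
    # mixed five-subject case
    list(c("A/A", "B/b"), c("A/a", "B/b"), c("a/a", "b/b"),
         c("A/a", "b/b"), c("A/A", "B/B")))
  haps <- c("AB", "Ab", "aB", "ab")
  for (calls in cases) {
    gm <- tiny_gm(calls, defs)
    hs <- em_haplotype_frequencies(gm, c("snpA", "snpB"))
    f_em <- stats::setNames(rep(0, 4), haps)
    f_em[hs$haplotypes] <- hs$freqs
    geno_a <- vapply(calls, function(x) gsub("/", "", x[1]), "")
    geno_b <- vapply(calls, function(x) gsub("/", "", x[2]), "")
    oracle <- grid_max_haplik(geno_a, geno_b, haps)
    expect_equal(unname(f_em[haps]), unname(oracle$freqs[haps]),
                 tolerance = 2e-3)
  }
})

test_that("EM log-likelihood is monotone and invariant to subject order", {
  sim <- simulate_cohort(sim_config(n_subjects = 400, seed = 31))
  hs <- em_haplotype_frequencies(sim$genotypes)
  expect_true(all(diff(hs$loglik_trace) >= -1e-9))
  expect_equal(sum(hs$freqs), 1, tolerance = 1e-9)
  # permute subjects: same frequencies
  gm <- sim$genotypes
  perm <- sample(seq_along(gm$subjects))
  gm2 <- genotype_matrix(gm$subjects[perm], gm$snps,
                         gm$a1[perm, ], gm$a2[perm, ])
  hs2 <- em_haplotype_frequencies(gm2)
  ord <- order(hs$haplotypes); ord2 <- order(hs2$haplotypes)
  expect_equal(hs$haplotypes[ord], hs2$haplotypes[ord2])
  expect_equal(hs$freqs[ord], hs2$freqs[ord2], tolerance = 1e-7)
})

test_that("EM excludes incomplete subjects and errors with none left", {
  defs <- two_snp_defs()
  gm <- tiny_gm(list(c("A/a", "./."), c("A/A", "B/B")), defs)
  hs <- em_haplotype_frequencies(gm, c("snpA", "snpB"))
  expect_equal(hs$n_subjects, 1L)
  gm2 <- tiny_gm(list(c("A/a", "./."), c("./.", "B/B")), defs)
  expect_error(em_haplotype_frequencies(gm2, c("snpA", "snpB")),
               "no subjects")
})

test_that("haplotype filtering keeps the >1% set and renormalizes", {
  hs <- structure(list(loci = ace_loci(),
                       haplotypes = c("CGA", "TCG", "TCA", "CCG", "TGA",
                                      "CCA"),
                       freqs = c(0.418, 0.470, 0.047, 0.041, 0.014, 0.005),
                       loglik_trace = 0, n_iter = 1L, converged = TRUE,
                       n_subjects = 142L),
                  class = "haplotype_set")
  hs$freqs <- hs$freqs / sum(hs$freqs)
  filt <- filter_haplotypes(hs, 0.01)
  expect_equal(length(filt$haplotypes), 5L)   # five haplotypes above 1%
  expect_equal(sum(filt$freqs), 1)
  expect_equal(filter_haplotypes(hs, 0)$haplotypes, hs$haplotypes)
  top <- filter_haplotypes(hs, 0.45)
  expect_equal(top$haplotypes, "TCG")
  expect_error(filter_haplotypes(hs, 0.99), "no haplotype")
})

test_that("diplotype posteriors follow frequency arithmetic", {
  # fully homozygous T/T C/C G/G -> (TCG, TCG), posterior 1, H2 homozygote
  defs <- ras_snp_defs()[match(ace_loci(), ras_snp_defs()$snp_id), ]
  gm <- tiny_gm(list(c("T/T", "C/C", "G/G"), c("C/T", "C/G", "A/G")), defs)
  hs <- structure(list(loci = ace_loci(),
                       haplotypes = c("CGA", "TCG", "TCA", "CCG", "TGA"),
                       freqs = c(0.418, 0.470, 0.047, 0.041, 0.014) / 0.99,
                       loglik_trace = 0, n_iter = 1L, converged = TRUE,
                       n_subjects = 2L),
                  class = "haplotype_set")
  calls <- assign_diplotypes(hs, gm)
  expect_equal(calls$hap1[1], "TCG")
  expect_equal(calls$posterior[1], 1)
  expect_equal(calls$is_hom_for[1], "TCG")
  expect_equal(diplotype_indicator(calls), c(1L, 0L))
  # the triple heterozygote is compatible with CGA/TCG (H1/H2) and
  # TGA/CCG (H5/H4) and CCA/TGG etc.; H1/H2 dominates the posterior
  expect_equal(sort(c(calls$hap1[2], calls$hap2[2])), c("CGA", "TCG"))
  # posterior ratio vs the H4/H5 phase exceeds 100:1
  expect_gt(calls$posterior[2],
            100 * (2 * 0.047 * 0.041) / (2 * 0.418 * 0.470))
})

test_that("diplotype calls recover the latent truth on synthetic data", {
  sim <- simulate_cohort(sim_config(n_subjects = 3000, seed = 32))
  hs <- em_haplotype_frequencies(sim$genotypes)
  calls <- assign_diplotypes(hs, sim$genotypes)
  truth <- paste(pmin(sim$truth$hap1, sim$truth$hap2),
                 pmax(sim$truth$hap1, sim$truth$hap2))
  called <- paste(calls$hap1, calls$hap2)
  expect_gt(mean(called == truth), 0.95)
  # every call is phase-consistent with the observed genotype
  for (k in seq_along(ace_loci())) {
    j <- match(ace_loci()[k], sim$genotypes$snps$snp_id)
    g_obs <- paste0(sim$genotypes$a1[, j], sim$genotypes$a2[, j])
    g_cal <- paste0(pmin(substr(calls$hap1, k, k), substr(calls$hap2, k, k)),
                    pmax(substr(calls$hap1, k, k), substr(calls$hap2, k, k)))
    expect_equal(g_cal, g_obs, ignore_attr = TRUE)
  }
})

test_that("LD statistics satisfy their algebraic identities", {
  # perfectly correlated SNPs -> D' = 1, r2 = 1
  defs <- two_snp_defs()
  gm <- tiny_gm(rep(list(c("A/A", "B/B"), c("a/a", "b/b"),
                         c("A/a", "B/b")), 4), defs)
  ld <- pairwise_ld(gm, "snpA", "snpB")
  expect_equal(ld$d_prime, 1, tolerance = 1e-6)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  # independent simulated SNPs -> r2 near 0
  sim <- simulate_cohort(sim_config(n_subjects = 50000, seed = 33))
  ld0 <- pairwise_ld(sim$genotypes, "rs5050", "rs2640543")
  expect_lt(ld0$r2, 0.01)
  expect_true(ld0$d_prime >= 0 && ld0$d_prime <= 1)
  # monomorphic SNP -> error
  gm_mono <- tiny_gm(list(c("A/A", "B/b"), c("A/A", "B/B")), defs)
  expect_error(pairwise_ld(gm_mono, "snpA", "snpB"), "monomorphic")
})

test_that("synthetic ACE pairs show the expected strong LD", {
  sim <- simulate_cohort(sim_config(n_subjects = 10000, seed = 34))
  pairs <- utils::combn(ace_loci(), 2)
  for (i in seq_len(ncol(pairs))) {
    ld <- pairwise_ld(sim$genotypes, pairs[1, i], pairs[2, i])
    expect_gte(ld$r2, 0.6)
    expect_gte(ld$d_prime, 0.8)
    expect_true(ld$r2 <= 1 && ld$d_prime <= 1)
  }
})
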