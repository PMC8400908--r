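#' Demonstration cohort reproducing the published marginal counts
#'
#' A deterministic 142-subject cohort (21 bleeding cases, 121 controls)
#' whose per-variable margins reproduce the published cohort tables
#' exactly: every grouped-genotype split of the 16-SNP panel (including
#' the per-SNP missingness implied by the printed row totals — one
#' missing rs7079 call, three missing rs275651 calls), the covariate
#' prevalences, the comedication/valve-type denominators, and the ACE
#' block with 33 H2/H2 subjects (1 case, 32 controls).  Joint structure
#' beyond these margins (and the internal consistency of the ACE
#' three-locus genotypes) is arbitrary, so only margin-level statistics
#' — 2x2 tables, odds ratios, chi-square/Fisher p-values, group
#' percentages — are meaningful on it; it is synthetic, not patient
#' data.
#'
#' @return List with `genotypes` (a [genotype_matrix()]) and
#'   `phenotypes` (data frame).
#' @export
demo_cohort <- function() {
  n_case <- 21L; n_ctrl <- 121L; n <- n_case + n_ctrl
  subjects <- sprintf("D%03d", seq_len(n))
  bleeding <- c(rep(1L, n_case), rep(0L, n_ctrl))

  # deterministic spread of k positives within a class, offset by column
  place <- function(m, k, offset) {
    v <- integer(m)
    if (k > 0) v[((offset + seq_len(k) - 1L) %% m) + 1L] <- 1L
    v
  }
  bin_col <- function(k_case, k_ctrl, offset)
    c(place(n_case, k_case, offset), place(n_ctrl, k_ctrl, offset * 3L))

  pt <- data.frame(subject_id = subjects, bleeding = bleeding,
                   stringsAsFactors = FALSE)
  covs <- list(sex_male = c(8L, 44L), age_ge_65 = c(10L, 36L),
               hypertension = c(6L, 33L), diabetes = c(3L, 10L),
               chronic_heart_failure = c(7L, 25L),
               atrial_fibrillation = c(17L, 70L),
               myocardial_infarction = c(2L, 2L))
  for (i in seq_along(covs))
    pt[[names(covs)[i]]] <- bin_col(covs[[i]][1], covs[[i]][2], i * 5L)
  pt$age_years <- ifelse(pt$age_ge_65 == 1,
                         66L + (seq_len(n) %% 10L),
                         45L + (seq_len(n) %% 20L))

  # comedications: recorded for 19 cases and 101 controls only
  med <- list(acei = c(2L, 19L), arb = c(4L, 19L), antiplatelet = c(0L, 4L),
              ccb = c(4L, 19L), diuretics = c(9L, 35L), statins = c(0L, 4L),
              inr_increasing = c(0L, 1L), inr_decreasing = c(1L, 0L))
  med_case_n <- 19L; med_ctrl_n <- 101L
  for (i in seq_along(med)) {
    v <- c(place(med_case_n, med[[i]][1], i * 7L),
           rep(NA_integer_, n_case - med_case_n),
           place(med_ctrl_n, med[[i]][2], i * 11L),
           rep(NA_integer_, n_ctrl - med_ctrl_n))
    pt[[names(med)[i]]] <- v
  }

  rep_lv <- function(levels, counts) rep(levels, counts)
  pt$valve_position <- c(
    rep_lv(c("aortic", "mitral", "double", "tricuspid"), c(6, 9, 5, 1)),
    rep_lv(c("aortic", "mitral", "double", "tricuspid"), c(28, 66, 20, 7)))
  vt_lv <- c("SJM", "CarboMedics", "ATS", "MIRA", "Duromedics", "OnX",
             "other")
  pt$valve_type <- c(
    rep_lv(vt_lv, c(7, 6, 2, 1, 2, 0, 0)), rep(NA, 3),
    rep_lv(vt_lv, c(39, 32, 15, 9, 6, 4, 9)), rep(NA, 7))
  pt$inr_mean <- round(2.38 + 0.001 * seq_len(n), 2)
  pt$followup_years <- round(8 + (seq_len(n) %% 13), 1)

  defs <- ras_snp_defs()
  a1 <- a2 <- matrix(NA_character_, n, nrow(defs))

  # exposed/unexposed genotype representatives per grouping model
  geno_for <- function(def, exposed) {
    if (exposed) c(def$ref_allele, def$var_allele)       # heterozygote
    else switch(def$grouping,
                carrier_dominant  = rep(def$ref_allele, 2),
                variant_recessive = rep(def$var_allele, 2),
                het_vs_ref        = rep(def$ref_allele, 2))
  }
  # exposed counts (case, ctrl) and missing counts (case, ctrl), Table 2
  snp_counts <- list(
    rs9934438 = list(e = c(3L, 27L)),
    rs1057910 = list(e = c(3L, 9L), m = c(0L, 1L)),
    rs7079 = list(e = c(2L, 33L), m = c(0L, 1L)),
    rs699 = list(e = c(5L, 42L)),      rs11122576 = list(e = c(19L, 99L)),
    rs5050 = list(e = c(13L, 32L)),    rs2368564 = list(e = c(7L, 50L)),
    rs12750834 = list(e = c(14L, 69L)),
    rs275651 = list(e = c(3L, 22L), m = c(1L, 2L)),
    rs2640543 = list(e = c(11L, 36L)), rs5182 = list(e = c(18L, 115L)),
    rs5186 = list(e = c(3L, 14L)),     rs1403543 = list(e = c(18L, 101L)))
  for (s in names(snp_counts)) {
    j <- match(s, defs$snp_id)
    def <- defs[j, ]
    cnt <- snp_counts[[s]]
    miss <- if (is.null(cnt$m)) c(0L, 0L) else cnt$m
    # exposure placed among the non-missing head of each class; missing
    # calls occupy the tail, so the complete-case split matches exactly
    exp_vec <- c(place(n_case - miss[1], cnt$e[1], j * 13L),
                 rep(NA, miss[1]),
                 place(n_ctrl - miss[2], cnt$e[2], j * 39L),
                 rep(NA, miss[2]))
    g <- t(vapply(exp_vec, function(e) {
      if (is.na(e)) c(NA_character_, NA_character_)
      else geno_for(def, e == 1L)
    }, c("", "")))
    a1[, j] <- g[, 1]; a2[, j] <- g[, 2]
  }

  # ACE block: joint three-locus genotypes consistent with the printed
  # per-SNP margins and the 33 H2/H2 (TT/CC/GG) subjects
  ace_rows <- function(g1800764, g4341, g4353, rows) {
    for (k in seq_along(ace_loci())) {
      j <- match(ace_loci()[k], defs$snp_id)
      g <- list(g1800764, g4341, g4353)[[k]]
      a1[rows, j] <<- substr(g, 1, 1); a2[rows, j] <<- substr(g, 2, 2)
    }
  }
  ace_rows("TT", "CC", "GG", 1L)                      # case, H2/H2
  ace_rows("TT", "CC", "AA", 2:3)
  ace_rows("CT", "CG", "AG", 4:21)
  ctrl <- function(i) n_case + i
  ace_rows("TT", "CC", "GG", ctrl(1:32))              # controls, H2/H2
  ace_rows("CT", "CG", "GG", ctrl(33:37))
  ace_rows("TT", "CC", "AG", ctrl(38:48))
  ace_rows("CT", "CC", "AG", ctrl(49:50))
  ace_rows("CT", "CG", "AG", ctrl(51:121))

  list(genotypes = genotype_matrix(subjects, defs, a1, a2),
       phenotypes = pt)
}
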