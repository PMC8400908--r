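#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the statistical structure of the study cohort: the
#' five canonical ACE haplotypes (H1 `CGA` 41.8%, H2 `TCG` 47.0%, H3
#' `TCA` 4.7%, H4 `CCG` 4.1%, H5 `TGA` 1.4%; the residual 1% is assigned
#' to H1), Hardy-Weinberg genotypes at the 13 non-ACE panel SNPs from
#' their reference minor-allele frequencies, independent binary covariates
#' at the published prevalences, and a logistic outcome with the three
#' adjusted effect sizes of the final multivariable model (rs5050 G
#' carrier OR 5.04, rs2640543 A carrier OR 3.17, ACE H2/H2 OR 0.12),
#' intercept calibrated so the expected marginal incidence equals the
#' cohort's 21/142.
#'
#' `effect_betas` names may be panel SNP ids (their carrier encoding is
#' the exposure), `"ace_h2h2"` (the H2-homozygote diplotype indicator), or
#' covariate names.
#'
#' @param n_subjects cohort size.
#' @param ace_haplotypes named numeric vector: three-locus haplotype
#'   (rs1800764-rs4341-rs4353 allele string) -> frequency.  Frequencies
#'   must be nonnegative; any residual mass is added to the first entry,
#'   then the vector is normalized to sum to one.
#' @param snp_mafs named vector of minor-allele frequencies for non-ACE
#'   SNPs (defaults from the panel definitions).
#' @param covariate_prevalences named vector of Bernoulli prevalences.
#' @param effect_betas named vector of log-odds effects.
#' @param target_incidence expected marginal outcome probability.
#' @param missing_rate per-call completely-at-random missingness rate.
#' @param seed integer seed (used by [simulate_cohort()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 142,
                       ace_haplotypes = ace_haplotype_freqs(),
                       snp_mafs = NULL,
                       covariate_prevalences = c(
                         sex_male = 52 / 142, age_ge_65 = 46 / 142,
                         hypertension = 39 / 142, diabetes = 13 / 142,
                         chronic_heart_failure = 32 / 142,
                         atrial_fibrillation = 87 / 142,
                         myocardial_infarction = 4 / 142),
                       effect_betas = c(rs5050 = log(5.04),
                                        rs2640543 = log(3.17),
                                        ace_h2h2 = log(0.12)),
                       target_incidence = 21 / 142,
                       missing_rate = 0,
                       seed = 1L) {
  defs <- ras_snp_defs()
  if (is.null(snp_mafs)) {
    non_ace <- defs[defs$gene != "ACE", ]
    snp_mafs <- stats::setNames(non_ace$maf, non_ace$snp_id)
  }
  if (any(ace_haplotypes < 0)) stop("haplotype frequencies must be >= 0")
  resid <- 1 - sum(ace_haplotypes)
  if (resid > 0) ace_haplotypes[1] <- ace_haplotypes[1] + resid
  ace_haplotypes <- ace_haplotypes / sum(ace_haplotypes)
  if (any(snp_mafs < 0 | snp_mafs > 0.5))
    stop("snp_mafs must lie in [0, 0.5]")
  if (target_incidence <= 0 || target_incidence >= 1)
    stop("target_incidence must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  structure(list(n_subjects = n_subjects, ace_haplotypes = ace_haplotypes,
                 snp_mafs = snp_mafs,
                 covariate_prevalences = covariate_prevalences,
                 effect_betas = effect_betas,
                 target_incidence = target_incidence,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 snp_defs = defs),
            class = "sim_config")
}

# frequency of the variant allele of a panel SNP implied by the config
.variant_freq <- function(cfg, snp_id) {
  def <- cfg$snp_defs[cfg$snp_defs$snp_id == snp_id, ]
  if (def$gene == "ACE") {
    loci <- ace_loci()
    pos <- match(snp_id, loci)
    al <- substr(names(cfg$ace_haplotypes), pos, pos)
    return(sum(cfg$ace_haplotypes[al == def$var_allele]))
  }
  maf <- cfg$snp_mafs[[snp_id]]
  if (def$minor_allele == def$var_allele) maf else 1 - maf
}

# marginal Bernoulli probability of one model term under the config
.term_prob <- function(cfg, term) {
  if (term == "ace_h2h2") {
    h2 <- cfg$ace_haplotypes[[ace_h2()]]
    return(h2^2)
  }
  if (term %in% cfg$snp_defs$snp_id) {
    q <- .variant_freq(cfg, term)             # variant-allele frequency
    def <- cfg$snp_defs[cfg$snp_defs$snp_id == term, ]
    return(switch(def$grouping,
                  carrier_dominant  = 1 - (1 - q)^2,
                  variant_recessive = 1 - q^2,
                  het_vs_ref        = 2 * q * (1 - q)))
  }
  if (term %in% names(cfg$covariate_prevalences))
    return(cfg$covariate_prevalences[[term]])
  stop("cannot resolve effect term: ", term)
}

# joint distribution over the 2^m strata of the (independent) model terms
.term_strata <- function(cfg) {
  terms <- names(cfg$effect_betas)
  probs <- vapply(terms, function(t) .term_prob(cfg, t), numeric(1))
  if (length(terms) == 0)
    return(list(design = matrix(0, 1, 0), prob = 1, lp = 0))
  design <- as.matrix(expand.grid(rep(list(0:1), length(terms))))
  colnames(design) <- terms
  prob <- apply(design, 1, function(x) prod(ifelse(x == 1, probs, 1 - probs)))
  lp <- drop(design %*% cfg$effect_betas)
  list(design = design, prob = prob, lp = lp)
}

#' Calibrate the outcome-model intercept by exact enumeration
#'
#' Solves for the intercept `b0` such that the expected marginal incidence
#' `E[logit^-1(b0 + sum(beta * exposure))]`, computed by exact summation
#' over the discrete joint distribution of the (independent) exposure
#' terms — not by simulation — equals `target_incidence`.  Deterministic;
#' accurate to `1e-9`.
#'
#' @param cfg a [sim_config()].
#' @return The intercept (log-odds scale).
#' @export
calibrate_intercept <- function(cfg) {
  st <- .term_strata(cfg)
  f <- function(b0) sum(st$prob * stats::plogis(b0 + st$lp)) -
    cfg$target_incidence
  sol <- tryCatch(stats::uniroot(f, c(-40, 40), tol = 1e-12),
                  error = function(e)
                    stop("target incidence unattainable: ",
                         conditionMessage(e)))
  sol$root
}

#' Expected marginal incidence under a configuration, by enumeration
#' @param cfg a [sim_config()].
#' @param intercept model intercept (default: calibrated).
#' @return Expected outcome probability.
#' @export
expected_incidence <- function(cfg, intercept = calibrate_intercept(cfg)) {
  st <- .term_strata(cfg)
  sum(st$prob * stats::plogis(intercept + st$lp))
}

#' Marginal (crude) odds ratio implied by the generative model
#'
#' For one effect term, computes the population crude odds ratio of
#' outcome given exposure by exhaustive summation over the exposure
#' strata — the value a 2x2 table converges to at large n, which differs
#' from the conditional (adjusted) OR `exp(beta)` by non-collapsibility.
#'
#' @param cfg a [sim_config()].
#' @param term name of an effect term.
#' @return The marginal crude OR.
#' @export
marginal_crude_or <- function(cfg, term) {
  st <- .term_strata(cfg)
  if (!term %in% colnames(st$design)) stop("term has no effect: ", term)
  b0 <- calibrate_intercept(cfg)
  r <- stats::plogis(b0 + st$lp)
  e <- st$design[, term] == 1
  p1 <- sum(st$prob[e] * r[e]) / sum(st$prob[e])
  p0 <- sum(st$prob[!e] * r[!e]) / sum(st$prob[!e])
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' Simulate a cohort with the study's statistical structure
#'
#' Each subject receives two ACE haplotypes drawn independently from
#' `ace_haplotypes` (Hardy-Weinberg), collapsed to unphased three-SNP
#' genotypes; every non-ACE panel SNP is drawn under Hardy-Weinberg from
#' its minor-allele frequency; binary covariates are independent
#' Bernoulli draws at their prevalences; the bleeding outcome is
#' Bernoulli(logistic(intercept + sum(beta * exposure))) with the
#' intercept from [calibrate_intercept()].  Identical seeds give
#' identical cohorts.
#'
#' @param cfg a [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()]), `phenotypes`
#'   (data frame), and `truth` (latent haplotype pairs, intercept, term
#'   design matrix and linear predictor).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  defs <- cfg$snp_defs
  subjects <- sprintf("S%05d", seq_len(n))

  haps <- names(cfg$ace_haplotypes)
  hap1 <- sample(haps, n, replace = TRUE, prob = cfg$ace_haplotypes)
  hap2 <- sample(haps, n, replace = TRUE, prob = cfg$ace_haplotypes)

  p <- nrow(defs)
  a1 <- a2 <- matrix(NA_character_, n, p)
  for (j in seq_len(p)) {
    def <- defs[j, ]
    if (def$gene == "ACE") {
      pos <- match(def$snp_id, ace_loci())
      a1[, j] <- substr(hap1, pos, pos)
      a2[, j] <- substr(hap2, pos, pos)
    } else {
      q <- .variant_freq(cfg, def$snp_id)
      pick <- function() ifelse(stats::runif(n) < q,
                                def$var_allele, def$ref_allele)
      a1[, j] <- pick(); a2[, j] <- pick()
    }
  }
  l1 <- a1; l2 <- a2   # latent (pre-missingness) genotypes
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
    a1[miss] <- NA; a2[miss] <- NA
  }
  gm <- genotype_matrix(subjects, defs, a1, a2)

  cov_names <- names(cfg$covariate_prevalences)
  covs <- vapply(cov_names, function(cv)
    as.integer(stats::runif(n) < cfg$covariate_prevalences[[cv]]),
    integer(n))
  covs <- as.data.frame(covs)

  pt <- data.frame(subject_id = subjects, covs,
                   stringsAsFactors = FALSE)
  if ("age_ge_65" %in% names(pt))
    pt$age_years <- ifelse(pt$age_ge_65 == 1,
                           65L + sample.int(15L, n, replace = TRUE) - 1L,
                           40L + sample.int(25L, n, replace = TRUE) - 1L)
  pt$inr_mean <- round(stats::rnorm(n, 2.44, 0.10), 2)
  pt$followup_years <- round(pmax(stats::rnorm(n, 14.3, 6.4), 0.5), 1)

  # exposures for the outcome model, from latent truth
  terms <- names(cfg$effect_betas)
  X <- matrix(0L, n, length(terms), dimnames = list(subjects, terms))
  for (t in terms) {
    X[, t] <- if (t == "ace_h2h2") {
      as.integer(hap1 == ace_h2() & hap2 == ace_h2())
    } else if (t %in% defs$snp_id) {
      # encode from the pre-missingness latent genotype
      jj <- match(t, defs$snp_id)
      def <- defs[jj, ]
      la1 <- l1[, jj]; la2 <- l2[, jj]
      nv <- (la1 == def$var_allele) + (la2 == def$var_allele)
      switch(def$grouping,
             carrier_dominant  = as.integer(nv >= 1),
             variant_recessive = as.integer(nv < 2),
             het_vs_ref        = as.integer(nv == 1))
    } else as.integer(pt[[t]])
  }
  b0 <- calibrate_intercept(cfg)
  lp <- b0 + drop(X %*% cfg$effect_betas)
  pt$bleeding <- as.integer(stats::runif(n) < stats::plogis(lp))

  truth <- list(hap1 = hap1, hap2 = hap2, intercept = b0,
                design = X, linear_predictor = lp,
                effect_betas = cfg$effect_betas)
  list(genotypes = gm, phenotypes = pt, truth = truth)
}

#' Permute the outcome labels (null-model harness)
#'
#' Uniformly permutes the `bleeding` column, leaving every other field
#' untouched; the outcome mean is preserved exactly.
#'
#' @param pt phenotype data frame with `bleeding`.
#' @param seed integer seed.
#' @return The phenotype table with permuted outcome.
#' @export
permute_outcome <- function(pt, seed) {
  if (!"bleeding" %in% names(pt)) stop("no outcome column to permute")
  set.seed(seed)
  pt$bleeding <- pt$bleeding[sample.int(nrow(pt))]
  pt
}
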