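---
title: "Methods: pharmacogenetic analysis of warfarin bleeding risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacogenetic analysis of warfarin bleeding risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxbleed)
```

## The scientific setting

Patients on long-term warfarin after mechanical heart valve replacement
can bleed even while their INR sits inside the therapeutic 2–3 window,
so INR monitoring alone does not explain bleeding risk. The
renin–angiotensin system (RAS) modulates both vascular remodelling and
the coagulation–fibrinolysis balance (ACE degrades bradykinin, a driver
of tissue plasminogen activator release; angiotensin II induces
plasminogen activator inhibitor-1), which makes RAS polymorphisms
plausible modifiers of bleeding risk on anticoagulants. `pgxbleed`
implements the complete statistical chain for a case–control analysis of
that hypothesis in a small cohort (~140 subjects, ~15% incidence):
grouped-genotype association, *ACE* haplotype analysis, multivariable
logistic modelling, genotype-guided screening statistics, and a
cross-validated model benchmark — together with a synthetic cohort
generator that makes every stage testable.

## Genotype representation and grouping models

Unphased diploid calls are stored as unordered allele pairs
(`genotype_matrix()`); allele order in the input carries no meaning and
is normalized away. Each SNP definition (`snp_def()`) declares a
reference and a variant allele (the two sides of the annotated allele
change, e.g. `T>G`), which of the two is *minor* in the study
population, and a grouping model mapping genotypes onto a binary
exposure:

* `carrier_dominant` — exposed = at least one variant allele;
* `variant_recessive` — exposed = not homozygous for the variant allele;
* `het_vs_ref` — exposed = heterozygote (used where the variant
  homozygote is absent from the cohort).

The distinction between *variant* and *minor* matters: at several RAS
loci in East-Asian cohorts (e.g. *ACE* rs1800764/rs4341/rs4353, *AGT*
rs699, *AGTR1* rs2640543) the derived allele is the common one, so the
reference-table minor-allele frequency refers to the ancestral allele.
The 16-SNP panel with its frequencies and grouping models is exposed as
`ras_snp_defs()`.

Missing calls (`./.`) are retained in the container and handled
complete-case *per analysis* (`complete_case_subset()`), not globally:
published cohort tables show varying row denominators, and a global
complete-case rule would silently shrink every analysis to the
intersection.

## Association testing

Every exposure is tested against the binary bleeding outcome in a 2×2
table. The test is Pearson's chi-square **without** continuity
correction when all expected cell counts are ≥ 5, and Fisher's exact
test (two-sided, point-probability method) otherwise. This switching
rule was chosen because it reproduces the published p-values for the
significant rows and the exact-test rows alike; its one known limitation
is that a couple of published non-significant sparse rows appear to have
been computed by chi-square regardless (their Fisher p differs in the
second decimal), which does not affect any selection decision.

Odds ratios use the cross-product with Woolf's log-method interval,

$$\mathrm{OR} = \frac{ad}{bc}, \qquad
\mathrm{CI} = \exp\!\left(\ln \mathrm{OR} \pm z_{1-\alpha/2}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right),$$

with the Haldane–Anscombe +0.5 correction (flagged) when a single cell
is zero. The univariate screen selects exposures with p < 0.05 and
always carries the clinical confounders (age ≥ 65, sex) into the
multivariable candidate set. No multiple-testing correction is applied
by default, mirroring the candidate-gene convention of this literature;
`univariate_screen(adjust = "BH")` is available and its absence from the
default is a documented limitation.

## EM haplotype estimation, LD, and diplotypes

Haplotype frequencies at the *ACE* block are estimated by the standard
EM algorithm over phase ambiguity: the E-step distributes each subject's
genotype probability mass across all phase-consistent haplotype pairs
proportionally to $2 f_i f_j$ (or $f_i^2$), assuming random mating; the
M-step re-estimates frequencies from expected counts. Numerical
choices: initialization at the product of observed allele frequencies
(deterministic — no seed dependence, and for a near-linkage-equilibrium
start the trajectory is reproducible), convergence when the largest
frequency change falls below 1e-8, a 1,000-iteration cap with an
explicit `converged` flag, and aggregation over unique multi-locus
genotypes so cohort size only affects counting. The log-likelihood
trace is retained and asserted non-decreasing in the tests; for two-locus
problems the fixed point is checked against an exhaustive likelihood
grid search.

Pairwise LD derives from the EM two-locus frequencies:
$D = f_{AB} - f_A f_B$, $D' = D/D_{\max}$, $r^2 = D^2/(f_A f_a f_B f_b)$,
with $D_{\max}$ the usual sign-dependent bound. Haplotypes below a
reporting threshold (1% in the canonical analysis) are dropped and the
remainder renormalized, with the unfiltered set kept as provenance.

Diplotypes are hard maximum-posterior calls, because the protective
H2/H2 grouping in the published model implies hard assignment; the
posterior is retained on each call so a dosage-style sensitivity
analysis remains possible. Ties break lexicographically on the
haplotype strings. A subject whose genotype is incompatible with every
retained haplotype is called against the unfiltered set with a warning.
At the canonical frequencies the calls are nearly deterministic (> 95%
agreement with the latent truth in simulation): H1 and H2 dominate, and
the main ambiguous class (the triple heterozygote) resolves to H1/H2
with posterior odds of roughly 100:1 over the rival H4/H5 phase.

## Logistic modelling and diagnostics

The multivariable model is a binomial-logit GLM fitted by IRLS, with
Wald standard errors from the inverse observed information. Backward
elimination repeatedly removes the largest Wald p ≥ 0.05 and refits;
the elimination path is recorded and the final model is invariant to
candidate ordering. Wald-based elimination (rather than likelihood
ratio) matches the convention of the clinical statistics software this
style of analysis is usually run in. Age and sex *enter* the candidate
set but are not forced to stay — in the canonical analysis the final
model retains only the three genetic terms — and a `forced_in` argument
covers the alternative convention. Quasi-separation (|beta| > 15) and
aliased columns are flagged rather than silently accepted; no Firth
correction is applied.

Calibration uses the Hosmer–Lemeshow statistic over quantile groups of
fitted probability (ties kept together, group count reduced with a
warning when the fitted values cannot support it; df = g − 2). The
default is g = 10; the published model's "5 degrees of freedom"
corresponds to g = 7, and the tests verify that setting. Note the
grouping only forms when the fitted probabilities take enough distinct
values — a model of three binary indicators has at most 8, so
calibration checks are run on designs including a continuous covariate.
Discrimination uses the rank (Mann–Whitney) identity for the AUROC with
mid-rank tie handling.

## Screening statistics

For a risk term with adjusted odds ratio AOR (protective terms inverted
first, so the statistic describes *absence* of protection):

* attributable risk (%) = ((AOR − 1)/AOR) × 100;
* RRR = (AOR − 1)/AOR; ARR = RRR × Risk~no genotyping~; NNG = ⌈1/ARR⌉
  (ceiling, as number-needed quantities conventionally round up).

The baseline "risk without genotyping" has no unique definition. The
package default is the overall cohort incidence, which reproduces the
published NNG of 8 for the H2/H2 term; `nng_audit()` reports the
overall, per-term reference-group, and user-supplied conventions side by
side, because no single convention reproduces every published NNG value
— a worked illustration that the convention must be stated for the
statistic to be auditable.

The weighted risk score assigns each retained term the nearest integer
to its (re-coded) beta, with a floor of one point; at the canonical
effect sizes (ln 5.04, ln 3.17, −ln 0.12) the points are 2, 1 and 2 and
the maximum score is 5. Raw-beta scoring is available for sensitivity
analysis. Stratification at the 25th/75th percentiles uses inverse-ECDF
quantiles with a documented tie policy (low ≤ lower cut, high ≥ upper
cut, mid strictly interior); with heavily discrete scores the empirical
percentile can land inside the modal score and swallow the middle
stratum — indeed the published quartile group sizes (29/102/11 of 142)
are incompatible with *any* empirical-percentile cut, whose bottom group
must hold at least 25% of subjects. The published cut values therefore
act as explicit score thresholds, and `stratify_by_percentile(cuts = )`
accepts them as such; that is how the quartile odds ratios are
reproduced in the acceptance checks.

## The synthetic cohort generator

`sim_config()` defaults define the emulated study conditions:

* *ACE* haplotypes H1 `CGA` 41.8%, H2 `TCG` 47.0%, H3 `TCA` 4.7%, H4
  `CCG` 4.1%, H5 `TGA` 1.4%; the residual 1% (real cohorts carry rare
  haplotypes below the reporting threshold) is assigned to H1, making
  its generating frequency 0.428. Two haplotypes per subject are drawn
  independently (Hardy–Weinberg) and collapsed to unphased genotypes.
* Non-*ACE* SNPs under Hardy–Weinberg at the panel minor-allele
  frequencies, with no cross-gene LD (none is reported to emulate).
* Binary covariates as independent Bernoulli draws at the published
  prevalences (e.g. atrial fibrillation 87/142). Independence is a
  modelling choice forced by the information available — only marginal
  prevalences and marginal (adjusted) odds ratios are published, so the
  joint exposure–covariate dependence is unconstrained. Passing tests
  on these cohorts therefore demonstrates correctness of the estimators
  under the stated generative model, not robustness to the confounding
  structure of real cohorts.
* Outcome: Bernoulli(logistic(b₀ + Σ β·exposure)) with default betas
  ln 5.04 (rs5050 carrier), ln 3.17 (rs2640543 carrier), ln 0.12 (H2/H2
  diplotype indicator, encoded directly with its negative coefficient),
  and b₀ calibrated by `calibrate_intercept()` — exact enumeration over
  the discrete exposure distribution, not simulation — so the expected
  marginal incidence equals 21/142 to 1e-6.
* Missingness injected completely at random at a configurable per-call
  rate (default 0).

The truth record (latent haplotype pairs, intercept, design matrix,
linear predictor) supports recovery tests: EM recovers the generating
haplotype frequencies within 0.01 at n = 10,000; the three-term logistic
fit recovers the rs5050 adjusted OR within 5% at n = 100,000; and the
enumerated *marginal* crude OR (`marginal_crude_or()`, ≈ 4.37 for
rs5050) is deliberately distinct from the conditional exp(β) = 5.04 —
non-collapsibility of the odds ratio, which the tests also verify.

## Cross-validated benchmark

`repeated_cv_auroc()` runs repeated (default 10×) stratified 5-fold
cross-validation for logistic regression, elastic net (`glmnet`), random
forest (`randomForest`), and linear/RBF SVMs (`e1071`). Hyperparameters
are tuned on an inner stratified 3-fold grid — mixing parameter
0.1, …, 1.0 with the automatic penalty path for the elastic net; 500
trees with mtry ∈ {√p, p/3} for the forest; cost 2⁻⁵…2⁵ for the SVMs
with the RBF width from the median heuristic scaled by
{0.1, 1, 10} — chosen as conventional defaults (the original analysis
reports none) and overridable through `grids`. Inner tuning exists to
keep the outer folds untouched by selection. Margin classifiers are
scored by decision values, which are rank-equivalent to probabilities
for AUROC and avoid a calibration dependence. Fold assignments depend
only on the outcome, k, repeats, and seed, so learners compared under
one seed are paired on identical folds (`compare_models()` enforces
this). The summary interval is the normal approximation across the 10
repeat means. Published AUROCs from the real cohort (≈ 0.67–0.74
across learners) depend on the deposited data and original tuning, so
only range-level agreement is checkable synthetically.

## Problem sizes and determinism

The test suite fixes all seeds and uses n = 10,000 for haplotype/LD
recovery, n = 100,000 for adjusted-OR recovery, 120–200 replicates at
n = 1,000–2,000 for coverage and selection Monte-Carlo checks, and
142-subject cohorts for the benchmark contract tests — sizes at which
the Monte-Carlo bands in the tests are comfortably wider than the
sampling noise. The whole suite runs in well under a minute on one
core. `scripts/acceptance.R` re-runs the headline computations from
scratch at the same sizes, seeded from its `--seed` argument.

## Known limitations

* Covariates and non-*ACE* genotypes are simulated independently; a
  correlation hook exists but no published joint structure constrains
  it.
* The chi-square/Fisher switching rule reproduces the decisive published
  p-values; two sparse non-significant rows suggest the original
  analysis used chi-square throughout.
* No multiple-testing correction by default; no Firth correction for
  separation; no time-to-event modelling (follow-up time is carried as
  metadata only); no HWE exact tests or trend tests.
* VCF ingestion handles biallelic GT fields only; multi-allelic records
  and imputation are out of scope.
* The demo cohort reproduces published *margins* exactly, but its joint
  structure is arbitrary; only margin-level statistics computed from it
  are meaningful.
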