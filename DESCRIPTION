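Package: pgxbleed
Title: Pharmacogenetic Analysis of Warfarin Bleeding Risk in the
    Renin-Angiotensin System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for case-control pharmacogenetic analysis of
    bleeding complications during warfarin anticoagulation at therapeutic
    INR: grouped-genotype (carrier/recessive) association testing with
    Woolf odds-ratio confidence intervals, EM estimation of multi-locus
    haplotype frequencies with D'/r-squared linkage disequilibrium,
    multivariable logistic modelling with backward elimination and
    Hosmer-Lemeshow/AUROC diagnostics, attributable risk and
    number-needed-to-genotype statistics, a beta-coefficient weighted risk
    score with percentile stratification, and a repeated stratified
    cross-validated AUROC benchmark over logistic, elastic-net, random
    forest and support-vector models.  Includes a synthetic cohort
    generator with haplotype-structured genotypes, Hardy-Weinberg loci and
    a calibrated logistic outcome model so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
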