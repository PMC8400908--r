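#' Define a SNP for grouped-genotype analysis
#'
#' A SNP definition records the two alleles, which of them is the minor
#' allele (with its population frequency), and the grouping model that maps
#' the three diploid genotypes onto a binary "exposed" indicator:
#'
#' * `carrier_dominant` — exposed = carries at least one variant allele;
#' * `variant_recessive` — exposed = is *not* homozygous for the variant
#'   allele (the variant homozygote is the reference group);
#' * `het_vs_ref` — exposed = heterozygote (used when the variant
#'   homozygote is absent from the cohort).
#'
#' The "variant" allele is the derived allele of the annotated allele
#' change (e.g. `T>G`: reference T, variant G).  Note that the variant
#' allele need not be the minor allele: at several renin–angiotensin loci
#' in East-Asian cohorts the derived allele is the common one, so `maf`
#' always refers to `minor_allele`.
#'
#' @param snp_id rs identifier.
#' @param gene gene symbol.
#' @param ref_allele,var_allele single-base reference and variant alleles
#'   of the allele change.
#' @param minor_allele which of the two alleles is minor in the study
#'   population.
#' @param maf minor-allele frequency, in `[0, 0.5]`.
#' @param grouping one of `"carrier_dominant"`, `"variant_recessive"`,
#'   `"het_vs_ref"`.
#' @return A one-row data frame of class `snp_def`.
#' @export
snp_def <- function(snp_id, gene, ref_allele, var_allele, minor_allele,
                    maf, grouping = c("carrier_dominant",
                                      "variant_recessive",
                                      "het_vs_ref")) {
  grouping <- match.arg(grouping)
  stopifnot(nchar(ref_allele) == 1L, nchar(var_allele) == 1L)
  if (ref_allele == var_allele)
    stop("ref_allele and var_allele must differ for ", snp_id)
  if (!minor_allele %in% c(ref_allele, var_allele))
    stop("minor_allele must be one of the declared alleles for ", snp_id)
  if (!is.na(maf) && (maf < 0 || maf > 0.5))
    stop("maf must lie in [0, 0.5] for ", snp_id)
  out <- data.frame(snp_id = snp_id, gene = gene,
                    ref_allele = ref_allele, var_allele = var_allele,
                    minor_allele = minor_allele, maf = maf,
                    grouping = grouping, stringsAsFactors = FALSE)
  class(out) <- c("snp_def", class(out))
  out
}

#' The 16-SNP renin-angiotensin / warfarin panel
#'
#' Definitions for the candidate SNPs of the analysis: four in *AGT*, two
#' in *REN*, three in *ACE*, four in *AGTR1*, one in *AGTR2*, plus the two
#' canonical warfarin dose-response variants (*VKORC1* rs9934438, *CYP2C9*
#' rs1057910).  Minor-allele frequencies and grouping models follow the
#' study's reference table.
#'
#' @return A data frame with one row per SNP (class `snp_def`).
#' @export
ras_snp_defs <- function() {
  defs <- rbind(
    snp_def("rs9934438",  "VKORC1", "C", "T", "C", 0.113, "variant_recessive"),
    snp_def("rs1057910",  "CYP2C9", "A", "C", "C", 0.043, "het_vs_ref"),
    snp_def("rs7079",     "AGT",    "G", "T", "T", 0.128, "carrier_dominant"),
    snp_def("rs699",      "AGT",    "A", "G", "A", 0.180, "variant_recessive"),
    snp_def("rs11122576", "AGT",    "T", "C", "C", 0.401, "variant_recessive"),
    snp_def("rs5050",     "AGT",    "T", "G", "G", 0.165, "carrier_dominant"),
    snp_def("rs2368564",  "REN",    "C", "T", "T", 0.225, "carrier_dominant"),
    snp_def("rs12750834", "REN",    "G", "A", "A", 0.373, "carrier_dominant"),
    snp_def("rs1800764",  "ACE",    "C", "T", "C", 0.465, "variant_recessive"),
    snp_def("rs4341",     "ACE",    "G", "C", "G", 0.437, "variant_recessive"),
    snp_def("rs4353",     "ACE",    "A", "G", "A", 0.486, "variant_recessive"),
    snp_def("rs275651",   "AGTR1",  "T", "A", "A", 0.094, "carrier_dominant"),
    snp_def("rs2640543",  "AGTR1",  "A", "G", "A", 0.190, "variant_recessive"),
    snp_def("rs5182",     "AGTR1",  "C", "T", "C", 0.254, "carrier_dominant"),
    snp_def("rs5186",     "AGTR1",  "A", "C", "C", 0.060, "het_vs_ref"),
    snp_def("rs1403543",  "AGTR2",  "G", "A", "G", 0.310, "carrier_dominant"))
  class(defs) <- c("snp_def", "data.frame")
  defs
}

#' The ACE haplotype block
#'
#' Loci and canonical haplotypes of the *ACE* gene used throughout:
#' three-SNP haplotypes over rs1800764-rs4341-rs4353, labelled H1..H5 in
#' descending population frequency.  H2 (`TCG`) carries the variant allele
#' at every locus; H2 homozygotes form the protective diplotype group.
#'
#' @return `ace_loci()`: character vector of the three SNP ids, in
#'   haplotype order.  `ace_haplotype_freqs()`: named numeric vector of
#'   the five canonical haplotype frequencies (summing to 0.99; the
#'   residual mass belongs to rare haplotypes below 1%).
#' @export
ace_loci <- function() c("rs1800764", "rs4341", "rs4353")

#' @rdname ace_loci
#' @export
ace_haplotype_freqs <- function() {
  c(CGA = 0.418, TCG = 0.470, TCA = 0.047, CCG = 0.041, TGA = 0.014)
}

#' @rdname ace_loci
#' @export
ace_h2 <- function() "TCG"
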