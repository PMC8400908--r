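#' Construct a genotype matrix of unphased diploid calls
#'
#' The central genotype container: subjects x SNPs, each call an unordered
#' allele pair.  Calls are stored as two character matrices with the pair
#' sorted alphabetically, so allele order as supplied carries no meaning.
#'
#' @param subjects character vector of unique subject identifiers.
#' @param snp_defs a `snp_def` data frame (one row per SNP, in column
#'   order).
#' @param allele1,allele2 character matrices (subjects x SNPs) of single
#'   bases; `NA` in either marks a missing call.
#' @return An object of class `genotype_matrix` with elements `subjects`,
#'   `snps`, `a1`, `a2` (alphabetically ordered pair) and `missing_mask`.
#' @export
genotype_matrix <- function(subjects, snp_defs, allele1, allele2) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects))
    stop("subject identifiers must be unique")
  n <- length(subjects); p <- nrow(snp_defs)
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  if (!all(dim(allele1) == c(n, p)) || !all(dim(allele2) == c(n, p)))
    stop("allele matrices must be ", n, " x ", p)
  miss <- is.na(allele1) | is.na(allele2)
  allele1[miss] <- NA_character_; allele2[miss] <- NA_character_
  # validate alleles against each SNP's declared pair
  for (j in seq_len(p)) {
    ok <- c(snp_defs$ref_allele[j], snp_defs$var_allele[j])
    bad <- which(!miss[, j] &
                   (!(allele1[, j] %in% ok) | !(allele2[, j] %in% ok)))
    if (length(bad))
      stop(sprintf("invalid allele for SNP %s, subject %s: %s/%s",
                   snp_defs$snp_id[j], subjects[bad[1]],
                   allele1[bad[1], j], allele2[bad[1], j]))
  }
  # canonical unordered storage
  swap <- !miss & allele1 > allele2
  tmp <- allele1[swap]; allele1[swap] <- allele2[swap]; allele2[swap] <- tmp
  dimnames(allele1) <- dimnames(allele2) <- dimnames(miss) <-
    list(subjects, snp_defs$snp_id)
  structure(list(subjects = subjects, snps = snp_defs,
                 a1 = allele1, a2 = allele2, missing_mask = miss),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%d missing calls)\n",
              length(x$subjects), nrow(x$snps), sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$subjects), nrow(x$snps))

#' Read a genotype table from TSV
#'
#' One row per subject; first column `subject_id`, one column per SNP;
#' calls written `"X/Y"` (order-free) with `"./."` for missing.
#'
#' @param path path to the tab-separated file.
#' @param snp_defs `snp_def` data frame naming the SNPs expected in the
#'   header (extra file columns are an error; column order in the file is
#'   free).
#' @return A [genotype_matrix()].  Per-SNP missing-call counts are
#'   reported via `message()`.
#' @export
read_genotype_table <- function(path, snp_defs) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "subject_id")
    stop("first column must be 'subject_id'")
  snp_cols <- header[-1]
  missing_defs <- setdiff(snp_defs$snp_id, snp_cols)
  if (length(missing_defs))
    stop("SNP columns absent from file: ",
         paste(missing_defs, collapse = ", "))
  unknown <- setdiff(snp_cols, snp_defs$snp_id)
  if (length(unknown))
    stop("file columns with no SNP definition: ",
         paste(unknown, collapse = ", "))
  body <- fields[-1]
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop(sprintf("malformed row at line %d: %d fields, expected %d",
                 which(nf != length(header))[1] + 1L,
                 nf[nf != length(header)][1], length(header)))
  m <- do.call(rbind, body)
  subjects <- m[, 1]
  calls <- m[, -1, drop = FALSE]
  colnames(calls) <- snp_cols
  calls <- calls[, snp_defs$snp_id, drop = FALSE]
  ok <- grepl("^[ACGT.]/[ACGT.]$", calls)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable call '%s' for subject %s, SNP %s",
                 calls[bad[1], bad[2]], subjects[bad[1]],
                 snp_defs$snp_id[bad[2]]))
  }
  a1 <- substr(calls, 1, 1); a2 <- substr(calls, 3, 3)
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  dim(a1) <- dim(a2) <- dim(calls)
  gm <- genotype_matrix(subjects, snp_defs, a1, a2)
  nmiss <- colSums(gm$missing_mask)
  if (any(nmiss > 0))
    message("missing calls per SNP: ",
            paste(sprintf("%s=%d", names(nmiss)[nmiss > 0],
                          nmiss[nmiss > 0]), collapse = ", "))
  gm
}

#' Write a genotype matrix to the TSV dialect read by
#' [read_genotype_table()]
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @export
write_genotype_table <- function(gm, path) {
  calls <- matrix(paste0(gm$a1, "/", gm$a2), nrow = length(gm$subjects))
  calls[gm$missing_mask] <- "./."
  out <- cbind(subject_id = gm$subjects, calls)
  colnames(out) <- c("subject_id", gm$snps$snp_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Thin adapter onto [genotype_matrix()]: reads a VCF 4.x with a GT field,
#' accepting unphased (`0/1`) and phased (`0|1`) calls; phase is
#' discarded, since the container stores unordered allele pairs.
#' Requires the `vcfR` package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param snp_defs `snp_def` data frame; VCF records are matched on ID.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, snp_defs) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  keep <- match(snp_defs$snp_id, ids)
  if (anyNA(keep))
    stop("VCF lacks records for: ",
         paste(snp_defs$snp_id[is.na(keep)], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  ref <- unname(vcfR::getREF(v))[keep]; alt <- unname(vcfR::getALT(v))[keep]
  subjects <- colnames(gt)
  n <- length(subjects); p <- nrow(snp_defs)
  a1 <- a2 <- matrix(NA_character_, n, p)
  for (j in seq_len(p)) {
    g <- gsub("|", "/", gt[j, ], fixed = TRUE)
    parts <- strsplit(g, "/", fixed = TRUE)
    alle <- c(`0` = ref[j], `1` = alt[j])
    for (i in seq_len(n)) {
      pr <- parts[[i]]
      if (length(pr) == 2 && all(pr %in% c("0", "1"))) {
        a1[i, j] <- alle[pr[1]]; a2[i, j] <- alle[pr[2]]
      }
    }
  }
  genotype_matrix(subjects, snp_defs, a1, a2)
}

#' Read a phenotype/covariate table
#'
#' CSV or TSV (sniffed from the extension) with one row per subject.  A
#' column mapping may rename arbitrary source columns onto the canonical
#' names (`subject_id`, `bleeding`, binary covariates, ...).  Consistency
#' of `age_ge_65` with `age_years` is checked when both are present.
#'
#' @param path file path.
#' @param column_map optional named character vector,
#'   `canonical_name = source_name`.
#' @return A data frame keyed by `subject_id`.
#' @export
read_phenotype_table <- function(path, column_map = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  pt <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    idx <- match(column_map, names(pt))
    if (anyNA(idx))
      stop("column_map names absent from file: ",
           paste(column_map[is.na(idx)], collapse = ", "))
    names(pt)[idx] <- names(column_map)
  }
  if (!"subject_id" %in% names(pt)) stop("phenotype table needs subject_id")
  if ("bleeding" %in% names(pt) &&
      !all(pt$bleeding %in% c(0, 1, NA)))
    stop("bleeding must be binary 0/1")
  if (all(c("age_years", "age_ge_65") %in% names(pt))) {
    both <- !is.na(pt$age_years) & !is.na(pt$age_ge_65)
    if (any((pt$age_years[both] >= 65) != (pt$age_ge_65[both] == 1)))
      stop("age_ge_65 inconsistent with age_years")
  }
  pt
}

#' Binary exposure encoding of a grouped genotype
#'
#' Applies the SNP's declared grouping model (see [snp_def()]) to produce
#' the 0/1 exposure used in association and regression: 1 for subjects in
#' the pooled "exposed" genotype group, 0 for the reference group, `NA`
#' for missing calls.
#'
#' @param gm a `genotype_matrix`.
#' @param snp_id SNP to encode.
#' @return Named integer vector (subjects), values 0/1/NA.
#' @export
carrier_encode <- function(gm, snp_id) {
  j <- match(snp_id, gm$snps$snp_id)
  if (is.na(j)) stop("unknown SNP: ", snp_id)
  def <- gm$snps[j, ]
  if (is.na(def$grouping) || !nzchar(def$grouping))
    stop("no grouping declared for ", snp_id)
  nv <- (gm$a1[, j] == def$var_allele) + (gm$a2[, j] == def$var_allele)
  enc <- switch(def$grouping,
                carrier_dominant  = as.integer(nv >= 1),
                variant_recessive = as.integer(nv < 2),
                het_vs_ref        = as.integer(nv == 1),
                stop("unknown grouping: ", def$grouping))
  names(enc) <- gm$subjects
  enc
}

#' Assemble the analysis table of outcome and binary exposures
#'
#' Joins the phenotype outcome/covariates with grouped-genotype encodings
#' (and, optionally, a haplotype indicator) into one subject-aligned data
#' frame.  Missing values are retained; use [complete_case_subset()] per
#' analysis.
#'
#' @param gm `genotype_matrix` (or `NULL` for covariates only).
#' @param pt phenotype data frame with `subject_id` and `bleeding`.
#' @param snps character vector of SNP ids to carrier-encode.
#' @param covariates phenotype columns to carry over.
#' @param indicators optional named list of extra 0/1 vectors aligned to
#'   `gm$subjects` (e.g. a diplotype indicator).
#' @return Data frame with `subject_id`, `bleeding`, one column per
#'   exposure; attribute `n_complete` gives per-column non-missing counts.
#' @export
analysis_table <- function(gm, pt, snps = character(),
                           covariates = character(),
                           indicators = list()) {
  if (!is.null(gm)) {
    idx <- match(gm$subjects, pt$subject_id)
    if (anyNA(idx)) stop("phenotype table lacks some genotyped subjects")
    pt <- pt[idx, , drop = FALSE]
    subjects <- gm$subjects
  } else subjects <- pt$subject_id
  at <- data.frame(subject_id = subjects, bleeding = pt$bleeding,
                   stringsAsFactors = FALSE)
  for (cv in covariates) {
    if (!cv %in% names(pt)) stop("covariate not in phenotype table: ", cv)
    at[[cv]] <- pt[[cv]]
  }
  for (s in snps) at[[s]] <- unname(carrier_encode(gm, s))
  for (nm in names(indicators)) {
    v <- indicators[[nm]]
    if (length(v) != nrow(at)) stop("indicator ", nm, " wrong length")
    at[[nm]] <- as.integer(v)
  }
  if (anyDuplicated(names(at))) stop("duplicate column names")
  attr(at, "n_complete") <- colSums(!is.na(at))
  at
}

#' Complete-case subset for one analysis
#'
#' Drops subjects missing any of the requested columns — for that analysis
#' only, matching the varying per-row denominators of published cohort
#' tables rather than a global complete-case rule.
#'
#' @param at analysis table (data frame).
#' @param columns columns that must be non-missing.
#' @return The subsetted data frame; the number of dropped subjects is
#'   reported via `message()` and the `"n_dropped"` attribute.
#' @export
complete_case_subset <- function(at, columns) {
  missing_cols <- setdiff(columns, names(at))
  if (length(missing_cols))
    stop("columns absent: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(at[, columns, drop = FALSE])
  if (!any(keep))
    stop("no complete cases for [", paste(columns, collapse = ", "),
         "]; inspect missingness before analysis")
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " subject(s) dropped for incomplete [",
            paste(columns, collapse = ", "), "]")
  out <- at[keep, , drop = FALSE]
  attr(out, "n_dropped") <- dropped
  out
}
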