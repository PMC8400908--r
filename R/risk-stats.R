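#' Attributable risk from an adjusted odds ratio
#'
#' `AR(%) = ((AOR - 1) / AOR) * 100`, the fraction of exposed cases
#' attributable to the exposure.  For a protective term (`AOR < 1`) the
#' reciprocal is taken first, so the statistic refers to *absence* of the
#' protective factor; the inversion is recorded.
#'
#' @param aor adjusted odds ratio (> 0).
#' @return Numeric percentage with attributes `aor_used` and `inverted`.
#' @export
attributable_risk <- function(aor) {
  if (!is.numeric(aor) || aor <= 0) stop("aor must be positive")
  inverted <- aor < 1
  aor_used <- if (inverted) 1 / aor else aor
  structure((aor_used - 1) / aor_used * 100,
            aor_used = aor_used, inverted = inverted)
}

#' Number needed to genotype
#'
#' The paper-defined chain of statistics for one risk term:
#' `RRR = (AOR - 1)/AOR`, `ARR = RRR * risk_reference`,
#' `NNG = ceiling(1/ARR)` — the number of patients one must genotype to
#' prevent one additional bleeding complication.  Protective AORs are
#' inverted first (as in [attributable_risk()]).  The reference risk
#' ("risk without genotyping") is not uniquely defined by the published
#' analysis, so its provenance is a required, echoed input; see
#' [nng_audit()] for a side-by-side report of the common conventions.
#'
#' @param aor adjusted odds ratio.
#' @param risk_reference baseline risk in (0, 1).
#' @param reference provenance label for `risk_reference`
#'   (`"overall"` cohort incidence, `"refgroup"` incidence, or
#'   `"user"`).
#' @param term optional term name for reporting.
#' @return Object of class `risk_stat`: `term`, `aor_used`, `inverted`,
#'   `attributable_risk_pct`, `rrr`, `arr`, `nng`, `risk_reference`,
#'   `reference`, `impractical` (flag for near-null effects).
#' @export
nng <- function(aor, risk_reference,
                reference = c("overall", "refgroup", "user"),
                term = NA_character_) {
  reference <- match.arg(reference)
  if (risk_reference <= 0 || risk_reference >= 1)
    stop("risk_reference must lie in (0, 1)")
  ar <- attributable_risk(aor)
  aor_used <- attr(ar, "aor_used")
  rrr <- (aor_used - 1) / aor_used
  arr <- rrr * risk_reference
  if (rrr == 0)
    warning("null effect (AOR = 1): NNG is infinite")
  val <- if (arr > 0) ceiling(1 / arr) else Inf
  structure(list(term = term, aor_used = aor_used,
                 inverted = attr(ar, "inverted"),
                 attributable_risk_pct = as.numeric(ar),
                 rrr = rrr, arr = arr, nng = val,
                 risk_reference = risk_reference, reference = reference,
                 impractical = is.finite(val) && val > 1000),
            class = "risk_stat")
}

#' @export
print.risk_stat <- function(x, ...) {
  cat(sprintf(
    "%s: AOR used %.3f%s, AR %.1f%%, RRR %.3f, ARR %.4f, NNG %s (ref risk %.4f, %s)%s\n",
    if (is.na(x$term)) "risk term" else x$term, x$aor_used,
    if (x$inverted) " (inverted protective OR)" else "",
    x$attributable_risk_pct, x$rrr, x$arr,
    format(x$nng), x$risk_reference, x$reference,
    if (x$impractical) " [impractically large]" else ""))
  invisible(x)
}

#' Audit NNG under the candidate reference-risk conventions
#'
#' Reports the NNG for each term under every supplied convention side by
#' side, since the definition of the baseline risk ("risk without
#' genotyping") materially changes the answer and published analyses
#' rarely state it.
#'
#' @param aors named vector of adjusted odds ratios.
#' @param overall overall cohort incidence.
#' @param refgroup optional named vector of reference-group incidences
#'   (per term).
#' @param user optional user-supplied risk.
#' @return Data frame: term, aor, and one NNG column per convention.
#' @export
nng_audit <- function(aors, overall, refgroup = NULL, user = NULL) {
  out <- data.frame(term = names(aors), aor = unname(aors),
                    stringsAsFactors = FALSE)
  out$nng_overall <- vapply(seq_along(aors), function(i)
    nng(aors[i], overall, "overall")$nng, numeric(1))
  if (!is.null(refgroup))
    out$nng_refgroup <- vapply(seq_along(aors), function(i)
      nng(aors[i], refgroup[[names(aors)[i]]], "refgroup")$nng, numeric(1))
  if (!is.null(user))
    out$nng_user <- vapply(seq_along(aors), function(i)
      nng(aors[i], user, "user")$nng, numeric(1))
  out
}

#' Weighted risk score from a fitted logistic model
#'
#' Integer points per model term are derived from the beta coefficients:
#' protective terms (beta < 0) are first re-coded to their absence (the
#' indicator is flipped and the beta sign with it), then each point is
#' the nearest integer to beta, with a minimum of 1 for any retained
#' term.  A subject's WRS is the sum of points over the risk variables
#' present.  `rounding = "raw_beta"` keeps the raw coefficients (the WRS
#' then equals the linear predictor minus the intercept, after
#' re-coding), for sensitivity analysis.
#'
#' @param fit a `logistic_fit` whose non-intercept terms are all binary.
#' @param at analysis table holding those term columns.
#' @param rounding `"nearest_int"` (default) or `"raw_beta"`.
#' @return Object of class `risk_scores`: `points_map` (named vector),
#'   `recoded` (terms whose absence is scored), `wrs` (per-subject,
#'   `NA` where any term is missing), `subject_id`, `rounding`.
#' @export
weighted_risk_score <- function(fit, at,
                                rounding = c("nearest_int", "raw_beta")) {
  rounding <- match.arg(rounding)
  terms <- setdiff(fit$terms, "(Intercept)")
  if (!length(terms)) stop("model has no scored terms")
  if (!all(terms %in% names(at)))
    stop("analysis table lacks model terms: ",
         paste(setdiff(terms, names(at)), collapse = ", "))
  beta <- fit$beta[terms]
  Xm <- as.matrix(at[, terms, drop = FALSE])
  if (!all(Xm %in% c(0, 1, NA))) stop("all scored terms must be binary")
  recoded <- terms[beta < 0]
  Xm[, recoded] <- 1 - Xm[, recoded]
  beta[recoded] <- -beta[recoded]
  points <- switch(rounding,
                   nearest_int = pmax(1, round(beta)),
                   raw_beta = beta)
  wrs <- drop(Xm %*% points)
  structure(list(points_map = points, recoded = recoded, wrs = wrs,
                 subject_id = at$subject_id, rounding = rounding),
            class = "risk_scores")
}

#' @export
print.risk_scores <- function(x, ...) {
  cat("weighted risk score (", x$rounding, "):\n", sep = "")
  pm <- x$points_map
  for (t in names(pm))
    cat(sprintf("  %s%s: %g point(s)\n",
                if (t %in% x$recoded) "absence of " else "", t, pm[[t]]))
  cat(sprintf("  scores: n = %d, range %g-%g\n",
              sum(!is.na(x$wrs)), min(x$wrs, na.rm = TRUE),
              max(x$wrs, na.rm = TRUE)))
  invisible(x)
}

#' Percentile stratification of the weighted risk score
#'
#' Cut points are the empirical percentiles of the WRS (inverse-ECDF
#' quantiles, so cut points are attained score values).  Tie policy for
#' discrete scores: the low group takes `wrs <= ` the lower cut point,
#' the high group `wrs >= ` the upper cut point, and the mid group is the
#' strict interior — so group sizes can deviate from the nominal
#' 25/50/25.  Odds ratios of the low and high groups versus mid come
#' from [odds_ratio_woolf()].
#'
#' With heavily discrete scores the empirical-percentile cut can make the
#' low group absorb the central mass (the 25th-percentile value then sits
#' inside the modal score); `cuts` lets the caller impose attained score
#' values as thresholds instead, as published quartile tables effectively
#' do.
#'
#' @param ws a `risk_scores` object.
#' @param outcome binary outcome aligned with the scores.
#' @param q percentile pair, default `c(25, 75)`.
#' @param cuts optional explicit score cut pair overriding the empirical
#'   percentiles.
#' @return Object of class `wrs_strata`: `cuts`, `group` (factor
#'   low/mid/high), `table` (counts and percentages per group),
#'   `or_low`, `or_high` (`contingency_result`s vs mid).
#' @export
stratify_by_percentile <- function(ws, outcome, q = c(25, 75),
                                   cuts = NULL) {
  wrs <- ws$wrs
  keep <- !is.na(wrs) & !is.na(outcome)
  wrs <- wrs[keep]; y <- outcome[keep]
  if (is.null(cuts))
    cuts <- stats::quantile(wrs, q / 100, type = 1, names = FALSE)
  if (cuts[1] == max(wrs) || length(unique(wrs)) == 1) {
    warning("degenerate score distribution: single stratum")
    return(structure(list(cuts = cuts,
                          group = factor(rep("mid", length(wrs)),
                                         levels = c("low", "mid", "high")),
                          table = NULL, or_low = NULL, or_high = NULL),
                     class = "wrs_strata"))
  }
  group <- factor(ifelse(wrs <= cuts[1], "low",
                         ifelse(wrs >= cuts[2], "high", "mid")),
                  levels = c("low", "mid", "high"))
  tab <- data.frame(group = levels(group),
                    cases = as.vector(tapply(y, group, sum)),
                    n = as.vector(table(group)))
  tab$pct_cases <- 100 * tab$cases / tab$n
  or_vs_mid <- function(g)
    odds_ratio_woolf(crosstab_2x2(
      as.integer(group[group %in% c(g, "mid")] == g),
      y[group %in% c(g, "mid")], labels = c(g, "bleeding")))
  structure(list(cuts = cuts, group = group, table = tab,
                 or_low = or_vs_mid("low"), or_high = or_vs_mid("high")),
            class = "wrs_strata")
}

#' @export
print.wrs_strata <- function(x, ...) {
  cat(sprintf("WRS strata (cuts %g / %g):\n", x$cuts[1], x$cuts[2]))
  if (!is.null(x$table)) {
    print(x$table, row.names = FALSE)
    cat("low  vs mid: "); print(x$or_low)
    cat("high vs mid: "); print(x$or_high)
  }
  invisible(x)
}
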