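#' 2x2 contingency table of a binary exposure against the outcome
#'
#' Counts are laid out `(a, b, c, d)` = (exposed case, exposed control,
#' unexposed case, unexposed control).  Subject pairs with a missing
#' value in either vector are dropped (complete-case per analysis).
#'
#' @param exposure,outcome 0/1 vectors of equal length.
#' @param labels optional `c(exposure_label, outcome_label)`.
#' @return Object of class `contingency_table` with elements `a,b,c,d`,
#'   `n`, `labels`.
#' @export
crosstab_2x2 <- function(exposure, outcome, labels = c("exposed", "case")) {
  if (!all(exposure %in% c(0, 1, NA)) || !all(outcome %in% c(0, 1, NA)))
    stop("exposure and outcome must be binary 0/1")
  keep <- !is.na(exposure) & !is.na(outcome)
  e <- exposure[keep]; y <- outcome[keep]
  structure(list(a = sum(e == 1 & y == 1), b = sum(e == 1 & y == 0),
                 c = sum(e == 0 & y == 1), d = sum(e == 0 & y == 0),
                 n = sum(keep), labels = labels),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c(x$labels[1], paste0("non-", x$labels[1])),
                              c(x$labels[2], paste0("non-", x$labels[2]))))
  print(m)
  invisible(x)
}

.ct_matrix <- function(ct) matrix(c(ct$a, ct$b, ct$c, ct$d), 2, byrow = TRUE)

#' Association test for a 2x2 table
#'
#' Pearson chi-square *without* continuity correction when all expected
#' cell counts are at least 5; otherwise Fisher's exact test (two-sided,
#' point-probability method: summing all tables on the hypergeometric
#' support whose probability does not exceed the observed one).  A table
#' with a zero margin yields `p = 1` with a warning.
#'
#' @param ct a [crosstab_2x2()] result.
#' @return List: `p_value`, `method` (`"chi_square"` or
#'   `"fisher_exact"`), `statistic` (chi-square value, or `NA`).
#' @export
association_test <- function(ct) {
  m <- .ct_matrix(ct)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin: association undefined, p = 1")
    return(list(p_value = 1, method = "undefined", statistic = NA_real_))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (min(expected) >= 5) {
    ht <- stats::chisq.test(m, correct = FALSE)
    list(p_value = unname(ht$p.value), method = "chi_square",
         statistic = unname(ht$statistic))
  } else {
    ht <- stats::fisher.test(m)
    list(p_value = unname(ht$p.value), method = "fisher_exact",
         statistic = NA_real_)
  }
}

#' Odds ratio with Woolf (log-method) confidence interval
#'
#' `OR = ad/bc`; `CI = exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' When any cell is zero the Haldane-Anscombe correction (+0.5 to every
#' cell) is applied and flagged.  A table with zero cells in a cross
#' position (a=d=0 or b=c=0) gives an undefined, flagged result.  The
#' accompanying p-value comes from [association_test()] on the
#' uncorrected counts.
#'
#' @param ct a [crosstab_2x2()] result.
#' @param alpha two-sided significance level for the CI (default 0.05).
#' @return Object of class `contingency_result`: `table`, `or_point`,
#'   `ci_low`, `ci_high`, `p_value`, `method`, `alpha`, `haldane`,
#'   `undefined`.
#' @export
odds_ratio_woolf <- function(ct, alpha = 0.05) {
  test <- suppressWarnings(association_test(ct))
  a <- ct$a; b <- ct$b; c <- ct$c; d <- ct$d
  undefined <- (a == 0 && d == 0) || (b == 0 && c == 0)
  haldane <- !undefined && any(c(a, b, c, d) == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  if (undefined) {
    or <- ci <- c(NA_real_, NA_real_)
    or <- NA_real_
  } else {
    or <- (a * d) / (b * c)
    z <- stats::qnorm(1 - alpha / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * z * se)
  }
  structure(list(table = ct, or_point = or, ci_low = ci[1],
                 ci_high = ci[2], p_value = test$p_value,
                 method = test$method, alpha = alpha,
                 haldane = haldane, undefined = undefined),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f-%.2f), p = %.4g [%s]%s\n",
              x$or_point, x$ci_low, x$ci_high, x$p_value, x$method,
              if (x$haldane) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' Univariate screen of candidate exposures
#'
#' Tests every candidate binary exposure against the outcome
#' (complete-case per candidate) and selects those with `p < alpha`,
#' together with the forced clinical confounders, as input to the
#' multivariable model.  No multiple-testing correction is applied by
#' default; pass `adjust` to get `p.adjust`-corrected selection.
#'
#' @param at analysis table from [analysis_table()].
#' @param candidates exposure columns to screen (default: all columns
#'   except `subject_id` and `bleeding`).
#' @param alpha selection threshold.
#' @param confounders columns always selected when present (default age
#'   >= 65 and sex).
#' @param adjust optional method for [stats::p.adjust()] applied before
#'   selection (default `"none"`).
#' @return Object of class `univariate_screen`: `results` (data frame
#'   sorted by p), `selected` (character vector), `alpha`.
#' @export
univariate_screen <- function(at, candidates = NULL, alpha = 0.05,
                              confounders = c("age_ge_65", "sex_male"),
                              adjust = "none") {
  if (is.null(candidates))
    candidates <- setdiff(names(at), c("subject_id", "bleeding"))
  res <- lapply(candidates, function(v) {
    ct <- crosstab_2x2(at[[v]], at$bleeding, labels = c(v, "bleeding"))
    r <- odds_ratio_woolf(ct)
    data.frame(term = v, n = ct$n, a = ct$a, b = ct$b, c = ct$c, d = ct$d,
               or = r$or_point, ci_low = r$ci_low, ci_high = r$ci_high,
               p_value = r$p_value, method = r$method,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  res <- res[order(res$p_value), ]
  picked <- if (alpha >= 1) res$term else res$term[res$p_adjusted < alpha]
  selected <- union(picked, intersect(confounders, candidates))
  structure(list(results = res, selected = selected, alpha = alpha),
            class = "univariate_screen")
}

#' @export
print.univariate_screen <- function(x, ...) {
  cat(sprintf("univariate screen (alpha = %g): %d candidates, %d selected\n",
              x$alpha, nrow(x$results), length(x$selected)))
  df <- x$results
  df$or <- round(df$or, 2); df$ci_low <- round(df$ci_low, 2)
  df$ci_high <- round(df$ci_high, 2); df$p_value <- signif(df$p_value, 3)
  print(df[, c("term", "n", "or", "ci_low", "ci_high", "p_value",
               "method")], row.names = FALSE)
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
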