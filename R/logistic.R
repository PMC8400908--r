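#' Multivariable logistic regression by maximum likelihood
#'
#' IRLS (Fisher scoring) fit of a binomial-logit model with Wald standard
#' errors from the inverse observed information; adjusted odds ratios and
#' their CIs are `exp(beta +/- z * se)`.  Rank-deficient designs have
#' their aliased columns dropped and reported; quasi-separation (any
#' |beta| > 15 or IRLS non-convergence) is flagged as `converged = FALSE`
#' with a warning.
#'
#' @param X data frame or matrix of predictors (binary exposures in this
#'   pipeline; an intercept is always added).
#' @param y binary 0/1 outcome.
#' @param tol IRLS convergence tolerance on the deviance.
#' @param max_iter maximum IRLS iterations.
#' @param conf_level confidence level for the AOR intervals.
#' @return Object of class `logistic_fit`: `terms`, `beta`, `se`,
#'   `wald_z`, `wald_p`, `aor`, `aor_ci` (matrix), `loglik`, `n`,
#'   `fitted`, `converged`, `aliased`, `y`.
#' @export
fit_logistic_mle <- function(X, y, tol = 1e-10, max_iter = 100L,
                             conf_level = 0.95) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  X <- as.data.frame(X)
  dat <- data.frame(.y = y)
  for (nm in names(X)) dat[[nm]] <- X[[nm]]
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = tol,
                                            maxit = max_iter)))
  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased))
    warning("aliased columns dropped: ", paste(aliased, collapse = ", "))
  keep <- !is.na(cf)
  beta <- cf[keep]
  se <- sqrt(diag(stats::vcov(fit)))[names(beta)]
  separated <- any(abs(beta) > 15)
  converged <- fit$converged && !separated
  if (separated)
    warning("possible separation (|beta| > 15); estimates unreliable — ",
            "consider collapsing sparse exposures")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  aor_ci <- cbind(low = exp(beta - z * se), high = exp(beta + z * se))
  structure(list(terms = names(beta), beta = beta, se = se,
                 wald_z = beta / se,
                 wald_p = 2 * stats::pnorm(-abs(beta / se)),
                 aor = exp(beta), aor_ci = aor_ci,
                 loglik = as.numeric(stats::logLik(fit)),
                 n = length(y), fitted = unname(stats::fitted(fit)),
                 converged = converged, aliased = aliased, y = y),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: n = %d, logLik = %.2f%s\n", x$n, x$loglik,
              if (x$converged) "" else "  [NOT converged]"))
  df <- data.frame(term = x$terms, beta = round(x$beta, 4),
                   se = round(x$se, 4),
                   aor = round(x$aor, 2),
                   ci_low = round(x$aor_ci[, "low"], 2),
                   ci_high = round(x$aor_ci[, "high"], 2),
                   p = signif(x$wald_p, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Backward elimination on Wald p-values
#'
#' Starting from the candidate set, repeatedly refits and removes the
#' term with the largest Wald p-value at or above `alpha`, until every
#' remaining term is significant.  Terms in `forced_in` are never
#' removed.  The elimination path is recorded.  In a screen-then-model
#' workflow the clinical confounders typically *enter* as candidates and
#' may be eliminated; pass them through `forced_in` to keep them
#' regardless.
#'
#' @param at analysis table (or any data frame containing `bleeding` and
#'   the candidate columns).
#' @param candidates columns to start from.
#' @param forced_in columns never removed (default none).
#' @param alpha retention threshold on the Wald p-value.
#' @inheritParams fit_logistic_mle
#' @return A `logistic_fit` for the final model, with extra elements
#'   `path` (data frame of steps) and `candidates`.
#' @export
backward_eliminate <- function(at, candidates, forced_in = character(),
                               alpha = 0.05, tol = 1e-10,
                               max_iter = 100L) {
  stopifnot(all(candidates %in% names(at)),
            all(forced_in %in% candidates))
  current <- candidates
  path <- list()
  step <- 0L
  repeat {
    cc <- stats::complete.cases(at[, c("bleeding", current), drop = FALSE])
    fit <- fit_logistic_mle(at[cc, current, drop = FALSE],
                            at$bleeding[cc], tol = tol,
                            max_iter = max_iter)
    removable <- setdiff(intersect(fit$terms, current), forced_in)
    if (!length(removable)) break
    p <- fit$wald_p[removable]
    worst <- removable[which.max(p)]
    if (max(p) < alpha) break
    step <- step + 1L
    path[[step]] <- data.frame(step = step, dropped = worst,
                               wald_p = unname(max(p)),
                               stringsAsFactors = FALSE)
    current <- setdiff(current, worst)
    if (!length(current)) {   # intercept-only end state
      cc <- !is.na(at$bleeding)
      fit <- fit_logistic_mle(data.frame(row.names = seq_len(sum(cc))),
                              at$bleeding[cc], tol = tol,
                              max_iter = max_iter)
      break
    }
  }
  fit$path <- if (length(path)) do.call(rbind, path) else
    data.frame(step = integer(), dropped = character(),
               wald_p = numeric())
  fit$candidates <- candidates
  fit$retained <- current
  fit
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are ranked by fitted probability and split into `g`
#' quantile-based groups with ties kept together;
#' `chi2 = sum_g (O_g - E_g)^2 / (n_g * pibar_g * (1 - pibar_g))` with
#' `df = g - 2`.  If the fitted probabilities support fewer distinct
#' groups than requested, `g` is reduced with a warning (df follows).
#' The published model's df of 5 corresponds to `g = 7`.
#'
#' @param fit a `logistic_fit` (its `fitted` and `y` are used).
#' @param g number of groups (>= 3; default 10).
#' @return List: `chi2`, `df`, `p_value`, `g_used`, `groups` (per-group
#'   observed/expected table).
#' @export
hosmer_lemeshow <- function(fit, g = 10L) {
  stopifnot(g >= 3)
  p <- fit$fitted; y <- fit$y
  if (length(unique(p)) < 2) {
    warning("constant fitted probabilities: Hosmer-Lemeshow undefined")
    return(list(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                g_used = 1L, groups = NULL))
  }
  brk <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1)))
  if (length(brk) - 1 < g) {
    g_used <- length(brk) - 1
    warning("ties reduce Hosmer-Lemeshow groups to ", g_used)
  } else g_used <- g
  if (g_used < 3)
    warning("fewer than 3 groups: test df is nonpositive")
  grp <- cut(p, breaks = brk, include.lowest = TRUE)
  O <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  pb <- tapply(p, grp, mean)
  chi2 <- sum((O - n_g * pb)^2 / (n_g * pb * (1 - pb)))
  df <- g_used - 2L
  list(chi2 = chi2, df = df,
       p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
                 else NA_real_,
       g_used = g_used,
       groups = data.frame(n = as.vector(n_g), observed = as.vector(O),
                           expected = as.vector(n_g * pb)))
}

#' Area under the ROC curve (Mann-Whitney identity)
#'
#' `AUROC = P(score_case > score_control) + 0.5 P(tie)`, computed from
#' mid-ranks; equivalent to the Wilcoxon-Mann-Whitney statistic divided
#' by `n1 * n0`.
#'
#' @param scores numeric risk scores.
#' @param y binary 0/1 outcome; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, y) {
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both outcome classes")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
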