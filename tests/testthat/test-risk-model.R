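test_that("logistic MLE matches closed forms and the 2x2 cross-product", {
  # intercept only: logit of the outcome mean
  y <- c(rep(1, 21), rep(0, 121))
  fit0 <- fit_logistic_mle(data.frame(row.names = seq_along(y)), y)
  expect_equal(unname(fit0$beta["(Intercept)"]), log(21 / 121),
               tolerance = 1e-8)
  # single binary predictor: beta equals the log crude OR exactly
  x <- c(rep(1, 45), rep(0, 97))
  y2 <- c(rep(1, 13), rep(0, 32), rep(1, 8), rep(0, 89))
  fit1 <- fit_logistic_mle(data.frame(exposed = x), y2)
  expect_equal(unname(fit1$beta["exposed"]), log((13 * 89) / (32 * 8)),
               tolerance = 1e-8)
  expect_true(fit1$converged)
  expect_true(all(fit1$aor_ci[, "low"] <= fit1$aor &
                    fit1$aor <= fit1$aor_ci[, "high"]))
})

test_that("one-parameter MLE matches the likelihood grid oracle", {
  x <- c(1, 1, 1, -1, -1, 1)
  y <- c(1, 1, 0, 0, 1, 1)
  b_grid <- logistic1_grid(x, y)
  dat <- data.frame(.y = y, x = x)
  b_glm <- unname(stats::coef(stats::glm(.y ~ 0 + x, data = dat,
                                         family = stats::binomial())))
  expect_equal(b_glm, b_grid, tolerance = 2e-4)
})

test_that("aliased columns are dropped and separation is flagged", {
  set.seed(1)
  x1 <- stats::rbinom(80, 1, 0.4)
  y <- stats::rbinom(80, 1, stats::plogis(-1 + x1))
  expect_warning(fit <- fit_logistic_mle(data.frame(a = x1, b = x1), y),
                 "aliased")
  expect_equal(fit$aliased, "b")
  # perfectly separating predictor
  ysep <- as.integer(x1 == 1)
  expect_warning(fsep <- fit_logistic_mle(data.frame(a = x1), ysep),
                 "separation")
  expect_false(fsep$converged)
})

test_that("backward elimination removes the weakest term first", {
  set.seed(2)
  n <- 600
  strong <- stats::rbinom(n, 1, 0.4)
  noise <- stats::rbinom(n, 1, 0.4)
  y <- stats::rbinom(n, 1, stats::plogis(-1.5 + 1.2 * strong))
  at <- data.frame(bleeding = y, strong = strong, noise = noise)
  fit <- backward_eliminate(at, c("strong", "noise"))
  expect_equal(fit$retained, "strong")
  expect_equal(fit$path$dropped, "noise")
  # all-null design: only the intercept survives
  ynull <- stats::rbinom(n, 1, 0.2)
  atn <- data.frame(bleeding = ynull, a = noise, b = strong)
  fitn <- backward_eliminate(atn, c("a", "b"))
  expect_equal(length(fitn$retained), 0L)
  expect_equal(fitn$terms, "(Intercept)")
  # forced-in terms are never removed
  fitf <- backward_eliminate(atn, c("a", "b"), forced_in = "a")
  expect_true("a" %in% fitf$terms)
  # candidate order does not change the final model
  fit2 <- backward_eliminate(at, c("noise", "strong"))
  expect_equal(sort(fit$retained), sort(fit2$retained))
})

test_that("elimination on screened synthetic cohorts recovers the true terms", {
  reps <- 120L
  hit <- 0L
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(sim_config(n_subjects = 2000, seed = 5000 + r))
    X <- as.data.frame(sim$truth$design)
    at <- data.frame(bleeding = sim$phenotypes$bleeding, X,
                     af = sim$phenotypes$atrial_fibrillation,
                     age_ge_65 = sim$phenotypes$age_ge_65,
                     sex_male = sim$phenotypes$sex_male)
    fit <- suppressWarnings(
      backward_eliminate(at, c("rs5050", "rs2640543", "ace_h2h2",
                               "af", "age_ge_65", "sex_male")))
    hit <- hit + all(c("rs5050", "rs2640543", "ace_h2h2") %in% fit$retained)
  }
  expect_gt(hit / reps, 0.8)
})

test_that("Wald intervals cover the generating betas at the nominal rate", {
  reps <- 200L
  true_beta <- c(rs5050 = log(5.04), rs2640543 = log(3.17),
                 ace_h2h2 = log(0.12))
  cover <- c(rs5050 = 0L, rs2640543 = 0L, ace_h2h2 = 0L)
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(sim_config(n_subjects = 2000, seed = 7000 + r))
    fit <- fit_logistic_mle(as.data.frame(sim$truth$design),
                            sim$phenotypes$bleeding)
    for (t in names(true_beta)) {
      lo <- fit$beta[t] - 1.96 * fit$se[t]
      hi <- fit$beta[t] + 1.96 * fit$se[t]
      cover[t] <- cover[t] + (lo <= true_beta[t] && true_beta[t] <= hi)
    }
  }
  for (t in names(cover))
    expect_true(cover[t] / reps >= 0.90 && cover[t] / reps <= 0.99,
                label = paste("coverage", t, cover[t] / reps))
})

test_that("Hosmer-Lemeshow grouping, df and calibration behave", {
  sim <- simulate_cohort(sim_config(n_subjects = 2000, seed = 41))
  # a continuous covariate spreads the fitted probabilities so the
  # requested quantile groups can actually form
  X <- as.data.frame(sim$truth$design)
  X$age_std <- (sim$phenotypes$age_years - 60) / 10
  fit <- fit_logistic_mle(X, sim$phenotypes$bleeding)
  hl7 <- hosmer_lemeshow(fit, g = 7)
  expect_equal(hl7$df, 5L)          # the published model's df
  expect_gt(hl7$p_value, 0.001)     # correctly specified model fits
  hl10 <- suppressWarnings(hosmer_lemeshow(fit, g = 10))
  expect_equal(hl10$df, hl10$g_used - 2L)
  expect_equal(sum(hl10$groups$n), 2000)
  # constant fitted probabilities: undefined with warning
  fit0 <- fit_logistic_mle(data.frame(row.names = 1:100),
                           stats::rbinom(100, 1, 0.3))
  expect_warning(hl0 <- hosmer_lemeshow(fit0), "constant|ties")
  expect_true(is.na(hl0$chi2))
})

test_that("Hosmer-Lemeshow p-values are roughly uniform under truth", {
  ps <- vapply(1:150, function(r) {
    sim <- simulate_cohort(sim_config(n_subjects = 1000, seed = 9000 + r))
    X <- as.data.frame(sim$truth$design)
    X$age_std <- (sim$phenotypes$age_years - 60) / 10
    fit <- fit_logistic_mle(X, sim$phenotypes$bleeding)
    suppressWarnings(hosmer_lemeshow(fit, g = 7)$p_value)
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)   # uniform p has mean 0.5
})

test_that("AUROC equals all-pairs counting and handles edge cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(3)
  s <- stats::runif(2000); y <- stats::rbinom(2000, 1, 0.3)
  expect_lt(abs(auroc(s, y) - 0.5), 0.05)
  # 4-point toy with a tie
  s4 <- c(0.3, 0.5, 0.5, 0.1); y4 <- c(1, 1, 0, 0)
  expect_equal(auroc(s4, y4), auroc_pairs(s4, y4))
  for (i in 1:20) {
    ss <- sample(1:5, 12, replace = TRUE)
    yy <- c(rep(1, 5), rep(0, 7))
    expect_equal(auroc(ss, yy), auroc_pairs(ss, yy))
  }
  expect_error(auroc(s4, c(1, 1, 1, 1)), "both")
})

test_that("attributable risk applies the AOR formula with inversion", {
  expect_equal(round(as.numeric(attributable_risk(5.04)), 1), 80.2)
  expect_equal(round(as.numeric(attributable_risk(3.17)), 1), 68.5)
  ar <- attributable_risk(0.12)
  expect_true(attr(ar, "inverted"))
  expect_equal(attr(ar, "aor_used"), 1 / 0.12)
  expect_equal(round(as.numeric(ar), 1), 88.0)
  expect_equal(as.numeric(attributable_risk(1)), 0)
  expect_error(attributable_risk(0), "positive")
  expect_error(attributable_risk(-2), "positive")
  # monotone in aor above 1
  aors <- seq(1, 20, by = 0.5)
  ars <- vapply(aors, function(a) as.numeric(attributable_risk(a)), 0)
  expect_true(all(diff(ars) > 0))
})

test_that("RRR/ARR/NNG chain follows the defining formulas", {
  r <- nng(2, 0.5, "user")
  expect_equal(r$rrr, 0.5)
  expect_equal(r$arr, 0.25)
  expect_equal(r$nng, 4)
  # protective OR, overall-incidence reference: the published NNG for H2
  rh2 <- nng(0.12, 21 / 142, "overall")
  expect_true(rh2$inverted)
  expect_equal(round(rh2$rrr, 3), 0.88)
  expect_equal(rh2$nng, 8)
  # near-null effect is flagged impractical
  rn <- nng(1.0001, 0.1, "user")
  expect_true(rn$impractical)
  expect_gt(rn$nng, 1e5)
  expect_warning(nng(1, 0.1, "user"), "infinite")
  expect_error(nng(2, 0), "risk_reference")
  # audit reports conventions side by side
  audit <- nng_audit(c(ace_h2h2 = 1 / 0.12, rs5050 = 5.04,
                       rs2640543 = 3.17),
                     overall = 21 / 142,
                     refgroup = c(ace_h2h2 = 20 / 109, rs5050 = 8 / 97,
                                  rs2640543 = 10 / 95))
  expect_equal(audit$nng_overall, c(8, 9, 10))
  expect_equal(audit$nng_refgroup, c(7, 16, 14))
})

test_that("weighted risk score rounds betas to points, recoding protection", {
  betas <- c(rs5050 = log(5.04), rs2640543 = log(3.17),
             ace_h2h2 = log(0.12))
  fit <- structure(list(terms = c("(Intercept)", names(betas)),
                        beta = c("(Intercept)" = -2.6, betas)),
                   class = "logistic_fit")
  at <- data.frame(subject_id = sprintf("S%d", 1:4),
                   rs5050 = c(1, 0, 1, 0), rs2640543 = c(1, 0, 0, 1),
                   ace_h2h2 = c(0, 1, 0, 0))
  ws <- weighted_risk_score(fit, at)
  expect_equal(unname(ws$points_map),
               c(2, 1, 2))                 # round(1.617), round(1.154), round(2.120)
  expect_equal(ws$recoded, "ace_h2h2")
  # max achievable score: 2 + 1 + 2 (carrier, carrier, not H2/H2)
  expect_equal(max(ws$wrs), 5)
  # subject with no risk variables (H2/H2, no carriers) scores 0
  expect_equal(ws$wrs[2], 0)
  # raw-beta mode equals the recoded linear predictor minus intercept
  wsr <- weighted_risk_score(fit, at, rounding = "raw_beta")
  lp <- as.matrix(at[, names(betas)]) %*% betas
  expect_equal(wsr$wrs, drop(lp) - log(0.12), tolerance = 1e-12)
})

test_that("percentile stratification reproduces the published quartile ORs", {
  # scores concentrated on 2/3/4 with the published group outcome counts
  wrs <- c(rep(2, 29), rep(3, 102), rep(4, 11))
  y <- c(rep(1, 1), rep(0, 28), rep(1, 13), rep(0, 89), rep(1, 7),
         rep(0, 4))
  ws <- structure(list(wrs = wrs, subject_id = seq_along(wrs),
                       points_map = c(x = 1), recoded = character(),
                       rounding = "nearest_int"),
                  class = "risk_scores")
  st <- stratify_by_percentile(ws, y, cuts = c(2, 4))
  expect_equal(st$table$n, c(29, 102, 11))
  expect_equal(round(st$or_high$or_point, 2), 11.98)
  expect_equal(round(c(st$or_high$ci_low, st$or_high$ci_high), 2),
               c(3.08, 46.65))
  expect_equal(round(c(st$or_low$ci_low, st$or_low$ci_high), 2),
               c(0.03, 1.95))
  expect_equal(st$or_low$or_point, 89 / 364, tolerance = 1e-9)
  # groups partition the scored subjects
  expect_equal(sum(st$table$n), length(wrs))
  # empirical-percentile default on a less discrete score
  set.seed(4)
  ws2 <- ws; ws2$wrs <- stats::rnorm(400)
  y2 <- stats::rbinom(400, 1, 0.3)
  st2 <- stratify_by_percentile(ws2, y2)
  # inverse-ECDF cuts with the "<= low, >= high" tie policy: 100 in the
  # low group, 101 in the high group (the 75th-percentile value itself)
  expect_equal(as.vector(table(st2$group)[c("low", "high")]), c(100, 101))
  # flat outcome probability: both ORs near 1
  expect_lt(abs(log(st2$or_low$or_point)), log(3))
  # degenerate all-equal scores
  ws3 <- ws; ws3$wrs <- rep(2, 400)
  expect_warning(stratify_by_percentile(ws3, y2), "degenerate")
})
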