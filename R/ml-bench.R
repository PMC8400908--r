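#' Stratified k-fold assignment
#'
#' Deals each outcome class round-robin into `k` folds after a seeded
#' shuffle, so per-fold class proportions are within one subject of the
#' global proportions.  `k = n` gives leave-one-out (stratification is
#' then moot).  Deterministic for a given seed.
#'
#' @param y binary outcome.
#' @param k number of folds.
#' @param stratified stratify on `y` (default TRUE).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k = 5L, stratified = TRUE, seed = 1L) {
  n <- length(y)
  set.seed(seed)
  if (k == n) return(sample.int(n))   # leave-one-out, shuffled ids
  if (k > n) stop("k cannot exceed n")
  folds <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k)
        stop("class ", cls, " has fewer than k = ", k,
             " members; use a smaller k")
      folds[idx] <- (seq_along(idx) %% k) + 1L
      folds[idx] <- folds[idx][sample.int(length(idx))]
    }
  } else {
    folds <- (seq_len(n) %% k + 1L)[sample.int(n)]
  }
  folds
}

# default hyperparameter grids (config-overridable)
.default_grids <- function() list(
  elastic_net = list(alpha = seq(0.1, 1, by = 0.1)),
  random_forest = list(ntree = 500L, mtry = NULL),  # NULL -> {sqrt(p), p/3}
  svm_linear = list(cost = 2^seq(-5, 5, by = 2)),
  svm_rbf = list(cost = 2^seq(-5, 5, by = 2), gamma_scale = c(0.1, 1, 10)))

# median heuristic for the RBF kernel width
.median_heuristic <- function(X) {
  n <- nrow(X)
  idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m == 0) 1 else 1 / (2 * m^2)
}

# fit one learner on (Xtr, ytr) with inner 3-fold tuning, score Xte
.fit_predict <- function(model_spec, Xtr, ytr, Xte, grids, inner_seed) {
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  inner_auc <- function(fit_fun) {
    # mean AUROC over 3 stratified inner folds for one candidate setting
    fl <- make_folds(ytr, k = 3L, seed = inner_seed)
    mean(vapply(1:3, function(f) {
      tr <- fl != f
      if (length(unique(ytr[!tr])) < 2) return(NA_real_)
      s <- fit_fun(Xtr[tr, , drop = FALSE], ytr[tr],
                   Xtr[!tr, , drop = FALSE])
      auroc(s, ytr[!tr])
    }, numeric(1)), na.rm = TRUE)
  }
  if (model_spec == "logistic") {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, Xtr), ytr,
                                           family = stats::binomial()))
    sc <- drop(cbind(1, Xte) %*% stats::coef(fit))
    return(list(scores = sc, chosen = NULL))
  }
  if (model_spec == "elastic_net") {
    alphas <- grids$elastic_net$alpha
    perf <- vapply(alphas, function(a) {
      inner_auc(function(x1, y1, x2) {
        cv <- glmnet::cv.glmnet(x1, y1, family = "binomial", alpha = a,
                                nfolds = 3, type.measure = "deviance")
        drop(stats::predict(cv, newx = x2, s = "lambda.min"))
      })
    }, numeric(1))
    a <- alphas[which.max(perf)]
    cv <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = a,
                            nfolds = 3, type.measure = "deviance")
    return(list(scores = drop(stats::predict(cv, newx = Xte,
                                             s = "lambda.min")),
                chosen = list(alpha = a, lambda = cv$lambda.min)))
  }
  if (model_spec == "random_forest") {
    p <- ncol(Xtr)
    mtrys <- grids$random_forest$mtry
    if (is.null(mtrys))
      mtrys <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3))))
    ntree <- grids$random_forest$ntree
    yf <- factor(ytr, levels = c(0, 1))
    perf <- vapply(mtrys, function(m) {
      inner_auc(function(x1, y1, x2) {
        rf <- randomForest::randomForest(x1, factor(y1, levels = c(0, 1)),
                                         ntree = ntree, mtry = m)
        stats::predict(rf, x2, type = "prob")[, "1"]
      })
    }, numeric(1))
    m <- mtrys[which.max(perf)]
    rf <- randomForest::randomForest(Xtr, yf, ntree = ntree, mtry = m)
    return(list(scores = stats::predict(rf, Xte, type = "prob")[, "1"],
                chosen = list(mtry = m, ntree = ntree)))
  }
  if (model_spec %in% c("svm_linear", "svm_rbf")) {
    kern <- if (model_spec == "svm_linear") "linear" else "radial"
    costs <- grids[[model_spec]]$cost
    gammas <- if (kern == "radial")
      .median_heuristic(Xtr) * grids$svm_rbf$gamma_scale else NA
    cand <- expand.grid(cost = costs, gamma = gammas)
    yf <- factor(ytr, levels = c(0, 1))
    svm_scores <- function(x1, y1, x2, cost, gamma) {
      args <- list(x = x1, y = factor(y1, levels = c(0, 1)),
                   kernel = kern, cost = cost, scale = FALSE)
      if (kern == "radial") args$gamma <- gamma
      fit <- do.call(e1071::svm, args)
      dvm <- attr(stats::predict(fit, x2, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # the column name "a/b" means positive values favour class a
      if (startsWith(colnames(dvm)[1], "0")) -dv else dv
    }
    perf <- vapply(seq_len(nrow(cand)), function(i) {
      inner_auc(function(x1, y1, x2)
        svm_scores(x1, y1, x2, cand$cost[i], cand$gamma[i]))
    }, numeric(1))
    b <- which.max(perf)
    sc <- svm_scores(Xtr, ytr, Xte, cand$cost[b], cand$gamma[b])
    return(list(scores = sc,
                chosen = list(cost = cand$cost[b],
                              gamma = if (kern == "radial")
                                cand$gamma[b] else NULL)))
  }
  stop("unknown model_spec: ", model_spec)
}

#' Repeated stratified cross-validated AUROC
#'
#' For each of `repeats` iterations a fresh stratified `k`-fold split is
#' drawn; within each fold the learner is tuned on an inner 3-fold grid
#' (where it has hyperparameters), fitted on the training folds and
#' scored on the held-out fold; the iteration-level AUROC is the mean
#' over folds.  The summary 95% CI is the normal approximation
#' `mean +/- 1.96 sd/sqrt(repeats)` across iteration means.  Margin
#' classifiers are scored by decision values (rank-equivalent to
#' probabilities for AUROC).
#'
#' Fold splits depend only on `y`, `k`, `repeats`, `seed` — not on the
#' learner — so results for different `model_spec`s under one seed share
#' fold assignments exactly (paired comparison contract).
#'
#' @param model_spec one of `"logistic"`, `"elastic_net"`,
#'   `"random_forest"`, `"svm_linear"`, `"svm_rbf"`.
#' @param X predictor data frame/matrix.
#' @param y binary outcome.
#' @param k folds (default 5).
#' @param repeats iterations (default 10).
#' @param seed integer seed.
#' @param grids optional list overriding the default hyperparameter
#'   grids.
#' @return Object of class `cv_result`: `model_name`, `auroc_per_repeat`,
#'   `mean_auroc`, `ci95`, `folds` (list of assignments), `chosen`
#'   (hyperparameters per repeat x fold), `seed`.
#' @export
repeated_cv_auroc <- function(model_spec, X, y, k = 5L, repeats = 10L,
                              seed = 1L, grids = NULL) {
  model_spec <- match.arg(model_spec,
                          c("logistic", "elastic_net", "random_forest",
                            "svm_linear", "svm_rbf"))
  g <- .default_grids()
  if (!is.null(grids)) g[names(grids)] <- grids
  X <- as.data.frame(X)
  folds_by_repeat <- lapply(seq_len(repeats), function(r)
    make_folds(y, k = k, seed = seed + r - 1L))
  per_repeat <- numeric(repeats)
  chosen <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- folds_by_repeat[[r]]
    fold_auc <- numeric(k)
    ch <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- folds != f
      res <- tryCatch(
        .fit_predict(model_spec, X[tr, , drop = FALSE], y[tr],
                     X[!tr, , drop = FALSE], g,
                     inner_seed = seed * 1000L + r * 10L + f),
        error = function(e) {
          warning("fold ", f, " repeat ", r, " skipped: ",
                  conditionMessage(e))
          NULL
        })
      fold_auc[f] <- if (is.null(res)) NA_real_
                     else auroc(res$scores, y[!tr])
      ch[[f]] <- if (is.null(res)) NULL else res$chosen
    }
    per_repeat[r] <- mean(fold_auc, na.rm = TRUE)
    chosen[[r]] <- ch
  }
  m <- mean(per_repeat)
  hw <- 1.96 * stats::sd(per_repeat) / sqrt(repeats)
  structure(list(model_name = model_spec,
                 auroc_per_repeat = per_repeat, mean_auroc = m,
                 ci95 = c(low = m - hw, high = m + hw),
                 folds = folds_by_repeat, chosen = chosen, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: mean AUROC %.3f (95%% CI %.3f-%.3f) over %d repeats\n",
              x$model_name, x$mean_auroc, x$ci95["low"], x$ci95["high"],
              length(x$auroc_per_repeat)))
  invisible(x)
}

#' Compare cross-validated models fitted on identical folds
#'
#' Tabulates mean AUROC and its 95% CI per model, ordered best-first.
#' Requires at least two results sharing exactly the same fold
#' assignments (the paired contract of [repeated_cv_auroc()] under one
#' seed); no significance test is applied.
#'
#' @param results list of `cv_result` objects.
#' @return Data frame: `model`, `mean_auroc`, `ci_low`, `ci_high`.
#' @export
compare_models <- function(results) {
  if (length(results) < 2) stop("need at least two cv_result objects")
  ref <- results[[1]]$folds
  for (r in results[-1])
    if (!identical(r$folds, ref))
      stop("fold assignments differ between models; rerun with one seed")
  out <- data.frame(
    model = vapply(results, `[[`, "", "model_name"),
    mean_auroc = vapply(results, `[[`, 0, "mean_auroc"),
    ci_low = vapply(results, function(r) r$ci95[["low"]], 0),
    ci_high = vapply(results, function(r) r$ci95[["high"]], 0))
  out[order(-out$mean_auroc), ]
}
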