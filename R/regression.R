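#' Stage-stratified calibration/validation split
#'
#' Randomly partitions the feature table into disjoint, exhaustive
#' calibration and validation sets, stratified so every stage is
#' represented in both.
#'
#' @param table Feature table with a `stage` column (or a `stratify_by`
#'   column of your choice).
#' @param ratio Calibration fraction (0 < ratio < 1; default 2/3).
#' @param stratify_by Stratification column name.
#' @param seed Integer seed.
#' @return List with `calibration` and `validation` data frames.
#' @export
split_calval <- function(table, ratio = 2 / 3, stratify_by = "stage",
                         seed = 1L) {
  stopifnot(ratio > 0, ratio < 1, nrow(table) >= 10)
  strata <- if (stratify_by %in% names(table)) table[[stratify_by]]
            else rep("all", nrow(table))
  set.seed(derive_seed(seed, "calval-split"))
  cal_idx <- integer(0)
  for (s in unique(strata)) {
    rows <- which(strata == s)
    if (length(rows) < 2) {
      stop("stratum '", s, "' has fewer than 2 samples", call. = FALSE)
    }
    k <- min(max(round(ratio * length(rows)), 1L), length(rows) - 1L)
    cal_idx <- c(cal_idx, sort(rows[sample.int(length(rows), k)]))
  }
  list(calibration = table[sort(cal_idx), , drop = FALSE],
       validation = table[setdiff(seq_len(nrow(table)), cal_idx), ,
                          drop = FALSE])
}

#' Partial least squares regression with cross-validated components
#'
#' Fits a PLS regression of AGB on the selected features, choosing the
#' latent-component count (up to `ncomp_max`) by seeded 10-fold
#' cross-validated RMSE. Zero-variance feature columns are dropped before
#' fitting; a constant target yields a degenerate mean-predicting model.
#' Predictions are deliberately not clipped at zero so the negative
#' low-AGB predictions the method is known for remain observable.
#'
#' @param x Feature matrix or feature table.
#' @param y Numeric target; defaults to `x$agb` for feature tables.
#' @param features Optional subset of feature names.
#' @param ncomp_max Maximum number of latent components (default 10).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed for the folds.
#' @return Object of class `agb_plsr` with a `predict` method.
#' @export
fit_plsr <- function(x, y = NULL, features = NULL, ncomp_max = 10L,
                     n_folds = 10L, seed = 1L) {
  if (is.data.frame(x) && is.null(y)) y <- x$agb
  X <- selection_matrix(x)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  n <- nrow(X)
  stopifnot(length(y) == n, n > 2)
  keep <- apply(X, 2, sd) > 0
  if (var(y) == 0 || !any(keep)) {
    return(structure(list(degenerate = TRUE, mean_y = mean(y),
                          features = colnames(X)), class = "agb_plsr"))
  }
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  # exactly collinear feature blocks (e.g. aliased harmonic orders) limit
  # the usable latent space to the rank of the centered predictors
  rank_x <- qr(scale(X, scale = FALSE))$rank
  ncomp_max <- max(1L, min(ncomp_max, p, n - 2L, rank_x))
  n_folds <- min(n_folds, n)
  set.seed(derive_seed(seed, "plsr-cv"))
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  cap <- max(1L, min(ncomp_max,
                     floor(n * (n_folds - 1) / n_folds) - 1L))
  sse <- rep(0, cap)
  for (fd in seq_len(n_folds)) {
    tr <- fold != fd
    if (sum(tr) <= cap + 1 || sum(!tr) == 0) next
    fit <- pls_safe(X[tr, , drop = FALSE], y[tr], cap)
    pr <- suppressWarnings(predict(fit, X[!tr, , drop = FALSE]))$predict
    kk <- dim(pr)[3]
    for (k in seq_len(cap)) {
      sse[k] <- sse[k] + sum((y[!tr] - pr[, 1, min(k, kk)])^2)
    }
  }
  ncomp <- which.min(sse)
  fit <- pls_safe(X, y, ncomp)
  ncomp <- fit$ncomp
  structure(list(degenerate = FALSE, fit = fit, ncomp = ncomp,
                 features = colnames(X)), class = "agb_plsr")
}

#' @export
predict.agb_plsr <- function(object, newdata, ...) {
  if (isTRUE(object$degenerate)) {
    n <- if (is.data.frame(newdata) || is.matrix(newdata)) nrow(newdata)
         else length(newdata)
    return(rep(object$mean_y, n))
  }
  X <- selection_matrix(newdata)[, object$features, drop = FALSE]
  pr <- suppressWarnings(predict(object$fit, X))$predict
  unname(pr[, 1, object$ncomp])
}

#' Random-forest regression of AGB
#'
#' @inheritParams fit_plsr
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed.
#' @return Object of class `agb_rfr` with a `predict` method.
#' @export
fit_rfr <- function(x, y = NULL, features = NULL, ntree = 500L,
                    seed = 1L) {
  if (is.data.frame(x) && is.null(y)) y <- x$agb
  X <- selection_matrix(x)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  stopifnot(length(y) == nrow(X))
  set.seed(derive_seed(seed, "rfr"))
  fit <- randomForest::randomForest(X, y, ntree = ntree)
  structure(list(fit = fit, features = colnames(X)), class = "agb_rfr")
}

#' @export
predict.agb_rfr <- function(object, newdata, ...) {
  X <- selection_matrix(newdata)[, object$features, drop = FALSE]
  unname(predict(object$fit, X))
}

#' Regression evaluation metrics
#'
#' \deqn{R^2 = 1 - SS_{res}/SS_{tot}} (can be negative; defined as 0 for
#' a constant observed vector), \deqn{RMSE = \sqrt{\sum (o-p)^2 / n},
#' \quad MAE = \sum |o-p| / n, \quad nRMSE = 100 \cdot RMSE /
#' \bar{o}\,\%.} Pairs with missing values are dropped with a warning.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return Named vector `R2, RMSE, MAE, nRMSE_pct` (nRMSE is `NA` when
#'   the observed mean is 0).
#' @export
evaluate_predictions <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  keep <- is.finite(observed) & is.finite(predicted)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) with missing values dropped",
            call. = FALSE)
  }
  o <- observed[keep]; p <- predicted[keep]
  if (length(o) < 2) stop("need >= 2 complete pairs", call. = FALSE)
  ss_res <- sum((o - p)^2)
  ss_tot <- sum((o - mean(o))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  rmse <- sqrt(mean((o - p)^2))
  mae <- mean(abs(o - p))
  nrmse <- if (abs(mean(o)) < 1e-12) NA_real_ else 100 * rmse / mean(o)
  c(R2 = r2, RMSE = rmse, MAE = mae, nRMSE_pct = nrmse)
}

#' The seven variable-dimension combinations
#'
#' All subsets of the four dimensions that contain the spectral variables
#' (SV) plus at least one of texture (TV), geometric (GV) and
#' frequency-domain (FDV) variables.
#'
#' @return Named list of 7 character vectors of dimension codes.
#' @export
enumerate_combinations <- function() {
  others <- c("TV", "GV", "FDV")
  combos <- list()
  for (k in 1:3) {
    for (s in utils::combn(others, k, simplify = FALSE)) {
      combos[[paste(c("SV", s), collapse = "+")]] <- c("SV", s)
    }
  }
  combos[order(lengths(combos))]
}

# NIPALS can still go numerically singular near the rank edge; retry
# with fewer components (spec of the model: singular block -> fewer
# components with a warning).
pls_safe <- function(X, y, ncomp) {
  repeat {
    fit <- tryCatch(
      suppressWarnings(mixOmics::pls(X, y, ncomp = ncomp,
                                     mode = "regression")),
      error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    if (ncomp <= 1) stop(fit)
    ncomp <- ncomp - 1L
    warning("singular feature block; reduced to ", ncomp,
            " PLS component(s)", call. = FALSE)
  }
}

selection_ranking <- function(method, table, seed, ...) {
  switch(method,
    none = NULL,
    rrelieff = rrelieff(table, seed = seed, ...),
    rf_gini = rf_gini_importance(table, seed = seed, ...),
    rf_oob = rf_oob_importance(table, seed = seed, ...),
    stop("unknown selection method: ", method, call. = FALSE))
}

#' Run the selection x regression x combination experiment
#'
#' For every requested (variable combination, selection method,
#' regression) cell: restrict the feature table to the combination's
#' dimensions, rank features on the calibration partition and keep the
#' top `top_n` (all features for `"none"`), fit on calibration, and
#' evaluate on both partitions. With the default single "ALL" combination
#' and all four selection settings this reproduces the 4 x 2 grid of a
#' selection-method comparison; with `combinations =
#' enumerate_combinations()` and one selection method it reproduces the
#' seven-combination comparison.
#'
#' @param table Feature table (see [extract_features()]); must carry the
#'   dimension map as `attr(table, "dims")` or use the standard 39
#'   feature names.
#' @param selections Character vector from `"none", "rrelieff",
#'   "rf_gini", "rf_oob"`.
#' @param regressions Character vector from `"plsr", "rfr"`.
#' @param combinations Named list of dimension-code vectors, or `NULL`
#'   for a single combination of all four dimensions.
#' @param ratio Calibration fraction for [split_calval()].
#' @param top_n Features kept per selection (default 10).
#' @param seed Integer seed controlling split, selection and forests.
#' @return Data frame of class `eval_report` with one row per
#'   (combination, selection, regression, partition):
#'   `combination, selection, regression, partition, n, n_features, R2,
#'   RMSE_g_m2, MAE_g_m2, nRMSE_pct`. Observed/predicted pairs are
#'   attached as `attr(x, "predictions")`.
#' @export
run_experiment <- function(table, selections = "rf_oob",
                           regressions = c("plsr", "rfr"),
                           combinations = NULL, ratio = 2 / 3,
                           top_n = 10L, seed = 1L) {
  dims <- attr(table, "dims") %||% default_dimension_map(table)
  if (is.null(combinations)) {
    combinations <- list(ALL = names(dims))
  }
  parts <- split_calval(table, ratio = ratio, seed = seed)
  cal <- parts$calibration; val <- parts$validation
  rows <- list()
  preds <- list()
  for (cb in names(combinations)) {
    feats_cb <- unlist(dims[combinations[[cb]]], use.names = FALSE)
    feats_cb <- intersect(feats_cb, names(table))
    for (sel in selections) {
      ranking <- selection_ranking(sel, cal[c(feats_cb, "agb")],
                                   seed = seed)
      feats <- if (is.null(ranking)) feats_cb
               else select_top(ranking, top_n)
      for (reg in regressions) {
        model <- switch(reg,
          plsr = fit_plsr(cal, features = feats, seed = seed),
          rfr = fit_rfr(cal, features = feats, seed = seed),
          stop("unknown regression: ", reg, call. = FALSE))
        for (part in c("calibration", "validation")) {
          dat <- if (part == "calibration") cal else val
          pr <- predict(model, dat)
          m <- evaluate_predictions(dat$agb, pr)
          rows[[length(rows) + 1L]] <- data.frame(
            combination = cb, selection = sel, regression = reg,
            partition = part, n = nrow(dat),
            n_features = length(feats),
            R2 = m[["R2"]], RMSE_g_m2 = m[["RMSE"]],
            MAE_g_m2 = m[["MAE"]], nRMSE_pct = m[["nRMSE_pct"]],
            stringsAsFactors = FALSE)
          preds[[length(preds) + 1L]] <- data.frame(
            combination = cb, selection = sel, regression = reg,
            partition = part,
            sample_id = dat$sample_id %||% seq_len(nrow(dat)),
            observed = dat$agb, predicted = pr,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  attr(out, "predictions") <- do.call(rbind, preds)
  out
}

# Fallback dimension map from standard column names when the feature
# table does not carry one.
default_dimension_map <- function(table) {
  nm <- names(table)
  list(SV = grep("_v$", nm, value = TRUE),
       TV = grep("^TEX_", nm, value = TRUE),
       GV = intersect(c("HEIGHT_m", "FVC"), nm),
       FDV = intersect(harmonic_feature_names(), nm))
}
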