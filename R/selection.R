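# Coerce a feature table / matrix + target into a numeric matrix with
# column names, dropping identifier columns.
selection_matrix <- function(x) {
  if (is.data.frame(x)) {
    drop_cols <- intersect(c("sample_id", "plot_id", "stage", "variety",
                             "fertilizer", "rep", "agb"), names(x))
    x <- x[setdiff(names(x), drop_cols)]
    x <- as.matrix(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  x
}

ranking_frame <- function(features, weight, method, seed) {
  rank <- rank(-weight, ties.method = "first")
  structure(data.frame(feature = features, weight = weight, rank = rank,
                       method = method, seed = seed,
                       stringsAsFactors = FALSE),
            class = c("importance_ranking", "data.frame"))
}

#' RReliefF feature weighting for regression
#'
#' Regression variant of the Relief family: features and target are
#' min-max normalized; for each sampled instance its k nearest neighbors
#' (Manhattan distance on the normalized features, uniform neighbor
#' weights) accumulate the probability mass of a differing prediction
#' (`NdY`), a differing feature value (`NdF`), and both (`NdYandF`); the
#' weight of feature F is
#' \deqn{W(F) = NdYandF / NdY - (NdF - NdYandF) / (m - NdY),}
#' the conditional-probability contrast between "feature differs given
#' prediction differs" and "feature differs given prediction agrees".
#' Constant features receive weight exactly 0.
#'
#' @param x Feature matrix or feature table (identifier and `agb` columns
#'   are dropped automatically).
#' @param y Numeric target (AGB, g/m2); taken from `x$agb` when `x` is a
#'   feature table and `y` is missing.
#' @param k_neighbors Number of nearest neighbors (default 10).
#' @param m Number of sampled instances; `NULL` uses every instance
#'   sequentially.
#' @param seed Integer seed (used when `m < n`).
#' @return `importance_ranking` data frame: `feature, weight, rank,
#'   method, seed`.
#' @export
rrelieff <- function(x, y = NULL, k_neighbors = 10L, m = NULL, seed = 1L) {
  if (is.data.frame(x) && is.null(y)) y <- x$agb
  X <- selection_matrix(x)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, all(is.finite(y)))
  if (k_neighbors >= n) stop("k_neighbors must be < n", call. = FALSE)
  rngs <- apply(X, 2, function(v) diff(range(v)))
  keep <- rngs > 0
  Xn <- X
  Xn[, keep] <- sweep(sweep(X[, keep, drop = FALSE], 2,
                            apply(X[, keep, drop = FALSE], 2, min)),
                      2, rngs[keep], "/")
  Xn[, !keep] <- 0
  yr <- diff(range(y))
  yn <- if (yr > 0) (y - min(y)) / yr else rep(0, n)

  set.seed(derive_seed(seed, "rrelieff"))
  idx <- if (is.null(m) || m >= n) seq_len(n) else sample.int(n, m)
  NdY <- 0
  NdF <- numeric(p)
  NdYandF <- numeric(p)
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  for (i in idx) {
    nb <- order(D[i, ])[-1][seq_len(k_neighbors)]
    w <- 1 / k_neighbors
    dy <- abs(yn[i] - yn[nb])
    df <- abs(sweep(Xn[nb, , drop = FALSE], 2, Xn[i, ]))  # k x p
    NdY <- NdY + sum(dy) * w
    NdF <- NdF + colSums(df) * w
    NdYandF <- NdYandF + colSums(df * dy) * w
  }
  m_eff <- length(idx)
  W <- if (NdY > 0 && NdY < m_eff) {
    NdYandF / NdY - (NdF - NdYandF) / (m_eff - NdY)
  } else numeric(p)
  W[!keep] <- 0
  ranking_frame(colnames(X), W, "RReliefF", seed)
}

#' Gini impurity of a class probability vector
#'
#' \deqn{G = \sum_v p_v (1 - p_v) = 1 - \sum_v p_v^2.}
#'
#' @param p Non-negative probabilities summing to 1.
#' @return Gini index in [0, 1).
#' @export
gini_index <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  1 - sum(p^2)
}

# Quantile-discretize a continuous target, collapsing empty bins.
discretize_target <- function(y, n_classes) {
  repeat {
    br <- unique(quantile(y, probs = seq(0, 1, length.out = n_classes + 1)))
    if (length(br) >= 3 || n_classes <= 2) break
    n_classes <- n_classes - 1L
  }
  if (length(br) < 3) {
    stop("target has too few distinct values to discretize", call. = FALSE)
  }
  if (length(br) < n_classes + 1) {
    warning("empty quantile bin(s); reduced to ", length(br) - 1,
            " classes", call. = FALSE)
  }
  cut(y, breaks = br, include.lowest = TRUE)
}

#' Random-forest Gini importance
#'
#' The Gini split criterion is a classification purity measure, so the
#' continuous AGB target is quantile-discretized into `n_classes` classes
#' and a classification forest is grown; the importance of a feature is
#' the total decrease of the Gini index over all splits on it, averaged
#' over trees. `mode = "variance"` instead grows a regression forest and
#' uses the analogous node-impurity (residual sum of squares) decrease.
#'
#' @inheritParams rrelieff
#' @param n_trees Number of trees.
#' @param n_classes Number of quantile classes for the discretization.
#' @param mode `"gini"` (discretized classification, default) or
#'   `"variance"` (regression impurity).
#' @return `importance_ranking` data frame.
#' @export
rf_gini_importance <- function(x, y = NULL, n_trees = 500L,
                               n_classes = 4L, seed = 1L,
                               mode = c("gini", "variance")) {
  mode <- match.arg(mode)
  if (is.data.frame(x) && is.null(y)) y <- x$agb
  X <- selection_matrix(x)
  stopifnot(nrow(X) >= 10)
  set.seed(derive_seed(seed, "rf-gini"))
  if (mode == "gini") {
    yc <- discretize_target(y, n_classes)
    fit <- randomForest::randomForest(X, yc, ntree = n_trees)
    imp <- fit$importance[, "MeanDecreaseGini"]
  } else {
    fit <- randomForest::randomForest(X, y, ntree = n_trees)
    imp <- fit$importance[, "IncNodePurity"]
  }
  ranking_frame(colnames(X), unname(imp), "RF-Gini", seed)
}

#' Random-forest out-of-bag permutation importance
#'
#' Grows a regression forest; for every tree the out-of-bag (OOB) mean
#' squared error \eqn{E_1} is compared with the OOB error \eqn{E_2}
#' obtained after corrupting feature F by permuting its column (one
#' seeded permutation per feature, evaluated on each tree's OOB samples),
#' and \eqn{IMP_F = \sum_k (E_2^{(k)} - E_1^{(k)}) / K}. `corrupt =
#' "noise"` instead adds Gaussian noise of the feature's own standard
#' deviation.
#'
#' @inheritParams rrelieff
#' @param n_trees Number of trees K.
#' @param corrupt `"permute"` (default) or `"noise"`.
#' @param permutations Optional named list of explicit permutation index
#'   vectors per feature (e.g. an identity permutation, which forces
#'   \eqn{E_2 = E_1} and importance 0).
#' @return `importance_ranking` data frame.
#' @export
rf_oob_importance <- function(x, y = NULL, n_trees = 500L, seed = 1L,
                              corrupt = c("permute", "noise"),
                              permutations = NULL) {
  corrupt <- match.arg(corrupt)
  if (is.data.frame(x) && is.null(y)) y <- x$agb
  X <- selection_matrix(x)
  n <- nrow(X)
  stopifnot(n >= 10, length(y) == n)
  set.seed(derive_seed(seed, "rf-oob"))
  fit <- randomForest::randomForest(X, y, ntree = n_trees,
                                    keep.inbag = TRUE, keep.forest = TRUE)
  pred_all <- predict(fit, X, predict.all = TRUE)$individual  # n x K
  oob <- fit$inbag == 0
  oob_n <- colSums(oob)
  usable <- oob_n >= 2
  if (!all(usable)) {
    warning(sum(!usable), " tree(s) with < 2 OOB samples contribute 0",
            call. = FALSE)
  }
  e1 <- vapply(seq_len(n_trees), function(k) {
    if (!usable[k]) return(NA_real_)
    mean((y[oob[, k]] - pred_all[oob[, k], k])^2)
  }, numeric(1))

  imp <- vapply(seq_len(ncol(X)), function(f) {
    Xp <- X
    fname <- colnames(X)[f]
    if (corrupt == "permute") {
      perm <- if (!is.null(permutations) && !is.null(permutations[[fname]]))
        permutations[[fname]]
      else {
        set.seed(derive_seed(seed, paste0("perm-", fname)))
        sample.int(n)
      }
      Xp[, f] <- X[perm, f]
    } else {
      set.seed(derive_seed(seed, paste0("noise-", fname)))
      Xp[, f] <- X[, f] + rnorm(n, 0, max(sd(X[, f]), 1e-12))
    }
    pp <- predict(fit, Xp, predict.all = TRUE)$individual
    e2 <- vapply(seq_len(n_trees), function(k) {
      if (!usable[k]) return(NA_real_)
      mean((y[oob[, k]] - pp[oob[, k], k])^2)
    }, numeric(1))
    d <- e2 - e1
    d[!usable] <- 0
    mean(d)
  }, numeric(1))
  ranking_frame(colnames(X), imp, "RF-OOB", seed)
}

#' Select the top-ranked features
#'
#' Returns the `n` best-ranked feature names; if fewer than `n` features
#' are available, all of them are selected. Ties in weight are broken by
#' the fixed feature order of the table.
#'
#' @param ranking An `importance_ranking` data frame.
#' @param n Number of features to keep (default 10).
#' @return Character vector of feature names.
#' @export
select_top <- function(ranking, n = 10L) {
  stopifnot(all(c("feature", "rank") %in% names(ranking)))
  n <- min(n, nrow(ranking))
  ranking$feature[order(ranking$rank)][seq_len(n)]
}

#' Pearson correlation screen against AGB
#'
#' @param x Feature matrix or feature table.
#' @param y Numeric target; defaults to `x$agb` for feature tables.
#' @param features Optional subset of feature names.
#' @return Data frame `feature, r, zero_variance`; zero-variance features
#'   are flagged and get r = 0.
#' @export
correlation_screen <- function(x, y = NULL, features = NULL) {
  if (is.data.frame(x) && is.null(y)) y <- x$agb
  X <- selection_matrix(x)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  stopifnot(nrow(X) >= 3, length(y) == nrow(X))
  zv <- apply(X, 2, function(v) sd(v[is.finite(v)]) == 0)
  r <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    keep <- is.finite(v) & is.finite(y)
    if (sum(keep) < 3 || sd(v[keep]) == 0 || sd(y[keep]) == 0) 0
    else cor(v[keep], y[keep])
  }, numeric(1))
  data.frame(feature = colnames(X), r = r, zero_variance = zv,
             stringsAsFactors = FALSE)
}

#' Synthetic benchmark table for selection methods
#'
#' Builds an n x 39 feature table in which AGB is a noisy linear function
#' of five known features, the rest being independent noise -- the
#' recovery setting used to validate the three selection methods.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param informative Names given to the five informative features.
#' @return List with `table` (feature data frame including `agb`) and
#'   `informative` (the five feature names).
#' @export
simulate_feature_table <- function(n = 144L, seed = 1L,
                                   informative = paste0("S", 1:5)) {
  stopifnot(length(informative) == 5)
  set.seed(derive_seed(seed, "selection-benchmark"))
  p <- 39L
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- c(informative, paste0("N", seq_len(p - 5)))
  beta <- c(3, 2.5, 2, 1.5, 1.2)
  agb <- as.vector(X[, 1:5] %*% beta) + rnorm(n, 0, 0.5)
  tab <- data.frame(X, agb = agb)
  list(table = tab, informative = informative)
}
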