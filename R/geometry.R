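#' Canopy height from surface and terrain models
#'
#' Per-pixel canopy height is `max(DSM - DEM, 0)`. With an ROI the plot
#' height is the mean over the ROI pixels; without one the full height map
#' is returned.
#'
#' @param dsm,dem Co-registered numeric matrices of identical shape (m).
#' @param roi Optional ROI `c(row0, row1, col0, col1)` (0-based,
#'   half-open) or plot-record row.
#' @return Plot mean height (m) if `roi` is given, else the height matrix.
#' @export
canopy_height <- function(dsm, dem, roi = NULL) {
  stopifnot(is.matrix(dsm), is.matrix(dem))
  if (!all(dim(dsm) == dim(dem))) {
    stop("DSM and DEM shapes differ", call. = FALSE)
  }
  chm <- pmax(dsm - dem, 0)
  if (is.null(roi)) return(chm)
  r <- roi_bounds(roi, dim(chm))
  mean(chm[(r[1] + 1L):r[2], (r[3] + 1L):r[4]])
}

#' Per-pixel NDVI map of a cube
#'
#' @param cube A [refl_cube()].
#' @return Matrix of NDVI values (`NA` where the denominator is zero).
#' @export
ndvi_map <- function(cube) {
  stopifnot(inherits(cube, "refl_cube"))
  nir <- cube$data[, , 6]; red <- cube$data[, , 3]
  den <- nir + red
  out <- (nir - red) / den
  out[abs(den) < 1e-12] <- NA_real_
  out
}

#' Fractional vegetation cover by the dimidiate pixel model
#'
#' The bare-soil and pure-plant NDVI bounds are the lower and upper
#' `(1 - confidence)/2` quantiles of the scene NDVI (98\% confidence by
#' default, i.e. the 1st/99th percentiles). Per-pixel FVC is
#' `(NDVI - NDVI_NS) / (NDVI_PP - NDVI_NS)` clipped to [0, 1]; the plot
#' value is the ROI mean.
#'
#' @param ndvi_pixels Scene NDVI matrix (see [ndvi_map()]).
#' @param roi ROI bounds (0-based, half-open) or plot-record row.
#' @param confidence Central confidence used for the bounds.
#' @return Object of class `fvc_estimate`: list with `method = "DPM"`,
#'   `value`, `ndvi_ns`, `ndvi_pp`.
#' @export
fvc_dpm <- function(ndvi_pixels, roi, confidence = 0.98) {
  stopifnot(is.matrix(ndvi_pixels), confidence > 0, confidence < 1)
  vals <- ndvi_pixels[is.finite(ndvi_pixels)]
  if (length(vals) < 10) {
    stop("need >= 10 finite NDVI pixels for stable percentiles",
         call. = FALSE)
  }
  a <- (1 - confidence) / 2
  ns <- unname(quantile(vals, a))
  pp <- unname(quantile(vals, 1 - a))
  if (pp - ns <= 1e-9) {
    stop("degenerate scene: NDVI_PP <= NDVI_NS", call. = FALSE)
  }
  r <- roi_bounds(roi, dim(ndvi_pixels))
  px <- ndvi_pixels[(r[1] + 1L):r[2], (r[3] + 1L):r[4]]
  fvc <- clip01((px - ns) / (pp - ns))
  structure(list(method = "DPM", value = mean(fvc, na.rm = TRUE),
                 ndvi_ns = ns, ndvi_pp = pp),
            class = "fvc_estimate")
}

#' Train a pixel classifier for vegetation cover
#'
#' Trains a support vector machine on band values of seed pixels. Seed
#' labels are taken from the scene NDVI extremes (pixels above the 0.85
#' quantile labeled vegetation, below the 0.15 quantile labeled soil),
#' or supplied explicitly.
#'
#' @param cube A [refl_cube()].
#' @param n_train Number of seed pixels sampled per class.
#' @param seed Integer seed for the sampling.
#' @param labels Optional logical matrix of known vegetation labels used
#'   instead of the NDVI seeding.
#' @return A fitted `e1071::svm` classifier over the six band values.
#' @export
train_fvc_classifier <- function(cube, n_train = 800L, seed = 1L,
                                 labels = NULL) {
  stopifnot(inherits(cube, "refl_cube"))
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1] * d[2], d[3])
  colnames(X) <- names(cube$wavelengths)
  if (is.null(labels)) {
    nd <- as.vector(ndvi_map(cube))
    qs <- quantile(nd, c(0.15, 0.85), na.rm = TRUE)
    veg_pool <- which(nd >= qs[2])
    soil_pool <- which(nd <= qs[1])
  } else {
    veg_pool <- which(as.vector(labels))
    soil_pool <- which(!as.vector(labels))
  }
  set.seed(derive_seed(seed, "fvc-classifier"))
  take <- function(pool) pool[sample.int(length(pool),
                                         min(n_train, length(pool)))]
  veg_take <- take(veg_pool)
  soil_take <- take(soil_pool)
  idx <- c(veg_take, soil_take)
  y <- factor(rep(c("veg", "soil"),
                  c(length(veg_take), length(soil_take))),
              levels = c("soil", "veg"))
  e1071::svm(x = X[idx, , drop = FALSE], y = y, kernel = "linear",
             scale = TRUE)
}

#' Fractional vegetation cover by pixel classification
#'
#' FVC is the number of ROI pixels classified as vegetation divided by the
#' total ROI pixel count. Any supervised pixel classifier over the six
#' band values fulfils the contract: a fitted `e1071::svm` from
#' [train_fvc_classifier()], or a plain function mapping an
#' `n x 6` band matrix to a logical vegetation indicator.
#'
#' @param cube A [refl_cube()].
#' @param roi ROI bounds (0-based, half-open) or plot-record row.
#' @param classifier Trained classifier (see above).
#' @return Object of class `fvc_estimate` with `method = "CLS"`.
#' @export
fvc_classification <- function(cube, roi, classifier) {
  stopifnot(inherits(cube, "refl_cube"))
  if (is.null(classifier)) stop("classifier not trained", call. = FALSE)
  r <- roi_bounds(roi, dim(cube$data)[1:2])
  sub <- cube$data[(r[1] + 1L):r[2], (r[3] + 1L):r[4], , drop = FALSE]
  X <- matrix(sub, prod(dim(sub)[1:2]), dim(sub)[3])
  colnames(X) <- names(cube$wavelengths)
  is_veg <- if (is.function(classifier)) {
    as.logical(classifier(X))
  } else {
    predict(classifier, X) == "veg"
  }
  structure(list(method = "CLS", value = mean(is_veg),
                 ndvi_ns = NA_real_, ndvi_pp = NA_real_),
            class = "fvc_estimate")
}

#' @export
print.fvc_estimate <- function(x, ...) {
  cat("<fvc_estimate>", x$method, "FVC =", round(x$value, 4), "\n")
  invisible(x)
}

#' Agreement between two FVC retrieval methods
#'
#' Compares paired plot-level FVC vectors from the dimidiate pixel model
#' and the classifier with the same metric definitions as the regression
#' evaluation (first argument plays the observed role).
#'
#' @param dpm,cls Equal-length numeric vectors (n >= 3).
#' @return List with `r2` and `rmse`.
#' @export
crossvalidate_fvc <- function(dpm, cls) {
  stopifnot(length(dpm) == length(cls))
  if (length(dpm) < 3) stop("need n >= 3 paired values", call. = FALSE)
  m <- evaluate_predictions(dpm, cls)
  list(r2 = m[["R2"]], rmse = m[["RMSE"]])
}
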