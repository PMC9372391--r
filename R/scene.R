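#' Configuration for a synthetic potato-trial scene
#'
#' Bundles the trial-design and imaging constants used by
#' [generate_scene()]. Defaults emulate a replicated factorial potato trial
#' (4 varieties x 4 NPK fertilization gradients x 3 repetitions = 48 plots)
#' imaged at one of three growth stages with a six-band multispectral
#' sensor over ridge-planted rows.
#'
#' @param seed Integer seed; fully determines the scene.
#' @param stage Growth stage: `"SP"` (seedling), `"FP"` (flowering) or
#'   `"TP"` (tuber).
#' @param n_varieties,n_fertilizer_levels,n_reps Trial-design counts
#'   (plots = product of the three).
#' @param plot_shape_px Plot ROI size in pixels, `c(rows, cols)`.
#' @param ridge_period_px Ridge spacing in pixels along the axis
#'   perpendicular to the ridges.
#' @param ridge_axis Axis along which ridge crests run: `"row"` or `"col"`.
#' @param mixing_noise_sd Gaussian noise sd added to mixed reflectance
#'   (reflectance units).
#' @param agb_noise_sd Gaussian noise sd on plot AGB (g/m2); `NULL` means
#'   4\% of the stage AGB span.
#' @param agb_range AGB clip range `c(min, max)` in g/m2; `NULL` selects a
#'   stage-specific default (SP 20-330, FP 50-700, TP 40-740).
#' @param soil_mix_range Half-width of the per-plot jitter of the
#'   lit/shaded soil split (the AGB-independent soil-background confound
#'   that plot-level vegetation indices absorb); 0 gives every plot the
#'   same soil composition.
#' @param scene_shape_px Optional full raster size `c(rows, cols)`; `NULL`
#'   sizes the raster to a near-square grid of plots.
#' @return Object of class `scene_config` (a validated list).
#' @export
scene_config <- function(seed = 1L, stage = c("SP", "FP", "TP"),
                         n_varieties = 4L, n_fertilizer_levels = 4L,
                         n_reps = 3L, plot_shape_px = c(60L, 40L),
                         ridge_period_px = 30L, ridge_axis = c("row", "col"),
                         mixing_noise_sd = 0.005, agb_noise_sd = NULL,
                         agb_range = NULL, soil_mix_range = 0.18,
                         scene_shape_px = NULL) {
  stage <- match.arg(stage)
  ridge_axis <- match.arg(ridge_axis)
  stopifnot(n_varieties >= 1, n_fertilizer_levels >= 1, n_reps >= 1,
            length(plot_shape_px) == 2, all(plot_shape_px >= 2),
            ridge_period_px >= 2, mixing_noise_sd >= 0,
            soil_mix_range >= 0, soil_mix_range <= 0.25)
  if (is.null(agb_range)) {
    agb_range <- switch(stage, SP = c(20, 330), FP = c(50, 700),
                        TP = c(40, 740))
  }
  stopifnot(length(agb_range) == 2, agb_range[2] > agb_range[1])
  if (is.null(agb_noise_sd)) agb_noise_sd <- 0.04 * diff(agb_range)
  stopifnot(agb_noise_sd >= 0)
  structure(list(
    seed = as.integer(seed), stage = stage,
    n_varieties = as.integer(n_varieties),
    n_fertilizer_levels = as.integer(n_fertilizer_levels),
    n_reps = as.integer(n_reps),
    plot_shape_px = as.integer(plot_shape_px),
    ridge_period_px = as.integer(ridge_period_px),
    ridge_axis = ridge_axis,
    mixing_noise_sd = mixing_noise_sd,
    agb_noise_sd = agb_noise_sd,
    agb_range = as.numeric(agb_range),
    soil_mix_range = soil_mix_range,
    scene_shape_px = if (!is.null(scene_shape_px))
      as.integer(scene_shape_px)
  ), class = "scene_config")
}

# Stage-specific canopy constants: maximum height (m) at full vigor and the
# split of the vegetated abundance over the stage's non-soil endmembers.
stage_constants <- function(stage) {
  switch(stage,
    SP = list(h_max = 0.25, veg_share = c(LL = 0.68, SL = 0.32)),
    FP = list(h_max = 0.60,
              veg_share = c(LL = 0.60, SL = 0.28, flower = 0.12)),
    TP = list(h_max = 0.50,
              veg_share = c(LGL = 0.42, SGL = 0.24, YL = 0.22,
                            flower = 0.12)))
}

#' Lay out the replicated trial on the raster grid
#'
#' Produces one plot record per variety x fertilizer x repetition cell,
#' tiled row-major onto a rectangular grid of non-overlapping ROIs. With
#' the defaults this yields the 48-plot layout on a 480 x 240 px raster.
#'
#' @param config A [scene_config()].
#' @return A `data.frame` with columns `plot_id`, `row0`, `row1`, `col0`,
#'   `col1` (0-based, half-open pixel bounds), `variety`, `fertilizer`
#'   (`N1P1K1` no fertilization ... `N4P4K4` double), `rep`, `stage`.
#' @export
generate_trial_layout <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  P <- config$n_varieties * config$n_fertilizer_levels * config$n_reps
  pr <- config$plot_shape_px[1]; pc <- config$plot_shape_px[2]
  if (is.null(config$scene_shape_px)) {
    gc <- ceiling(sqrt(P * pc / pr))
    gr <- ceiling(P / gc)
  } else {
    gr <- config$scene_shape_px[1] %/% pr
    gc <- config$scene_shape_px[2] %/% pc
    if (gr * gc < P) {
      stop("scene_shape_px too small: grid of ", gr, "x", gc,
           " plot cells cannot hold ", P, " plots", call. = FALSE)
    }
  }
  i <- seq_len(P) - 1L
  fr <- config$n_fertilizer_levels * config$n_reps
  variety <- i %/% fr
  fert <- (i %/% config$n_reps) %% config$n_fertilizer_levels
  rep_i <- i %% config$n_reps
  cell_r <- i %/% gc
  cell_c <- i %% gc
  data.frame(
    plot_id = sprintf("P%03d", i + 1L),
    row0 = cell_r * pr, row1 = (cell_r + 1L) * pr,
    col0 = cell_c * pc, col1 = (cell_c + 1L) * pc,
    variety = paste0("V", variety + 1L),
    fertilizer = sprintf("N%dP%dK%d", fert + 1L, fert + 1L, fert + 1L),
    rep = rep_i + 1L,
    stage = config$stage,
    stringsAsFactors = FALSE)
}

scene_grid_shape <- function(config) {
  lay <- generate_trial_layout(config)
  if (is.null(config$scene_shape_px)) {
    c(max(lay$row1), max(lay$col1))
  } else config$scene_shape_px
}

# Parametric endmember templates on the six band wavelengths (nm).
# Leaves: logistic red edge + green bump; yellow leaf: elevated visible;
# soil: linear brightness ramp; flower: bright, nearly flat.
endmember_template <- function(kind, wl = UAVAGB_WAVELENGTHS) {
  switch(kind,
    green_leaf = 0.03 + 0.45 * plogis((wl - 715) / 16) +
      0.05 * exp(-0.5 * ((wl - 555) / 30)^2),
    yellow_leaf = 0.08 + 0.35 * plogis((wl - 700) / 25) +
      0.16 * exp(-0.5 * ((wl - 570) / 45)^2),
    soil = 0.12 + 0.20 * (wl - 450) / 390,
    flower = 0.35 + 2e-4 * (wl - 450),
    stop("unknown endmember template: ", kind, call. = FALSE))
}

# Shadowed spectra are darker with a mild wavelength-dependent factor
# (shadows are relatively brighter in the NIR): scaling by a constant would
# make lit and shaded columns collinear and abundances unidentifiable.
shade_spectrum <- function(r, wl = UAVAGB_WAVELENGTHS) {
  r * (0.30 + 0.22 * (wl - 450) / 390)
}

#' Stage-specific endmember library
#'
#' Builds the pure-component spectra used for spectral mixture analysis at
#' each growth stage: seedling (`SP`) has lit/shaded leaf and lit/shaded
#' soil (LL, SL, LS, SS); flowering (`FP`) adds the flower; tuber (`TP`)
#' distinguishes lit/shaded green leaf and yellow leaf (LGL, SGL, YL, LS,
#' SS, flower). Spectra are parametric templates with small seeded
#' per-band jitter; reflectances lie in [0, 1].
#'
#' @param stage `"SP"`, `"FP"` or `"TP"`.
#' @param seed Integer seed for the jitter.
#' @return An [endmember_library()] object.
#' @export
generate_endmembers <- function(stage, seed = 1L) {
  stopifnot(stage %in% c("SP", "FP", "TP"))
  wl <- UAVAGB_WAVELENGTHS
  leaf <- endmember_template("green_leaf", wl)
  soil <- endmember_template("soil", wl)
  base <- switch(stage,
    SP = list(LL = leaf, SL = shade_spectrum(leaf),
              LS = soil, SS = shade_spectrum(soil)),
    FP = list(LL = leaf, SL = shade_spectrum(leaf),
              LS = soil, SS = shade_spectrum(soil),
              flower = endmember_template("flower", wl)),
    TP = list(LGL = leaf, SGL = shade_spectrum(leaf),
              YL = endmember_template("yellow_leaf", wl),
              LS = soil, SS = shade_spectrum(soil),
              flower = endmember_template("flower", wl)))
  set.seed(derive_seed(seed, paste0("endmembers-", stage)))
  spectra <- t(vapply(base, function(r) {
    clip01(r * (1 + rnorm(length(r), 0, 0.015)))
  }, numeric(length(wl))))
  endmember_library(stage, rownames(spectra), spectra,
                    is_soil = names(base) %in% c("LS", "SS"))
}

#' Generate a full synthetic trial scene
#'
#' Builds the reflectance cube, surface/terrain models and ground-truth
#' tables for one growth stage. Per-pixel reflectance is a fully
#' constrained linear mixture of the stage endmembers plus Gaussian noise,
#' clipped to [0, 1]. Vegetation abundance follows a ridge-periodic
#' pattern whose canopy width and density grow with a per-plot latent
#' vigor `v` (a monotone function of fertilization level plus a variety
#' offset plus noise). True AGB is an affine function of a latent combining
#' `v` with small independent height and cover jitters; canopy height is
#' `h_max * v^0.7` (times the height jitter) inside the vegetation mask and
#' 0 elsewhere; DSM = DEM + height.
#'
#' @param config A [scene_config()].
#' @return Object of class `uav_scene`: list with elements `cube`
#'   (a `refl_cube`), `dsm`, `dem` (matrices, m), `truth` (list: `plots`
#'   data frame with latents and true AGB, `abundance` array, `height_map`,
#'   `veg_mask`), `layout` (plot records with `measured_agb`,
#'   `measured_height`), `endmembers`, and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  layout <- generate_trial_layout(config)
  shp <- scene_grid_shape(config)
  nr <- shp[1]; nc <- shp[2]
  lib <- generate_endmembers(config$stage, config$seed)
  sc <- stage_constants(config$stage)
  M <- nrow(lib$spectra)

  # per-plot latents
  set.seed(derive_seed(config$seed, "latents"))
  P <- nrow(layout)
  fert_level <- as.integer(substr(layout$fertilizer, 2, 2))
  var_idx <- as.integer(sub("V", "", layout$variety))
  var_off <- seq(-0.06, 0.06, length.out = max(config$n_varieties, 2))
  v <- pmin(pmax(0.1 + 0.27 * (fert_level - 1) + var_off[var_idx] +
                   rnorm(P, 0, 0.04), 0.05), 0.95)
  eta_h <- rnorm(P, 0, 0.06)
  eta_c <- rnorm(P, 0, 0.04)
  # AGB-independent soil-composition confound: the lit/shaded soil split
  # varies across plots, so plot-level VIs absorb soil signal that the
  # abundance-weighted (soil-free) VIs suppress
  soil_mix <- runif(P, -config$soil_mix_range, config$soil_mix_range)
  span <- diff(config$agb_range)
  # canopy vigor: superlinear in the canopy amount (cover x density) the
  # ridge profile realizes -- mass accumulates faster than cover; AGB is
  # affine in vigor plus the height/texture latents
  amount <- 0.28 + 0.65 * v
  amt01 <- (amount - 0.3125) / 0.585
  vigor <- 0.3 * amt01 + 0.7 * amt01^2
  latent <- clip01(vigor + eta_h + eta_c)
  agb <- config$agb_range[1] + 0.02 * span + 0.94 * span * latent +
    rnorm(P, 0, config$agb_noise_sd)
  agb <- pmin(pmax(agb, config$agb_range[1]), config$agb_range[2])
  plot_height <- sc$h_max * v^0.7 * pmax(1 + eta_h, 0)

  # per-pixel abundances: steep ridge-periodic canopy profile
  abundance <- array(0, dim = c(nr, nc, M),
                     dimnames = list(NULL, NULL, lib$names))
  soil_idx <- which(lib$is_soil)
  veg_idx <- match(names(sc$veg_share), lib$names)
  u_axis <- if (config$ridge_axis == "row") "row" else "col"
  for (p in seq_len(P)) {
    rows <- (layout$row0[p] + 1L):layout$row1[p]
    cols <- (layout$col0[p] + 1L):layout$col1[p]
    w <- pmin(pmax(0.28 + 0.65 * v[p], 0.05), 0.95)
    plateau <- 1
    u <- if (u_axis == "row") rows - 1L else cols - 1L
    s <- if (u_axis == "row") cols - 1L else rows - 1L
    prof <- plateau * plogis(14 * (cos(2 * pi * u /
                                         config$ridge_period_px) -
                                     cos(pi * w)))
    a_veg <- if (u_axis == "row") {
      matrix(prof, length(rows), length(cols))
    } else {
      matrix(prof, length(rows), length(cols), byrow = TRUE)
    }
    # furrow shadow banding: the lit/shaded soil split oscillates along
    # the ridge with per-plot amplitude (the texture latent eta_c) --
    # strong co-occurrence signal, near-zero effect on plot means
    band_amp <- 0.25 * pmin(pmax(0.5 + 4 * eta_c[p], 0), 1)
    ls_share <- pmin(pmax(0.68 - soil_mix[p] -
                            band_amp * sin(2 * pi * s / 6), 0.02), 0.98)
    ls_map <- if (u_axis == "row") {
      matrix(ls_share, length(rows), length(cols), byrow = TRUE)
    } else {
      matrix(ls_share, length(rows), length(cols))
    }
    for (k in seq_along(veg_idx)) {
      abundance[rows, cols, veg_idx[k]] <- a_veg * sc$veg_share[k]
    }
    abundance[rows, cols, soil_idx[1]] <- (1 - a_veg) * ls_map
    abundance[rows, cols, soil_idx[2]] <- (1 - a_veg) * (1 - ls_map)
  }
  # pixels outside any plot (unused grid cells) are bare soil
  covered <- matrix(FALSE, nr, nc)
  for (p in seq_len(P)) {
    covered[(layout$row0[p] + 1L):layout$row1[p],
            (layout$col0[p] + 1L):layout$col1[p]] <- TRUE
  }
  if (!all(covered)) {
    base_soil <- c(0.68, 0.32)
    for (k in seq_along(soil_idx)) {
      band <- abundance[, , soil_idx[k]]
      band[!covered] <- base_soil[k]
      abundance[, , soil_idx[k]] <- band
    }
  }

  # mix: R = sum_i Abd_i * R_i + noise, clipped to [0, 1]
  flat_abd <- matrix(abundance, nr * nc, M)
  refl <- flat_abd %*% lib$spectra
  if (config$mixing_noise_sd > 0) {
    set.seed(derive_seed(config$seed, "mixing-noise"))
    refl <- refl + rnorm(length(refl), 0, config$mixing_noise_sd)
  }
  refl <- clip01(refl)
  cube_data <- array(refl, dim = c(nr, nc, length(UAVAGB_WAVELENGTHS)))
  cube <- refl_cube(cube_data)

  veg_mask <- matrix(rowSums(flat_abd[, !lib$is_soil, drop = FALSE]) > 0.5,
                     nr, nc)
  height_map <- matrix(0, nr, nc)
  for (p in seq_len(P)) {
    rows <- (layout$row0[p] + 1L):layout$row1[p]
    cols <- (layout$col0[p] + 1L):layout$col1[p]
    height_map[rows, cols][veg_mask[rows, cols]] <- plot_height[p]
  }
  rr <- matrix(seq_len(nr) - 1L, nr, nc)
  cc <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
  dem <- 200 + 0.0015 * rr + 0.001 * cc + 0.05 * sin(2 * pi * cc / 150)
  dsm <- dem + height_map

  # under linear mixing the summed non-soil abundance is the subpixel
  # vegetated-area fraction, so true plot FVC is its ROI mean
  veg_frac <- matrix(rowSums(flat_abd[, !lib$is_soil, drop = FALSE]),
                     nr, nc)
  fvc_truth <- vapply(seq_len(P), function(p) {
    mean(veg_frac[(layout$row0[p] + 1L):layout$row1[p],
                  (layout$col0[p] + 1L):layout$col1[p]])
  }, numeric(1))

  truth_plots <- data.frame(plot_id = layout$plot_id, vigor = vigor,
                            fertility = v,
                            eta_h = eta_h, eta_c = eta_c, agb = agb,
                            height = plot_height, fvc = fvc_truth,
                            stringsAsFactors = FALSE)
  layout$measured_agb <- agb
  layout$measured_height <- plot_height

  structure(list(cube = cube, dsm = dsm, dem = dem,
                 truth = list(plots = truth_plots, abundance = abundance,
                              height_map = height_map,
                              veg_mask = veg_mask),
                 layout = layout, endmembers = lib, config = config),
            class = "uav_scene")
}

#' @export
print.uav_scene <- function(x, ...) {
  cat("<uav_scene> stage", x$config$stage, "--",
      nrow(x$layout), "plots,",
      paste(dim(x$cube$data)[1:2], collapse = " x "), "px\n")
  invisible(x)
}
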