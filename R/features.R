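#' Extract the 39 candidate predictors from one or more scenes
#'
#' For every plot of every scene, computes the four dimensions of
#' candidate variables:
#' \itemize{
#' \item SV (6): soil-free vegetation indices `NDVI_v ... OSAVI_v` -- the
#'   plot-level index times the plot's summed non-soil abundance from
#'   per-pixel fully constrained unmixing (or from unmixing the
#'   plot-mean spectrum with `vi_v_mode = "plot"`).
#' \item TV (6): the six GLCM statistics of the band/direction pair most
#'   correlated with AGB, screened over all 6 bands x 3 ridge-relative
#'   directions (columns `TEX_<band>_<dir>_<stat>`).
#' \item GV (2): `HEIGHT_m` (mean DSM-DEM over the ROI) and `FVC`
#'   (dimidiate pixel model by default, or pixel classification).
#' \item FDV (25): harmonic decomposition parameters of the plot-mean
#'   spectrum (`A0half, A1..A6, B1..B6, C1..C6, PHI1..PHI6`).
#' }
#'
#' @param scenes A `uav_scene` or named list of them (one per stage).
#' @param glcm_levels,glcm_distance GLCM quantization levels and pair
#'   distance.
#' @param fvc_method `"dpm"` or `"cls"`.
#' @param dpm_confidence Central confidence for the DPM NDVI bounds.
#' @param vi_v_mode `"pixel"`: plot vegetation abundance is the ROI mean
#'   of the per-pixel non-soil abundance map (default); `"plot"`: unmix
#'   the plot-mean spectrum instead.
#' @param texture_source Optional list `(band, direction)` to bypass the
#'   AGB-based screening (useful when no AGB is available).
#' @param seed Seed for the FVC classifier (`fvc_method = "cls"`).
#' @return Feature table: `sample_id, plot_id, stage, variety,
#'   fertilizer, rep`, the 39 feature columns, and `agb`. The dimension
#'   map is attached as `attr(x, "dims")` and the screened texture source
#'   as `attr(x, "texture_source")`.
#' @export
extract_features <- function(scenes, glcm_levels = 32L,
                             glcm_distance = 1L,
                             fvc_method = c("dpm", "cls"),
                             dpm_confidence = 0.98,
                             vi_v_mode = c("pixel", "plot"),
                             texture_source = NULL, seed = 1L) {
  fvc_method <- match.arg(fvc_method)
  vi_v_mode <- match.arg(vi_v_mode)
  if (inherits(scenes, "uav_scene")) scenes <- list(scenes)
  base_rows <- list()
  tex_rows <- list()
  for (scene in scenes) {
    stopifnot(inherits(scene, "uav_scene"))
    cube <- scene$cube
    layout <- scene$layout
    lib <- scene$endmembers
    ridge_axis <- scene$config$ridge_axis
    nd <- ndvi_map(cube)
    veg_map <- if (vi_v_mode == "pixel") {
      vegetation_abundance_map(unmix_image(cube, lib), lib)
    }
    classifier <- if (fvc_method == "cls") {
      train_fvc_classifier(cube, seed = seed)
    }
    for (p in seq_len(nrow(layout))) {
      roi <- layout[p, ]
      spec <- plot_mean_spectrum(cube, roi)
      vis <- compute_all_vis(spec)
      veg_abund <- if (vi_v_mode == "pixel") {
        r <- roi_bounds(roi, dim(nd))
        mean(veg_map[(r[1] + 1L):r[2], (r[3] + 1L):r[4]])
      } else {
        vegetation_abundance(unmix_fcls(spec, lib), lib)
      }
      sv <- stats::setNames(vapply(vis, compute_vi_v, numeric(1),
                                   veg_abund = veg_abund),
                            paste0(names(vis), "_v"))
      fvc <- if (fvc_method == "dpm") {
        fvc_dpm(nd, roi, dpm_confidence)$value
      } else {
        fvc_classification(cube, roi, classifier)$value
      }
      gv <- c(HEIGHT_m = canopy_height(scene$dsm, scene$dem, roi),
              FVC = fvc)
      fdv <- harmonic_vector(spec)
      base_rows[[length(base_rows) + 1L]] <- data.frame(
        sample_id = paste0(layout$stage[p], "_", layout$plot_id[p]),
        plot_id = layout$plot_id[p], stage = layout$stage[p],
        variety = layout$variety[p], fertilizer = layout$fertilizer[p],
        rep = layout$rep[p],
        as.list(c(sv, gv, fdv)),
        agb = layout$measured_agb[p],
        stringsAsFactors = FALSE)
      r <- roi_bounds(roi, dim(cube$data)[1:2])
      tex <- unlist(lapply(seq_along(cube$wavelengths), function(b) {
        w <- cube$data[(r[1] + 1L):r[2], (r[3] + 1L):r[4], b]
        tf <- texture_features(w, glcm_levels, glcm_distance, ridge_axis)
        stats::setNames(tf, paste0("TEX_", names(cube$wavelengths)[b],
                                   "_", names(tf)))
      }))
      tex_rows[[length(tex_rows) + 1L]] <- as.data.frame(as.list(tex))
    }
  }
  base <- do.call(rbind, base_rows)
  tex_all <- do.call(rbind, tex_rows)
  if (is.null(texture_source)) {
    texture_source <- screen_texture_source(tex_all, base$agb)
  }
  sel <- paste0("TEX_", texture_source$band, "_",
                texture_source$direction, "_", GLCM_STATS)
  out <- cbind(base[setdiff(names(base), "agb")], tex_all[sel],
               agb = base$agb)
  # fixed column order: SV, TV, GV, FDV
  id_cols <- c("sample_id", "plot_id", "stage", "variety", "fertilizer",
               "rep")
  sv_cols <- paste0(VI_NAMES, "_v")
  dims <- list(SV = sv_cols, TV = sel, GV = c("HEIGHT_m", "FVC"),
               FDV = harmonic_feature_names())
  out <- out[c(id_cols, unlist(dims, use.names = FALSE), "agb")]
  attr(out, "dims") <- dims
  attr(out, "texture_source") <- texture_source[c("band", "direction")]
  out
}

#' Names and dimension map of the 39 candidate features
#'
#' @param tex_band,tex_direction Band and direction of the texture
#'   variables (the screened pair).
#' @return Named list of feature-name vectors for the four dimensions
#'   `SV` (6), `TV` (6), `GV` (2), `FDV` (25).
#' @export
feature_dimensions <- function(tex_band = "B", tex_direction = "Dperp") {
  list(SV = paste0(VI_NAMES, "_v"),
       TV = paste0("TEX_", tex_band, "_", tex_direction, "_", GLCM_STATS),
       GV = c("HEIGHT_m", "FVC"),
       FDV = harmonic_feature_names())
}
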