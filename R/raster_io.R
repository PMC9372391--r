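#' Six-band reflectance cube
#'
#' Container for a six-band reflectance raster. Bands are ordered by
#' ascending center wavelength (450, 555, 660, 720, 750, 840 nm); all
#' values must be finite and in [0, 1].
#'
#' @param data Numeric array `rows x cols x 6` of reflectance.
#' @param wavelengths Band center wavelengths in nm, ascending.
#' @param transform Pixel-to-world affine as `c(a, b, c, d, e, f)` in
#'   world-file order (x-scale, rotations, y-scale, upper-left x, y).
#' @return Object of class `refl_cube`.
#' @export
refl_cube <- function(data, wavelengths = UAVAGB_WAVELENGTHS,
                      transform = c(1, 0, 0, -1, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[3] != length(wavelengths)) {
    stop("reflectance cube must have ", length(wavelengths), " bands, got ",
         dim(data)[3], call. = FALSE)
  }
  if (is.unsorted(wavelengths)) stop("wavelengths must be ascending",
                                     call. = FALSE)
  if (!all(is.finite(data)) || min(data) < 0 || max(data) > 1) {
    stop("reflectance values must be finite and in [0, 1]", call. = FALSE)
  }
  dimnames(data)[[3]] <- names(wavelengths) %||%
    paste0("nm", wavelengths)
  structure(list(data = data, wavelengths = wavelengths,
                 transform = as.numeric(transform)),
            class = "refl_cube")
}

#' @export
print.refl_cube <- function(x, ...) {
  cat("<refl_cube>", paste(dim(x$data)[1:2], collapse = " x "), "px,",
      length(x$wavelengths), "bands (", paste(x$wavelengths,
      collapse = ", "), "nm )\n")
  invisible(x)
}

write_world_file <- function(transform, path) {
  # ESRI world file: x-scale, y-rot, x-rot, y-scale, x-origin, y-origin
  writeLines(format(transform[c(1, 2, 3, 4, 5, 6)], digits = 17), path)
}

read_world_file <- function(path) {
  as.numeric(readLines(path))
}

#' Write / read a reflectance cube
#'
#' Cubes are stored as multi-page 32-bit float TIFF (one page per band,
#' ascending wavelength) with an ESRI world-file (`.tfw`) carrying the
#' affine transform and a JSON sidecar carrying band wavelengths.
#'
#' @param cube A [refl_cube()].
#' @param path Output `.tif` path.
#' @return `write_cube`: the path, invisibly. `read_cube`: a `refl_cube`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "refl_cube"))
  pages <- lapply(seq_along(cube$wavelengths),
                  function(b) cube$data[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_world_file(cube$transform, sub("\\.tif{1,2}$", ".tfw", path))
  jsonlite::write_json(list(wavelengths_nm = unname(cube$wavelengths),
                            band_names = names(cube$wavelengths)),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_cube
#' @param clip If `TRUE`, values slightly outside [0, 1] are clipped on
#'   read; if `FALSE` (default) they are rejected.
#' @export
read_cube <- function(path, clip = FALSE) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(UAVAGB_WAVELENGTHS)) {
    stop("expected a 6-band raster, got ", length(pages), " band(s)",
         call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  wl <- UAVAGB_WAVELENGTHS
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    wl <- stats::setNames(meta$wavelengths_nm, meta$band_names)
    ord <- order(wl)
    wl <- wl[ord]; pages <- pages[ord]
  }
  data <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (min(data) < 0 || max(data) > 1) {
    if (clip) data <- clip01(data)
    else stop("reflectance outside [0, 1]; pass clip = TRUE to clip",
              call. = FALSE)
  }
  tfw <- sub("\\.tif{1,2}$", ".tfw", path)
  transform <- if (file.exists(tfw)) read_world_file(tfw)
               else c(1, 0, 0, -1, 0, 0)
  refl_cube(data, wl, transform)
}

#' Write / read a single-band raster (e.g. DSM, DEM)
#'
#' Stored as 32-bit float TIFF. Values of arbitrary magnitude are packed
#' linearly to [0, 1] with the offset and scale recorded in a JSON
#' sidecar, plus a world file for the affine transform.
#'
#' @param x Numeric matrix.
#' @param path Output `.tif` path.
#' @param transform Affine transform in world-file order.
#' @return `write_raster`: the path, invisibly; `read_raster`: a matrix.
#' @export
write_raster <- function(x, path, transform = c(1, 0, 0, -1, 0, 0)) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  off <- min(x)
  scl <- max(x) - off
  packed <- if (scl > 0) (x - off) / scl else x * 0
  tiff::writeTIFF(packed, path, bits.per.sample = 32L)
  jsonlite::write_json(list(offset = off, scale = scl),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_world_file(transform, sub("\\.tif{1,2}$", ".tfw", path))
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  packed <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  packed * meta$scale + meta$offset
}

#' Plot-mean reflectance spectrum
#'
#' The plot-level spectrum is the arithmetic mean reflectance per band over
#' the ROI pixels.
#'
#' @param cube A [refl_cube()].
#' @param roi ROI as `c(row0, row1, col0, col1)`, 0-based half-open, or a
#'   plot-record row with those columns.
#' @return Named 6-vector of mean reflectance.
#' @export
plot_mean_spectrum <- function(cube, roi) {
  stopifnot(inherits(cube, "refl_cube"))
  r <- roi_bounds(roi, dim(cube$data)[1:2])
  apply(cube$data[(r[1] + 1L):r[2], (r[3] + 1L):r[4], , drop = FALSE],
        3, mean)
}

# Validate and normalize an ROI spec to c(row0,row1,col0,col1) half-open.
roi_bounds <- function(roi, shape) {
  if (is.data.frame(roi) || is.list(roi)) {
    roi <- c(roi$row0, roi$row1, roi$col0, roi$col1)
  }
  roi <- as.integer(roi)
  stopifnot(length(roi) == 4)
  if (roi[2] <= roi[1] || roi[4] <= roi[3]) {
    stop("empty ROI", call. = FALSE)
  }
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > shape[1] || roi[4] > shape[2]) {
    stop("ROI out of raster bounds", call. = FALSE)
  }
  roi
}

PLOT_TABLE_REQUIRED <- c("plot_id", "row0", "row1", "col0", "col1",
                         "variety", "fertilizer", "rep", "stage")

#' Read / write the plot-layout table
#'
#' CSV with one row per plot: `plot_id, row0, row1, col0, col1, variety,
#' fertilizer, rep, stage` plus optional `measured_agb` (g/m2) and
#' `measured_height` (m). ROI bounds are 0-based, half-open.
#'
#' @param path CSV path.
#' @return `read_plot_table`: a `data.frame` of plot records.
#' @export
read_plot_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PLOT_TABLE_REQUIRED, names(tab))
  if (length(missing)) {
    stop("plot table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(tab$stage %in% c("SP", "FP", "TP"))) {
    stop("stage must be one of SP, FP, TP", call. = FALSE)
  }
  tab
}

#' @rdname read_plot_table
#' @param table Plot-record `data.frame`.
#' @export
write_plot_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a feature table
#'
#' Feature tables hold one row per plot-stage sample: identifier columns
#' (`sample_id`, `plot_id`, `stage`), the named feature columns and the
#' `agb` target. Numeric values survive the CSV round trip at full double
#' precision.
#'
#' @param table Feature `data.frame`.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"agb" %in% names(tab)) {
    stop("feature table is missing the 'agb' column", call. = FALSE)
  }
  tab
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report Report `data.frame` (see [run_experiment()]).
#' @param path Output path without extension; `.csv` and `.json` are added.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(report, paste0(path, ".json"), dataframe = "rows",
                       digits = NA)
  invisible(path)
}
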