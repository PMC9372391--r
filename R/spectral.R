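#' Endmember library
#'
#' Pure-component spectra used by the fully constrained unmixing. At least
#' one soil and one non-soil entry are required; reflectances in [0, 1].
#'
#' @param stage Growth stage label.
#' @param names Endmember names.
#' @param spectra Matrix `M x 6` of reflectances, bands ascending.
#' @param is_soil Logical vector: which entries are soil components.
#' @return Object of class `endmember_library`.
#' @export
endmember_library <- function(stage, names, spectra, is_soil) {
  spectra <- as.matrix(spectra)
  stopifnot(nrow(spectra) == length(names),
            length(is_soil) == length(names),
            ncol(spectra) == length(UAVAGB_WAVELENGTHS))
  if (length(names) < 2) {
    stop("library needs >= 2 endmembers", call. = FALSE)
  }
  if (!any(is_soil) || !any(!is_soil)) {
    stop("library needs at least one soil and one non-soil endmember",
         call. = FALSE)
  }
  if (!all(is.finite(spectra)) || min(spectra) < 0 || max(spectra) > 1) {
    stop("endmember reflectances must be in [0, 1]", call. = FALSE)
  }
  rownames(spectra) <- names
  colnames(spectra) <- names(UAVAGB_WAVELENGTHS)
  structure(list(stage = stage, names = names, spectra = spectra,
                 is_soil = as.logical(is_soil)),
            class = "endmember_library")
}

#' @export
print.endmember_library <- function(x, ...) {
  cat("<endmember_library> stage", x$stage, "--",
      paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an endmember library as CSV
#'
#' Columns: `stage, name, is_soil, R450, R555, R660, R720, R750, R840`.
#'
#' @param lib An [endmember_library()].
#' @param path CSV path.
#' @export
write_endmember_library <- function(lib, path) {
  df <- data.frame(stage = lib$stage, name = lib$names,
                   is_soil = lib$is_soil)
  sp <- lib$spectra
  colnames(sp) <- paste0("R", UAVAGB_WAVELENGTHS)
  utils::write.csv(cbind(df, as.data.frame(sp)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endmember_library
#' @export
read_endmember_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- paste0("R", UAVAGB_WAVELENGTHS)
  if (!all(c("stage", "name", "is_soil", cols) %in% names(df))) {
    stop("endmember CSV is missing required columns", call. = FALSE)
  }
  endmember_library(df$stage[1], df$name, as.matrix(df[cols]), df$is_soil)
}

VI_NAMES <- c("NDVI", "NDRE", "MTCI", "EVI2", "VARI", "OSAVI")

#' Names of the supported vegetation indices
#' @return Character vector of the six index names.
#' @export
vi_names <- function() VI_NAMES

#' Vegetation indices from a six-band spectrum
#'
#' Evaluates the named index on a band spectrum ordered by ascending
#' wavelength (450, 555, 660, 720, 750, 840 nm):
#' \deqn{NDVI = (R_{840} - R_{660}) / (R_{840} + R_{660})}
#' \deqn{NDRE = (R_{840} - R_{720}) / (R_{840} + R_{720})}
#' \deqn{MTCI = (R_{840} - R_{720}) / (R_{720} + R_{660})}
#' \deqn{EVI2 = 2.5 (R_{840} - R_{660}) / (R_{840} + 2.4 R_{660} + 1)}
#' \deqn{VARI = (R_{555} - R_{660}) / (R_{555} + R_{660})}
#' \deqn{OSAVI = 1.16 (R_{840} - R_{660}) / (R_{840} + R_{660} + 0.16)}
#' A zero denominator yields `NA` (the sample is treated as missing
#' downstream rather than raising an error).
#'
#' @param spectrum Numeric 6-vector of reflectance in [0, 1].
#' @param index_name One of [vi_names()].
#' @return Index value, or `NA` for a degenerate denominator.
#' @export
compute_vi <- function(spectrum, index_name) {
  stopifnot(length(spectrum) == 6, all(is.finite(spectrum)))
  index_name <- match.arg(index_name, VI_NAMES)
  g <- spectrum[2]; r <- spectrum[3]; re1 <- spectrum[4]; nir <- spectrum[6]
  ratio <- function(num, den) if (abs(den) < 1e-12) NA_real_ else num / den
  unname(switch(index_name,
    NDVI = ratio(nir - r, nir + r),
    NDRE = ratio(nir - re1, nir + re1),
    MTCI = ratio(nir - re1, re1 + r),
    EVI2 = ratio(2.5 * (nir - r), nir + 2.4 * r + 1),
    VARI = ratio(g - r, g + r),
    OSAVI = ratio(1.16 * (nir - r), nir + r + 0.16)))
}

#' @rdname compute_vi
#' @return `compute_all_vis`: named 6-vector of all indices.
#' @export
compute_all_vis <- function(spectrum) {
  vapply(VI_NAMES, compute_vi, numeric(1), spectrum = spectrum)
}

#' Fully constrained least-squares unmixing of one spectrum
#'
#' Finds abundances minimizing \eqn{\|R_{mp} - \sum_i Abd_i R_i\|_2}
#' subject to \eqn{0 \le Abd_i \le 1} and \eqn{\sum_i Abd_i = 1}, by an
#' active-set quadratic program. A rank-deficient library (e.g. duplicated
#' endmembers) is still solved -- the KKT system then uses the
#' minimum-norm pseudo-inverse solution -- but flagged non-unique.
#'
#' @param mixed Numeric 6-vector, the mixed-pixel spectrum.
#' @param lib An [endmember_library()].
#' @return List with `abundances` (named vector), `residual` (root mean
#'   square spectral error) and `nonunique` flag.
#' @export
unmix_fcls <- function(mixed, lib) {
  stopifnot(inherits(lib, "endmember_library"),
            length(mixed) == ncol(lib$spectra), all(is.finite(mixed)))
  fit <- .fcls_batch(matrix(mixed, nrow = 1), lib$spectra)
  nonunique <- qr(rbind(t(lib$spectra), 1))$rank < nrow(lib$spectra)
  list(abundances = stats::setNames(drop(fit$abundance), lib$names),
       residual = fit$residual[1], nonunique = nonunique)
}

#' Per-pixel unmixing of a reflectance cube
#'
#' Applies [unmix_fcls()] to every pixel, producing per-endmember
#' abundance maps and a residual map.
#'
#' @param cube A [refl_cube()].
#' @param lib An [endmember_library()].
#' @return List with `abundance` (array `rows x cols x M`, endmember names
#'   on the third dimension) and `residual` (matrix of RMS spectral error).
#' @export
unmix_image <- function(cube, lib) {
  stopifnot(inherits(cube, "refl_cube"), inherits(lib, "endmember_library"))
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1] * d[2], d[3])
  fit <- .fcls_batch(X, lib$spectra)
  list(abundance = array(fit$abundance, dim = c(d[1], d[2],
         nrow(lib$spectra)), dimnames = list(NULL, NULL, lib$names)),
       residual = matrix(fit$residual, d[1], d[2]))
}

#' Summed non-soil abundance
#'
#' Vegetation abundance of a pixel or plot is the sum of abundances over
#' all non-soil endmembers (leaves, yellow leaf and flower included).
#'
#' @param result Result of [unmix_fcls()], or a named abundance vector.
#' @param lib The [endmember_library()] used for unmixing.
#' @return Vegetation abundance in [0, 1].
#' @export
vegetation_abundance <- function(result, lib) {
  a <- if (is.list(result)) result$abundances else result
  sum(a[lib$names[!lib$is_soil]])
}

#' Non-soil abundance map from an unmixed image
#'
#' @param unmixed Result of [unmix_image()].
#' @param lib The [endmember_library()] used.
#' @return Matrix of per-pixel summed non-soil abundance.
#' @export
vegetation_abundance_map <- function(unmixed, lib) {
  veg <- unmixed$abundance[, , !lib$is_soil, drop = FALSE]
  apply(veg, c(1, 2), sum)
}

#' Soil-free vegetation index
#'
#' The soil-corrected index is the product of the plot-level index and the
#' plot's summed non-soil abundance.
#'
#' @param vi_plot Plot-level index value.
#' @param veg_abund Vegetation abundance in [0, 1].
#' @return `vi_plot * veg_abund` (`NA` propagates).
#' @export
compute_vi_v <- function(vi_plot, veg_abund) {
  stopifnot(is.na(veg_abund) || (veg_abund >= -1e-9 & veg_abund <= 1 + 1e-9))
  vi_plot * veg_abund
}
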