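GLCM_DIRECTIONS <- c("Dpar", "Dperp", "D45")
GLCM_STATS <- c("VAR", "HOM", "CON", "DIS", "ENT", "SEC")

#' Gray-level quantization of an image window
#'
#' Linear min-max scaling of the window into `levels` equal-width bins.
#' A constant window maps to bin 0.
#'
#' @param values Numeric matrix.
#' @param levels Number of gray levels G.
#' @return Integer matrix with values in `0 .. G-1`.
#' @export
quantize_gray <- function(values, levels = 32L) {
  stopifnot(is.matrix(values), all(is.finite(values)), levels >= 2)
  rng <- range(values)
  if (rng[2] == rng[1]) {
    return(matrix(0L, nrow(values), ncol(values)))
  }
  g <- floor((values - rng[1]) / (rng[2] - rng[1]) * levels)
  g[g == levels] <- levels - 1L
  mode(g) <- "integer"
  g
}

# Pixel-pair offset (drow, dcol) for a ridge-relative direction.
direction_offset <- function(direction, ridge_axis = "row") {
  direction <- match.arg(direction, GLCM_DIRECTIONS)
  stopifnot(ridge_axis %in% c("row", "col"))
  if (ridge_axis == "row") {
    # ridge crests run along image rows: along-ridge = column offset
    switch(direction, Dpar = c(0L, 1L), Dperp = c(1L, 0L),
           D45 = c(1L, 1L))
  } else {
    switch(direction, Dpar = c(1L, 0L), Dperp = c(0L, 1L),
           D45 = c(1L, 1L))
  }
}

#' Gray level co-occurrence matrix
#'
#' Counts ordered pixel pairs at the offset vector of a ridge-relative
#' direction (`Dpar` 1 px along the ridge, `Dperp` 1 px across, `D45`
#' 1 px diagonal; scaled by `distance`), symmetrized by adding the
#' transpose and normalized to probabilities.
#'
#' @param gray Integer matrix of gray levels in `0 .. levels-1`
#'   (see [quantize_gray()]).
#' @param direction `"Dpar"`, `"Dperp"` or `"D45"`.
#' @param distance Pair distance in pixels.
#' @param levels Number of gray levels; defaults to `max(gray) + 1`.
#' @param symmetric Symmetrize by adding the transpose (default).
#' @param ridge_axis Axis along which ridge crests run.
#' @return Object of class `glcm`: list with the `levels x levels`
#'   probability `matrix`, `direction`, `distance`, `symmetric`.
#' @export
compute_glcm <- function(gray, direction = "Dperp", distance = 1L,
                         levels = max(gray) + 1L, symmetric = TRUE,
                         ridge_axis = "row") {
  stopifnot(is.matrix(gray), min(gray) >= 0, max(gray) < levels)
  off <- direction_offset(direction, ridge_axis) * as.integer(distance)
  nr <- nrow(gray); nc <- ncol(gray)
  if (nr <= abs(off[1]) || nc <= abs(off[2])) {
    stop("window too small for offset (", off[1], ", ", off[2], ")",
         call. = FALSE)
  }
  r1 <- 1:(nr - abs(off[1])); c1 <- 1:(nc - abs(off[2]))
  a <- gray[r1, c1, drop = FALSE]
  b <- gray[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- matrix(tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                            nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(matrix = counts / sum(counts), levels = levels,
                 direction = direction, distance = as.integer(distance),
                 symmetric = symmetric),
            class = "glcm")
}

#' Haralick statistics of a co-occurrence matrix
#'
#' Standard definitions over the probability matrix \eqn{P(i,j)} with
#' 0-based levels: contrast \eqn{CON = \sum P (i-j)^2}; dissimilarity
#' \eqn{DIS = \sum P |i-j|}; homogeneity \eqn{HOM = \sum P / (1+(i-j)^2)};
#' entropy \eqn{ENT = -\sum P \ln P} (natural log, \eqn{0 \ln 0 = 0});
#' second moment \eqn{SEC = \sum P^2}; variance
#' \eqn{VAR = \sum P (i-\mu)^2} with \eqn{\mu} the marginal mean.
#'
#' @param glcm A [compute_glcm()] result (or a probability matrix).
#' @return Named vector `VAR, HOM, CON, DIS, ENT, SEC`.
#' @export
glcm_statistics <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$matrix else glcm
  stopifnot(abs(sum(P) - 1) < 1e-8, all(P >= 0))
  G <- nrow(P)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  d <- i - j
  mu <- sum(i * P)
  pnz <- P[P > 0]
  c(VAR = sum(P * (i - mu)^2),
    HOM = sum(P / (1 + d^2)),
    CON = sum(P * d^2),
    DIS = sum(P * abs(d)),
    ENT = -sum(pnz * log(pnz)),
    SEC = sum(P^2))
}

#' All texture features of one image window
#'
#' Quantizes the window and computes the six Haralick statistics in the
#' three ridge-relative directions.
#'
#' @param window Numeric matrix (one band's ROI).
#' @param levels Gray levels for quantization.
#' @param distance Pair distance in pixels.
#' @param ridge_axis Axis along which ridge crests run.
#' @return Named vector of 18 values, names `<dir>_<stat>`.
#' @export
texture_features <- function(window, levels = 32L, distance = 1L,
                             ridge_axis = "row") {
  g <- quantize_gray(window, levels)
  out <- unlist(lapply(GLCM_DIRECTIONS, function(d) {
    s <- glcm_statistics(compute_glcm(g, d, distance, levels,
                                      ridge_axis = ridge_axis))
    stats::setNames(s, paste0(d, "_", names(s)))
  }))
  out
}

#' Screen texture band and direction against AGB
#'
#' Selects the band/direction pair whose six texture statistics have the
#' highest mean absolute Pearson correlation with AGB. Zero-variance
#' features contribute r = 0; ties are broken by band order then
#' direction order.
#'
#' @param tex Data frame or matrix of texture columns named
#'   `TEX_<band>_<dir>_<stat>` (as built by [extract_features()]).
#' @param agb Numeric AGB vector, same length as rows of `tex`.
#' @return List with `band`, `direction` and the score table
#'   (`band, direction, mean_abs_r`).
#' @export
screen_texture_source <- function(tex, agb) {
  tex <- as.data.frame(tex)
  stopifnot(nrow(tex) == length(agb), nrow(tex) >= 3)
  parts <- strsplit(sub("^TEX_", "", names(tex)), "_")
  bands <- vapply(parts, `[`, "", 1)
  dirs <- vapply(parts, `[`, "", 2)
  band_order <- names(UAVAGB_WAVELENGTHS)
  grid <- expand.grid(direction = GLCM_DIRECTIONS,
                      band = intersect(band_order, unique(bands)),
                      stringsAsFactors = FALSE)[, c("band", "direction")]
  grid$mean_abs_r <- vapply(seq_len(nrow(grid)), function(k) {
    cols <- which(bands == grid$band[k] & dirs == grid$direction[k])
    rs <- vapply(cols, function(cc) {
      x <- tex[[cc]]
      if (sd(x) == 0 || sd(agb) == 0) 0 else abs(cor(x, agb))
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  best <- which.max(grid$mean_abs_r)  # first max: band then direction order
  list(band = grid$band[best], direction = grid$direction[best],
       scores = grid)
}
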