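#' Harmonic decomposition of a six-band spectrum
#'
#' Expresses the band spectrum \eqn{r_j} (j = 1..6, ascending wavelength)
#' as a constant plus sine/cosine terms:
#' \deqn{A_0/2 = \frac{1}{n}\sum_j r_j}
#' \deqn{A_t = \frac{2}{n}\sum_j r_j \cos(2\pi t j / n), \qquad
#'       B_t = \frac{2}{n}\sum_j r_j \sin(2\pi t j / n)}
#' for decomposition orders t = 1..6, with amplitude
#' \eqn{C_t = \sqrt{A_t^2 + B_t^2}} and phase
#' \eqn{\varphi_t = \mathrm{atan2}(A_t, B_t)} (the two-argument
#' arctangent resolves quadrants; a single-argument \eqn{\arctan(A_t/B_t)}
#' is undefined at \eqn{B_t = 0}, which provably occurs at t = 6). The
#' phase is defined as 0 when \eqn{C_t \approx 0}.
#'
#' With n = 6 the orders alias: \eqn{A_{6-t} = A_t},
#' \eqn{B_{6-t} = -B_t}, so \eqn{C_5 = C_1}, \eqn{C_4 = C_2}, and
#' \eqn{A_6 = 2 \cdot A_0/2}, \eqn{B_6 = 0}. All six orders are still
#' emitted because the downstream screening operates on the full
#' 25-parameter set.
#'
#' @param spectrum Numeric 6-vector ordered by ascending wavelength.
#' @return Object of class `harmonic_set`: list with `a0_half` and
#'   per-order vectors `A`, `B`, `C`, `phi` (t = 1..6).
#' @export
harmonic_decompose <- function(spectrum) {
  stopifnot(length(spectrum) == 6, all(is.finite(spectrum)))
  n <- 6L
  j <- 1:n
  t_ord <- 1:n
  A <- vapply(t_ord, function(t) 2 / n * sum(spectrum *
                                               cos(2 * pi * t * j / n)),
              numeric(1))
  B <- vapply(t_ord, function(t) 2 / n * sum(spectrum *
                                               sin(2 * pi * t * j / n)),
              numeric(1))
  C <- sqrt(A^2 + B^2)
  phi <- ifelse(C < 1e-12, 0, atan2(A, B))
  structure(list(a0_half = mean(spectrum), A = A, B = B, C = C,
                 phi = phi), class = "harmonic_set")
}

#' @export
print.harmonic_set <- function(x, ...) {
  cat("<harmonic_set> A0/2 =", round(x$a0_half, 4), " C_t =",
      paste(round(x$C, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Names of the 25 harmonic feature columns
#'
#' @return Character vector `A0half, A1..A6, B1..B6, C1..C6, PHI1..PHI6`
#'   in fixed order.
#' @export
harmonic_feature_names <- function() {
  c("A0half", paste0("A", 1:6), paste0("B", 1:6), paste0("C", 1:6),
    paste0("PHI", 1:6))
}

#' Harmonic parameters as a named feature vector
#'
#' @param spectrum Numeric 6-vector ordered by ascending wavelength.
#' @return Named 25-vector in [harmonic_feature_names()] order.
#' @export
harmonic_vector <- function(spectrum) {
  h <- harmonic_decompose(spectrum)
  stats::setNames(c(h$a0_half, h$A, h$B, h$C, h$phi),
                  harmonic_feature_names())
}
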