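# Shared fixtures: tiny scenes and libraries built in code.

small_config <- function(seed = 1L, stage = "SP", ...) {
  scene_config(seed = seed, stage = stage, n_varieties = 2L,
               n_fertilizer_levels = 2L, n_reps = 1L,
               plot_shape_px = c(40L, 30L), ...)
}

# A fixed, well-separated 3-endmember library used by the unmixing tests.
toy_library <- function() {
  endmember_library(
    stage = "SP",
    names = c("veg", "soil", "shade"),
    spectra = rbind(c(0.03, 0.08, 0.05, 0.28, 0.40, 0.48),
                    c(0.12, 0.17, 0.23, 0.26, 0.28, 0.32),
                    c(0.02, 0.03, 0.04, 0.05, 0.06, 0.08)),
    is_soil = c(FALSE, TRUE, FALSE))
}

random_simplex <- function(m) {
  x <- -log(runif(m))
  x / sum(x)
}

# Exhaustive simplex grid search oracle for 3-endmember FCLS: returns the
# minimum squared residual over abundances on a grid of the given step.
grid_fcls_residual <- function(x, E, step = 1e-3) {
  a1 <- seq(0, 1, by = step)
  grid <- expand.grid(a1 = a1, a2 = a1)
  grid <- grid[grid$a1 + grid$a2 <= 1 + 1e-12, ]
  A <- cbind(grid$a1, grid$a2, 1 - grid$a1 - grid$a2)
  G <- E %*% t(E)
  h <- as.vector(E %*% x)
  q <- rowSums((A %*% G) * A) - 2 * A %*% h + sum(x^2)
  sqrt(max(min(q), 0) / length(x))
}
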