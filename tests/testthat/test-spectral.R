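test_that("vegetation indices match their printed formulas", {
  s <- c(0.05, 0.08, 0.10, 0.30, 0.40, 0.50)
  expect_equal(compute_vi(s, "NDVI"), (0.5 - 0.1) / (0.5 + 0.1))
  expect_equal(compute_vi(s, "NDRE"), (0.5 - 0.3) / (0.5 + 0.3))
  expect_equal(compute_vi(s, "MTCI"), (0.5 - 0.3) / (0.3 + 0.1))
  expect_equal(compute_vi(s, "EVI2"),
               2.5 * (0.5 - 0.1) / (0.5 + 2.4 * 0.1 + 1))
  expect_equal(compute_vi(s, "VARI"), (0.08 - 0.1) / (0.08 + 0.1))
  expect_equal(compute_vi(s, "OSAVI"),
               1.16 * (0.5 - 0.1) / (0.5 + 0.1 + 0.16))

  # frozen spot values
  s2 <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.5)
  expect_equal(compute_vi(s2, "NDVI"), 2 / 3, tolerance = 1e-12)
  s3 <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.4)
  expect_equal(compute_vi(s3, "EVI2"), 2.5 * 0.3 / 1.64, tolerance = 1e-12)
  # R840 == R660 -> 0 by symmetry
  expect_equal(compute_vi(rep(0.3, 6), "NDVI"), 0)
})

test_that("degenerate VI denominators propagate as missing values", {
  z <- c(0, 0, 0, 0, 0, 0)
  expect_true(is.na(compute_vi(z, "NDVI")))
  expect_true(is.na(compute_vi(z, "VARI")))
  expect_false(is.na(compute_vi(z, "EVI2")))  # +1 keeps it defined
  all_vis <- compute_all_vis(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.5))
  expect_named(all_vis, vi_names())
})

test_that("FCLS recovers vertices and exact interior mixtures", {
  lib <- toy_library()
  for (k in 1:3) {
    res <- unmix_fcls(lib$spectra[k, ], lib)
    expect_equal(unname(res$abundances[k]), 1, tolerance = 1e-8)
    expect_lt(res$residual, 1e-10)
  }
  mix <- 0.5 * lib$spectra[1, ] + 0.5 * lib$spectra[2, ]
  res <- unmix_fcls(mix, lib)
  expect_equal(unname(res$abundances), c(0.5, 0.5, 0), tolerance = 1e-9)
  expect_false(res$nonunique)
})

test_that("FCLS output always satisfies the simplex constraints", {
  lib <- toy_library()
  set.seed(42)
  for (i in 1:200) {
    x <- runif(6)  # arbitrary spectra, far from the simplex
    res <- unmix_fcls(x, lib)
    expect_gte(min(res$abundances), -1e-8)
    expect_lte(max(res$abundances), 1 + 1e-8)
    expect_lt(abs(sum(res$abundances) - 1), 1e-8)
    expect_gte(res$residual, 0)
  }
})

test_that("FCLS matches the constrained QP oracle on noisy mixtures", {
  skip_if_not_installed("quadprog")
  lib <- toy_library()
  E <- lib$spectra
  set.seed(7)
  for (i in 1:50) {
    x <- as.vector(random_simplex(3) %*% E) + rnorm(6, 0, 0.01)
    ours <- unmix_fcls(x, lib)
    qp <- quadprog::solve.QP(Dmat = E %*% t(E), dvec = as.vector(E %*% x),
                             Amat = cbind(rep(1, 3), diag(3)),
                             bvec = c(1, 0, 0, 0), meq = 1)
    qp_res <- sqrt(mean((as.vector(t(E) %*% qp$solution) - x)^2))
    expect_lt(ours$residual, qp_res + 1e-8)
    expect_equal(unname(ours$abundances), qp$solution, tolerance = 1e-6)
  }
})

test_that("duplicate endmembers are solved but flagged non-unique", {
  lib <- toy_library()
  dup <- endmember_library("SP", c(lib$names, "veg2"),
                           rbind(lib$spectra, lib$spectra[1, ]),
                           c(lib$is_soil, FALSE))
  res <- unmix_fcls(lib$spectra[1, ], dup)
  expect_true(res$nonunique)
  expect_lt(res$residual, 1e-8)
  expect_lt(abs(sum(res$abundances) - 1), 1e-8)
})

test_that("per-pixel unmixing recovers generated abundances", {
  sc <- generate_scene(small_config(seed = 9, mixing_noise_sd = 0))
  um <- unmix_image(sc$cube, sc$endmembers)
  expect_lt(max(abs(um$abundance - sc$truth$abundance)), 1e-6)
})

test_that("abundance recovery error grows with mixing noise", {
  noise_levels <- c(0, 0.005, 0.02, 0.05)
  mean_err <- vapply(noise_levels, function(ns) {
    errs <- vapply(1:5, function(seed) {
      sc <- generate_scene(small_config(seed = seed,
                                        mixing_noise_sd = ns))
      um <- unmix_image(sc$cube, sc$endmembers)
      mean(abs(um$abundance - sc$truth$abundance))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})

test_that("vegetation abundance excludes only the soil endmembers", {
  lib <- generate_endmembers("SP", 1)
  a <- c(LL = 0.4, SL = 0.2, LS = 0.3, SS = 0.1)
  expect_equal(vegetation_abundance(a, lib), 0.6)
  expect_equal(vegetation_abundance(c(LL = 0, SL = 0, LS = 0.7, SS = 0.3),
                                    lib), 0)
  expect_equal(vegetation_abundance(c(LL = 1, SL = 0, LS = 0, SS = 0),
                                    lib), 1)
  # flower counts as vegetation at FP
  lib_fp <- generate_endmembers("FP", 1)
  a_fp <- c(LL = 0.2, SL = 0.1, LS = 0.3, SS = 0.1, flower = 0.3)
  expect_equal(vegetation_abundance(a_fp, lib_fp), 0.6)
})

test_that("soil-free index is the product with vegetation abundance", {
  expect_equal(compute_vi_v(0.8, 0.5), 0.4)
  expect_equal(compute_vi_v(0.8, 1), 0.8)
  expect_equal(compute_vi_v(0.8, 0), 0)
  expect_true(is.na(compute_vi_v(NA_real_, 0.5)))
  expect_error(compute_vi_v(0.8, 1.4))
})

test_that("soil-corrected VIs correlate better with AGB than plot VIs", {
  # plot-level indices absorb soil-composition signal and saturate in
  # cover while biomass keeps accumulating; the abundance-weighted index
  # removes the soil term and restores proportionality to canopy amount.
  # VARI is excluded: its plot values change sign across the
  # soil-to-canopy transition in these scenes, which breaks the
  # product-weighting premise (see the methods vignette).
  for (stage in c("SP", "FP", "TP")) {
    sc <- generate_scene(scene_config(seed = 21, stage = stage,
                                      mixing_noise_sd = 0))
    lay <- sc$layout
    um <- unmix_image(sc$cube, sc$endmembers)
    veg <- vegetation_abundance_map(um, sc$endmembers)
    agb <- sc$truth$plots$agb
    for (vn in setdiff(vi_names(), "VARI")) {
      vi_plot <- numeric(nrow(lay))
      vi_v <- numeric(nrow(lay))
      for (p in seq_len(nrow(lay))) {
        spec <- plot_mean_spectrum(sc$cube, lay[p, ])
        vi_plot[p] <- compute_vi(spec, vn)
        r <- c(lay$row0[p], lay$row1[p], lay$col0[p], lay$col1[p])
        vab <- mean(veg[(r[1] + 1):r[2], (r[3] + 1):r[4]])
        vi_v[p] <- compute_vi_v(vi_plot[p], vab)
      }
      expect_gte(cor(vi_v, agb), cor(vi_plot, agb))
    }
  }
})
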