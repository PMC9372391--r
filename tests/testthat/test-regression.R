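toy_feature_table <- function(n_per_stage = 16, seed = 1) {
  set.seed(seed)
  stages <- rep(c("SP", "FP", "TP"), each = n_per_stage)
  n <- length(stages)
  data.frame(sample_id = paste0(stages, "_", seq_len(n)), stage = stages,
             f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
             agb = runif(n, 20, 700))
}

test_that("split is disjoint, exhaustive and stage-stratified", {
  tab <- toy_feature_table(16, seed = 2)
  parts <- split_calval(tab, ratio = 2 / 3, seed = 5)
  expect_equal(nrow(parts$calibration), 33)  # round(2/3 * 16) per stage
  expect_equal(nrow(parts$validation), 15)
  expect_length(intersect(parts$calibration$sample_id,
                          parts$validation$sample_id), 0)
  expect_setequal(c(parts$calibration$sample_id,
                    parts$validation$sample_id), tab$sample_id)
  expect_setequal(unique(parts$calibration$stage), c("SP", "FP", "TP"))
  expect_setequal(unique(parts$validation$stage), c("SP", "FP", "TP"))

  again <- split_calval(tab, ratio = 2 / 3, seed = 5)
  expect_identical(parts, again)

  one <- tab[c(1, 17:48), ]
  expect_error(split_calval(one, seed = 1), "fewer than 2")
})

test_that("144 samples at ratio 2/3 split into 96 + 48", {
  tab <- toy_feature_table(48, seed = 3)
  parts <- split_calval(tab, ratio = 2 / 3, seed = 1)
  expect_equal(nrow(parts$calibration), 96)
  expect_equal(nrow(parts$validation), 48)
})

test_that("evaluation metrics match hand-computed values", {
  expect_equal(unname(evaluate_predictions(c(1, 2, 3), c(1, 2, 3))),
               c(1, 0, 0, 0))
  m <- evaluate_predictions(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m[["RMSE"]], sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m[["MAE"]], 2 / 3, tolerance = 1e-12)
  expect_equal(m[["R2"]], 0, tolerance = 1e-12)
  expect_equal(m[["nRMSE_pct"]], 100 * sqrt(2 / 3) / 2, tolerance = 1e-12)
  # predictions worse than the mean give negative R2
  worse <- evaluate_predictions(c(1, 2, 3), c(5, -4, 9))
  expect_lt(worse[["R2"]], 0)
  # constant observed vector: R2 is 0 by convention, nRMSE defined
  expect_equal(evaluate_predictions(c(2, 2), c(1, 3))[["R2"]], 0)
  expect_true(is.na(evaluate_predictions(c(-1, 1), c(0, 0))[["nRMSE_pct"]]))
})

test_that("metric identities hold on random vectors", {
  set.seed(6)
  for (i in 1:50) {
    o <- rnorm(20, 100, 30)
    p <- o + rnorm(20, 0, 10)
    m <- evaluate_predictions(o, p)
    expect_gte(m[["RMSE"]], m[["MAE"]])
    expect_lte(m[["R2"]], 1)
    # independent hand-coded formulas
    expect_equal(m[["RMSE"]], sqrt(sum((o - p)^2) / 20), tolerance = 1e-12)
    expect_equal(m[["MAE"]], sum(abs(o - p)) / 20, tolerance = 1e-12)
    expect_equal(m[["R2"]], 1 - sum((o - p)^2) / sum((o - mean(o))^2),
                 tolerance = 1e-12)
  }
})

test_that("PLSR is exact on noiseless linear targets", {
  set.seed(7)
  n <- 60
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.vector(x %*% c(3, -2, 1, 0.5, 4)) + 7
  tr <- 1:40; va <- 41:60
  fit <- fit_plsr(x[tr, ], y[tr], seed = 1)
  pred <- predict(fit, x[va, ])
  expect_equal(evaluate_predictions(y[va], pred)[["R2"]], 1,
               tolerance = 1e-6)
})

test_that("degenerate fits fall back to the mean model", {
  set.seed(8)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fit_plsr(x, rep(5, 20), seed = 1)
  expect_equal(predict(fit, x[1:4, ]), rep(5, 4))
  fit2 <- fit_plsr(matrix(1, 20, 2, dimnames = list(NULL, c("a", "b"))),
                   rnorm(20), seed = 1)
  expect_true(fit2$degenerate)
  # RFR predicts (nearly) the constant for a constant target
  rf <- suppressWarnings(fit_rfr(x, rep(5, 20), seed = 1))
  expect_equal(unname(predict(rf, x[1:3, ])), rep(5, 3), tolerance = 1e-9)
})

test_that("PLSR survives exactly collinear feature blocks", {
  set.seed(9)
  n <- 40
  base <- matrix(rnorm(n * 3), n)
  x <- cbind(base, base[, 1], base[, 2] * 2)  # duplicated directions
  colnames(x) <- paste0("f", 1:5)
  y <- base %*% c(1, 2, 3) + rnorm(n, 0, 0.1)
  fit <- fit_plsr(x, as.vector(y), seed = 2)
  expect_lte(fit$ncomp, 3)
  expect_gt(evaluate_predictions(as.vector(y), predict(fit, x))[["R2"]],
            0.98)
})

test_that("the seven dimension combinations are enumerated exactly", {
  combos <- enumerate_combinations()
  expect_length(combos, 7)
  expect_true(all(vapply(combos, function(cc) "SV" %in% cc, logical(1))))
  expect_setequal(names(combos),
                  c("SV+TV", "SV+GV", "SV+FDV", "SV+TV+GV", "SV+TV+FDV",
                    "SV+GV+FDV", "SV+TV+GV+FDV"))
  expect_setequal(combos[["SV+TV+GV+FDV"]], c("SV", "TV", "GV", "FDV"))
  expect_equal(sum(lengths(combos) == 2), 3)
  expect_equal(sum(lengths(combos) == 3), 3)
  expect_equal(sum(lengths(combos) == 4), 1)
})

test_that("run_experiment produces the selection-grid report shape", {
  scenes <- lapply(c("SP", "FP", "TP"), function(st) {
    generate_scene(scene_config(seed = 31, stage = st))
  })
  ft <- extract_features(scenes)
  rep2 <- suppressWarnings(
    run_experiment(ft, selections = c("none", "rrelieff", "rf_gini",
                                      "rf_oob"),
                   regressions = c("plsr", "rfr"), seed = 31))
  expect_equal(nrow(rep2), 4 * 2 * 2)  # selections x regressions x parts
  expect_setequal(unique(rep2$partition), c("calibration", "validation"))
  expect_true(all(rep2$RMSE_g_m2 >= rep2$MAE_g_m2))
  expect_true(all(rep2$R2 <= 1))
  # top-10 selection except for "none" (all 39)
  expect_true(all(rep2$n_features[rep2$selection == "none"] == 39))
  expect_true(all(rep2$n_features[rep2$selection != "none"] == 10))

  rep2b <- suppressWarnings(
    run_experiment(ft, selections = c("none", "rrelieff", "rf_gini",
                                      "rf_oob"),
                   regressions = c("plsr", "rfr"), seed = 31))
  expect_identical(rep2, rep2b)  # determinism

  preds <- attr(rep2, "predictions")
  expect_true(all(c("observed", "predicted") %in% names(preds)))
})

test_that("run_experiment covers the seven-combination grid", {
  scenes <- lapply(c("SP", "FP", "TP"), function(st) {
    generate_scene(scene_config(seed = 32, stage = st))
  })
  ft <- extract_features(scenes)
  rep3 <- suppressWarnings(
    run_experiment(ft, selections = "rf_oob", regressions = c("plsr",
                                                              "rfr"),
                   combinations = enumerate_combinations(), seed = 32))
  expect_equal(nrow(rep3), 7 * 2 * 2)
  expect_setequal(unique(rep3$combination), names(enumerate_combinations()))
  # small combinations cannot exceed their own feature count
  expect_true(all(rep3$n_features[rep3$combination == "SV+GV"] <= 8))
})
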