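make_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(target_copy = numeric(n), n1 = rnorm(n), n2 = rnorm(n),
             n3 = rnorm(n), n4 = rnorm(n), n5 = rnorm(n))
}

test_that("RReliefF ranks a target-identical feature above noise", {
  wins <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 30
    y <- runif(n, 0, 100)
    tab <- data.frame(signal = y, matrix(rnorm(n * 5), n,
                                         dimnames = list(NULL,
                                                         paste0("n", 1:5))))
    r <- rrelieff(tab, y, seed = seed)
    r$rank[r$feature == "signal"] == 1
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("RReliefF guards and symmetries", {
  set.seed(3)
  n <- 30
  y <- runif(n)
  tab <- data.frame(constant = rep(1, n), f = rnorm(n))
  tab$dup1 <- tab$f
  names(tab)[names(tab) == "f"] <- "dup2"
  r <- rrelieff(tab, y)
  expect_identical(r$weight[r$feature == "constant"], 0)
  expect_equal(r$weight[r$feature == "dup1"],
               r$weight[r$feature == "dup2"], tolerance = 1e-12)
  expect_error(rrelieff(tab, y, k_neighbors = 30), "k_neighbors")
  # reordering the samples leaves the weights unchanged (m = n uses all)
  perm <- sample(n)
  r2 <- rrelieff(tab[perm, , drop = FALSE], y[perm])
  expect_equal(sort(r2$weight), sort(r$weight), tolerance = 1e-12)
})

test_that("gini index matches the closed form", {
  expect_equal(gini_index(c(1, 0, 0)), 0)
  expect_equal(gini_index(c(0.5, 0.5)), 0.5)
  expect_equal(gini_index(rep(0.25, 4)), 1 - 4 * 0.0625)
  expect_error(gini_index(c(0.7, 0.7)))
})

test_that("RF-Gini recovers a threshold-function feature", {
  wins <- vapply(1:20, function(seed) {
    set.seed(seed + 100)
    n <- 60
    x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
    y <- ifelse(x[, 3] > 0, 100, 10) + rnorm(n, 0, 2)
    r <- rf_gini_importance(x, y, n_trees = 200, seed = seed)
    r$rank[r$feature == "f3"] == 1
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("RF-Gini discretization handles degenerate targets", {
  set.seed(5)
  x <- matrix(rnorm(200), 20, 10)
  expect_error(rf_gini_importance(x, rep(1, 20)), "distinct")
  y2 <- rep(c(0, 1), 10)
  expect_warning(rf_gini_importance(x, y2, n_classes = 4, seed = 2),
                 "classes")
})

test_that("RF-OOB importance recovers the generative feature", {
  set.seed(7)
  n <- 50
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- x[, 2]
  r <- rf_oob_importance(x, y, n_trees = 300, seed = 7)
  expect_equal(r$feature[r$rank == 1], "f2")
  # independent features have importance near zero relative to the
  # generative one
  imp <- stats::setNames(r$weight, r$feature)
  expect_lt(max(abs(imp[-2])), imp["f2"] / 10)
})

test_that("identity permutation forces zero OOB importance", {
  set.seed(8)
  n <- 40
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- x[, 1] + rnorm(n, 0, 0.1)
  r <- rf_oob_importance(x, y, n_trees = 100, seed = 8,
                         permutations = list(a = seq_len(n)))
  expect_identical(r$weight[r$feature == "a"], 0)
  expect_true(all(is.finite(r$weight)))
})

test_that("all three methods place known features in the top ten", {
  hits <- vapply(1:10, function(seed) {
    bench <- simulate_feature_table(n = 120, seed = seed)
    tab <- bench$table
    vapply(c("rrelieff", "rf_gini", "rf_oob"), function(m) {
      r <- switch(m,
                  rrelieff = rrelieff(tab, seed = seed),
                  rf_gini = rf_gini_importance(tab, seed = seed,
                                               n_trees = 300),
                  rf_oob = rf_oob_importance(tab, seed = seed,
                                             n_trees = 300))
      sum(bench$informative %in% select_top(r, 10)) >= 4
    }, logical(1))
  }, logical(3))
  expect_gte(sum(hits["rrelieff", ]), 9)
  expect_gte(sum(hits["rf_gini", ]), 9)
  expect_gte(sum(hits["rf_oob", ]), 9)
})

test_that("selection is deterministic given a seed", {
  bench <- simulate_feature_table(n = 60, seed = 4)
  a <- rf_oob_importance(bench$table, n_trees = 100, seed = 11)
  b <- rf_oob_importance(bench$table, n_trees = 100, seed = 11)
  expect_identical(a, b)
  c1 <- rrelieff(bench$table, seed = 11)
  c2 <- rrelieff(bench$table, seed = 11)
  expect_identical(c1, c2)
})

test_that("select_top honours n, the shortfall rule and tie-breaks", {
  w <- c(a = 3, b = 2, c = 2, d = 1)
  r <- structure(data.frame(feature = names(w), weight = unname(w),
                            rank = rank(-w, ties.method = "first"),
                            method = "x", seed = 1),
                 class = c("importance_ranking", "data.frame"))
  expect_equal(select_top(r, 2), c("a", "b"))  # tie: fixed order
  expect_equal(select_top(r, 10), c("a", "b", "c", "d"))
  bench <- simulate_feature_table(n = 40, seed = 2)
  rk <- rrelieff(bench$table, seed = 1)
  expect_length(select_top(rk, 10), 10)
  expect_equal(nrow(rk), 39)
})

test_that("correlation screen matches the textbook formula", {
  set.seed(10)
  y <- runif(25, 0, 700)
  x <- cbind(double_agb = 2 * y, neg = -y, zv = rep(1, 25),
             noise = rnorm(25))
  out <- correlation_screen(x, y)
  expect_equal(out$r[out$feature == "double_agb"], 1, tolerance = 1e-12)
  expect_equal(out$r[out$feature == "neg"], -1, tolerance = 1e-12)
  expect_identical(out$r[out$feature == "zv"], 0)
  expect_true(out$zero_variance[out$feature == "zv"])
  # brute-force covariance formula
  v <- rnorm(25)
  r_oracle <- sum((v - mean(v)) * (y - mean(y))) /
    sqrt(sum((v - mean(v))^2) * sum((y - mean(y))^2))
  expect_equal(correlation_screen(cbind(v = v), y)$r, r_oracle,
               tolerance = 1e-12)
})
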