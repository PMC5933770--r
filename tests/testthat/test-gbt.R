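tree_splits <- function(tr) tr$nodes[tr$nodes[, "feature"] > 0, , drop = FALSE]

test_that("single split is found by exact SSE search", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  tr <- reg_tree(X, c(0, 0, 1, 1), max_depth = 1)
  sp <- tree_splits(tr)
  expect_equal(nrow(sp), 1L)
  expect_equal(unname(sp[1, "feature"]), 1)
  expect_equal(unname(sp[1, "threshold"]), 1.5)
  expect_equal(predict(tr, X), c(0, 0, 1, 1))
})

test_that("constant response yields a single leaf", {
  X <- matrix(rnorm(10), ncol = 1)
  tr <- reg_tree(X, rep(0.7, 10), max_depth = 8)
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(predict(tr, X), rep(0.7, 10))
})

test_that("deep trees drive the training SSE to zero on distinct samples", {
  set.seed(1)
  # unlimited depth: every impure node admits an SSE-reducing split, so
  # distinct samples are fitted exactly
  X <- matrix(sample(seq(0, 1, length.out = 500), 200), ncol = 1)
  y <- rnorm(200)
  tr <- reg_tree(X, y, max_depth = 200)
  expect_lt(sum((predict(tr, X) - y)^2), 1e-20)
  # a piecewise-constant response with 8 plateaus is recovered exactly at
  # depth 8: even the worst greedy order peels one boundary per level
  Xs <- matrix(seq_len(64), ncol = 1)
  ys <- rep(c(3, 1, 4, 1, 5, 9, 2, 6), each = 8)
  tr8 <- reg_tree(Xs, ys, max_depth = 8)
  expect_equal(predict(tr8, Xs), ys)
})

test_that("min_leaf and depth limits are honoured", {
  set.seed(2)
  X <- matrix(rnorm(60 * 3), 60)
  y <- rnorm(60)
  tr <- reg_tree(X, y, max_depth = 3, min_leaf = 7)
  leaves <- tr$nodes[tr$nodes[, "feature"] == 0, , drop = FALSE]
  expect_true(all(leaves[, "n"] >= 7))
  expect_true(nrow(leaves) <= 2^3)
})

test_that("tree matches the brute-force split-search oracle", {
  set.seed(3)
  for (i in 1:6) {
    n <- sample(10:40, 1)
    p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    depth <- sample(1:4, 1)
    tr <- reg_tree(X, y, max_depth = depth)
    oracle <- brute_tree_fit(X, y, max_depth = depth)
    expect_equal(predict(tr, X), brute_tree_predict(oracle, X),
                 tolerance = 1e-12)
  }
})

test_that("boosting on an all-positive set follows the shrinkage geometric series", {
  X <- matrix(rnorm(20), ncol = 1)
  fit <- gbt(X, rep(1, 20), ntree = 100, shrinkage = 0.005, max_depth = 2)
  expect_equal(predict(fit, X), rep(1 - (1 - 0.005)^100, 20),
               tolerance = 1e-12)
})

test_that("an empty ensemble predicts zero and one tree predicts its shrunken output", {
  X <- matrix(rnorm(10), ncol = 1)
  fit0 <- gbt(X, rep(1, 10), ntree = 0)
  expect_equal(predict(fit0, X), rep(0, 10))
  fit1 <- gbt(matrix(0, 3, 1), c(1, 1, 1), ntree = 1, shrinkage = 0.005)
  # single leaf fits the mean residual 1; shrunken prediction = 0.005 * 1
  expect_equal(predict(fit1, matrix(0, 1, 1)), 0.005)
})

test_that("boosted ensemble matches the brute-force boosting oracle to 1e-9", {
  set.seed(4)
  for (i in 1:5) {
    n <- 50
    X <- matrix(rnorm(n * 3), n)
    y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.3) > 0)
    Xnew <- matrix(rnorm(10 * 3), 10)
    fit <- gbt(X, y, ntree = 20, shrinkage = 0.1, max_depth = 3)
    expect_equal(predict(fit, Xnew),
                 brute_gbt_predict(X, y, Xnew, ntree = 20, shrinkage = 0.1,
                                   max_depth = 3),
                 tolerance = 1e-9)
  }
})

test_that("boosted ensemble agrees with xgboost's exact-greedy squared-error fit", {
  # cross-check against an external gradient-boosting implementation
  # configured identically (squared error, no subsampling, no
  # regularisation); xgboost accumulates gradients in single precision, so
  # agreement is to float32 resolution, not 1e-9
  set.seed(5)
  n <- 80
  X <- matrix(rnorm(n * 4), n)
  y <- as.numeric(X[, 1] - X[, 3] > 0)
  fit <- gbt(X, y, ntree = 15, shrinkage = 0.1, max_depth = 3)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgb <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = 0.1, max_depth = 3,
                  lambda = 0, alpha = 0, gamma = 0, min_child_weight = 1,
                  subsample = 1, colsample_bytree = 1, base_score = 0,
                  tree_method = "exact"),
    data = dtrain, nrounds = 15)
  expect_equal(predict(fit, X), as.numeric(predict(xgb, dtrain)),
               tolerance = 2e-5)
})

test_that("training SSE is non-increasing over boosting rounds", {
  set.seed(6)
  X <- matrix(rnorm(80 * 3), 80)
  y <- rbinom(80, 1, 0.5)
  fit <- gbt(X, y, ntree = 60, shrinkage = 0.05, max_depth = 2)
  expect_true(all(diff(fit$train_sse) <= 1e-10))
})

test_that("fits are invariant to sample order", {
  set.seed(7)
  X <- matrix(rnorm(40 * 3), 40)
  y <- rbinom(40, 1, 0.5)
  perm <- sample(40)
  f1 <- gbt(X, y, ntree = 10, shrinkage = 0.1, max_depth = 3)
  f2 <- gbt(X[perm, ], y[perm], ntree = 10, shrinkage = 0.1, max_depth = 3)
  Xnew <- matrix(rnorm(15 * 3), 15)
  expect_equal(predict(f1, Xnew), predict(f2, Xnew), tolerance = 1e-12)
})

test_that("non-binary targets and dimension mismatches are rejected", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(gbt(X, rep(0.5, 10)), "binary")
  fit <- gbt(X, rep(1, 10), ntree = 2)
  expect_error(predict(fit, matrix(0, 2, 3)), "features")
  expect_error(reg_tree(matrix(numeric(0), 0, 1), numeric(0)), "zero samples")
})

test_that("the balanced pair splits pathogenic variants into complementary halves", {
  set.seed(8)
  X <- matrix(rnorm(30 * 2), 30)
  y <- rep(c(1, 0), c(10, 20))
  fit <- truncpath(X, y, ntree = 5, seed = 3)
  expect_length(fit$half_a, 5L)
  expect_length(fit$half_b, 5L)
  expect_length(intersect(fit$half_a, fit$half_b), 0L)
  expect_setequal(c(fit$half_a, fit$half_b), which(y == 1))

  y11 <- rep(c(1, 0), c(11, 19))
  fit11 <- truncpath(X, y11, ntree = 5, seed = 3)
  expect_equal(lengths(fit11[c("half_a", "half_b")]),
               c(half_a = 6L, half_b = 5L))   # ceiling convention

  # same seed twice: identical halves and identical predictions
  fit2 <- truncpath(X, y, ntree = 5, seed = 3)
  expect_identical(fit$half_a, fit2$half_a)
  Xnew <- matrix(rnorm(20), 10)
  expect_identical(predict(fit, Xnew), predict(fit2, Xnew))

  expect_error(truncpath(X, rep(1, 30), ntree = 5), "both classes")
})

test_that("the pair score is the clipped mean of the two models", {
  set.seed(9)
  X <- matrix(rnorm(40 * 2), 40)
  y <- rbinom(40, 1, 0.5)
  if (sum(y) < 2) y[1:2] <- 1
  fit <- truncpath(X, y, ntree = 10, seed = 1)
  Xnew <- matrix(rnorm(12), 6)
  raw <- (predict(fit$model_a, Xnew) + predict(fit$model_b, Xnew)) / 2
  expect_equal(predict(fit, Xnew, type = "raw"), raw)
  expect_equal(predict(fit, Xnew), pmin(pmax(raw, 0), 1))
  expect_true(all(predict(fit, Xnew) >= 0 & predict(fit, Xnew) <= 1))
  calls <- predict(fit, Xnew, type = "call")
  expect_setequal(unique(calls) %in% c("disease-associated", "neutral"), TRUE)
})

test_that("a separable planted signal is learnt perfectly on the training set", {
  set.seed(10)
  n <- 200
  # margin-separated classes: sig > 1 for pathogenic, < -1 for neutral
  X <- cbind(sig = c(runif(n / 2, 1, 2), runif(n / 2, -2, -1)),
             noise = rnorm(n))
  y <- rep(c(1, 0), each = n / 2)
  fit <- truncpath(X, y, ntree = 200, seed = 1)  # default depth/shrinkage
  m <- classification_metrics(confusion(fitted(fit),
                                        ifelse(y == 1, "pathogenic", "neutral"),
                                        0.5))
  expect_equal(unname(m["mcc"]), 1)
  expect_equal(range(residuals(fit)) <= 1, c(TRUE, TRUE))
})

test_that("models survive a JSON round-trip", {
  set.seed(11)
  X <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("f1", "f2")))
  y <- rbinom(30, 1, 0.5)
  if (sum(y) < 2) y[1:2] <- 1
  fit <- truncpath(X, y, ntree = 8, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  truncpath_save(fit, path)
  back <- truncpath_load(path)
  Xnew <- matrix(rnorm(10 * 2), 10)
  expect_equal(predict(back, Xnew), predict(fit, Xnew), tolerance = 1e-12)
  expect_identical(back$feature_names, c("f1", "f2"))
})
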