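test_that("bootstrap tuning returns the best config with a full score table", {
  b <- smallBenchmark()
  one <- list(rfConfig(n_trees = 100L, max_features = 0.33))
  t1 <- tuneForest(b$X, b$y, grid = one, B = 5L, seed = 2)
  expect_identical(t1$best, one[[1L]])
  expect_identical(dim(t1$table), c(5L, 1L))
  expect_true(all(is.finite(t1$table)))
  # determinism
  t2 <- tuneForest(b$X, b$y, grid = one, B = 5L, seed = 2)
  expect_identical(t1$table, t2$table)
  # richer per-split sampling beats an starved one on a smooth response
  grid <- list(rfConfig(n_trees = 100L, max_features = 0.01),
               rfConfig(n_trees = 100L, max_features = 0.5))
  t3 <- tuneForest(b$X, b$y, grid = grid, B = 8L, seed = 3)
  expect_gt(t3$scores$mean_r2[2], t3$scores$mean_r2[1])
  expect_identical(t3$best$max_features, 0.5)
  expect_error(tuneForest(b$X, b$y, grid = list(), B = 5L), "empty")
  expect_error(rfConfig(max_features = 0), "max_features")
  expect_error(rfConfig(bootstrap_rows = 1.5), "bootstrap_rows")
})

test_that("training is deterministic and interpolates a constant response", {
  b <- smallBenchmark()
  yc <- rep(2.5, nrow(b$X))
  bc <- trainForest(b$X, yc, config = rfConfig(n_trees = 50L, seed = 1L))
  expect_equal(unname(predictWithSpread(bc, b$X)$prediction), yc,
               tolerance = 1e-12)
  m1 <- trainForest(b$X, b$y, config = rfConfig(n_trees = 80L, seed = 4L))
  m2 <- trainForest(b$X, b$y, config = rfConfig(n_trees = 80L, seed = 4L))
  expect_identical(predictWithSpread(m1, b$X)$prediction,
                   predictWithSpread(m2, b$X)$prediction)
  expect_error(trainForest(cbind(b$X[, 1], NA), b$y), "non-finite")
})

test_that("training fit exceeds validation fit (overfit direction)", {
  b <- smallBenchmark()
  idx <- seq_len(150)
  m <- trainForest(b$X[idx, ], b$y[idx],
                   config = rfConfig(n_trees = 150L, seed = 8L))
  rTrain <- regressionMetrics(b$y[idx],
                              predictWithSpread(m, b$X[idx, ])$prediction)$r2
  rVal <- regressionMetrics(b$y[-idx],
                            predictWithSpread(m, b$X[-idx, ])$prediction)$r2
  expect_gt(rTrain, rVal)
})

test_that("per-tree spread behaves like a definition of ensemble variance", {
  b <- smallBenchmark()
  # single tree: zero spread
  m1 <- trainForest(b$X, b$y, config = rfConfig(n_trees = 1L, seed = 1L))
  expect_equal(predictWithSpread(m1, b$X)$tree_sd, rep(0, nrow(b$X)),
               tolerance = 1e-12)
  # prediction equals the mean of per-tree outputs
  m <- trainForest(b$X, b$y, config = rfConfig(n_trees = 60L, seed = 2L))
  pr <- predict(m@rf, b$X, predict.all = TRUE)
  got <- predictWithSpread(m, b$X)
  expect_equal(got$prediction, unname(rowMeans(pr$individual)),
               tolerance = 1e-12)
  # an extrapolated point has larger spread than a deep-interior one
  xFar <- matrix(8, 1, ncol(b$X), dimnames = list(NULL, colnames(b$X)))
  xIn <- matrix(0, 1, ncol(b$X), dimnames = list(NULL, colnames(b$X)))
  sdFar <- predictWithSpread(m, xFar)$tree_sd
  sdIn <- predictWithSpread(m, xIn)$tree_sd
  expect_gt(sdFar, sdIn)
  # schema errors are explicit
  Xbad <- b$X[, rev(colnames(b$X))]
  expect_error(predictWithSpread(m, Xbad), "do not match")
})

test_that("row subsampling is honoured when bootstrap_rows < 1", {
  b <- smallBenchmark()
  m <- trainForest(b$X[1:40, ], b$y[1:40],
                   config = rfConfig(n_trees = 25L, bootstrap_rows = 0.632,
                                     seed = 3L))
  inbag <- m@rf$inbag
  expect_true(any(colSums(inbag > 0) < 40))
  expect_true(all(colSums(inbag) == ceiling(0.632 * 40)))
})

test_that("cross-validated errors partition rows and show CV pessimism", {
  b <- smallBenchmark()
  cfg <- rfConfig(n_trees = 80L)
  cv <- cvAbsErrors(b$X, b$y, config = cfg, k = 10L, seed = 6)
  expect_length(cv$errors, nrow(b$X))
  expect_true(all(table(cv$folds) %in% c(20L)))
  expect_true(all(is.finite(cv$predictions)))
  # constant response: all errors zero
  cv0 <- cvAbsErrors(b$X, rep(1, nrow(b$X)), config = cfg, k = 5L, seed = 1)
  expect_equal(cv0$errors, rep(0, nrow(b$X)), tolerance = 1e-12)
  # mean CV error >= mean resubstitution error
  m <- trainForest(b$X, b$y, config = rfConfig(n_trees = 80L, seed = 2L))
  resub <- mean(abs(b$y - predictWithSpread(m, b$X)$prediction))
  expect_gte(mean(cv$errors), resub)
  expect_error(cvAbsErrors(b$X, b$y, k = 1000L), "k must not exceed")
})
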