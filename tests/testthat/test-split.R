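test_that("PCA scores capture planar data and fix the sign convention", {
  # points exactly on a 2-D plane embedded in 4-D
  base <- withr::with_seed(5, matrix(rnorm(60 * 2), 60, 2))
  X <- cbind(base[, 1] + base[, 2], base[, 1] - base[, 2],
             2 * base[, 1], base[, 2])
  colnames(X) <- paste0("d", 1:4); rownames(X) <- paste0("c", 1:60)
  p <- pcaScores(X)
  expect_equal(sum(p$explainedVariance), 1, tolerance = 1e-9)
  # anisotropic axis-aligned cloud: PC1 aligns with the dominant axis
  Y <- withr::with_seed(6, cbind(a = rnorm(300, sd = 8),
                                 b = rnorm(300, sd = 1),
                                 c = rnorm(300, sd = 0.1)))
  rownames(Y) <- paste0("c", 1:300)
  # autoscaling removes marginal variance, so embed the dominant axis in
  # two correlated columns instead
  Y2 <- cbind(x1 = Y[, "a"] + 0.05 * Y[, "c"], x2 = Y[, "a"] + 0.05 * Y[, "b"],
              x3 = Y[, "b"])
  p2 <- pcaScores(Y2)
  cosine <- abs(cor(p2$scores[, 1], Y[, "a"]))
  expect_gt(cosine, 0.99)
  # determinism incl. sign: identical scores across runs
  expect_identical(pcaScores(X)$scores, p$scores)
  # rank < 2 errors
  Z <- matrix(rep(1:10, 2), 10, 2); Z[, 2] <- Z[, 1] * 2
  colnames(Z) <- c("a", "b"); rownames(Z) <- paste0("c", 1:10)
  expect_error(pcaScores(Z), "rank")
})

test_that("dissimilarity split is an exact partition with round-half-up size", {
  X <- withr::with_seed(9, matrix(rnorm(10 * 3), 10, 3,
                                  dimnames = list(paste0("c", 1:10),
                                                  paste0("d", 1:3))))
  y <- withr::with_seed(10, rnorm(10))
  sc <- pcaScores(X)$scores
  sp <- dissimilaritySplit(sc, y, frac = 0.8, seed = 4)
  expect_length(sp$train_idx, 8L)
  expect_length(sp$valid_idx, 2L)
  expect_setequal(c(sp$train_idx, sp$valid_idx), 1:10)
  expect_length(intersect(sp$train_idx, sp$valid_idx), 0L)
  # |train| = round(0.8 n) with round-half-up: n = 15 -> 12
  X15 <- withr::with_seed(11, matrix(rnorm(15 * 3), 15, 3,
                                     dimnames = list(paste0("c", 1:15),
                                                     paste0("d", 1:3))))
  y15 <- withr::with_seed(12, rnorm(15))
  sp15 <- dissimilaritySplit(pcaScores(X15)$scores, y15, seed = 1)
  expect_length(sp15$train_idx, 12L)
  expect_error(dissimilaritySplit(sc[1:5, ], y[1:5], seed = 1), "at least 7")
  expect_error(dissimilaritySplit(sc, y, frac = 1.2, seed = 1), "frac")
})

test_that("split is seed-deterministic and captures extreme points", {
  n <- 40
  sc <- withr::with_seed(21, matrix(rnorm(n * 2), n, 2))
  y <- withr::with_seed(22, rnorm(n))
  s1 <- dissimilaritySplit(sc, y, seed = 3)
  s2 <- dissimilaritySplit(sc, y, seed = 3)
  expect_identical(s1$train_idx, s2$train_idx)
  s3 <- dissimilaritySplit(sc, y, seed = 4)
  expect_false(identical(s1$train_idx, s3$train_idx))
  # a gross outlier in (PC, y) space joins the training pool first
  sc2 <- rbind(sc, c(50, 50))
  y2 <- c(y, 0)
  for (seed in 1:5) {
    sp <- dissimilaritySplit(sc2, y2, seed = seed)
    expect_true(41 %in% sp$train_idx)
  }
  # and with a minimal training budget the outlier is the first iterative
  # pick: train = 5 seeds + outlier
  sp6 <- dissimilaritySplit(sc2, y2, frac = 6 / 41, seed = 1)
  seeds5 <- withr::with_seed(1, sample.int(41, 5))
  expect_setequal(sp6$train_idx, c(seeds5, 41L))
})

test_that("maxmin training sets are space-filling", {
  hits <- 0L
  for (seed in 1:10) {
    sc <- withr::with_seed(100 + seed, matrix(runif(30 * 2), 30, 2))
    y <- withr::with_seed(200 + seed, runif(30))
    sp <- dissimilaritySplit(sc, y, seed = seed)
    space <- cbind(sc, as.numeric(scale(y)))
    D <- as.matrix(dist(space))
    trn <- sp$train_idx; val <- sp$valid_idx
    dtrn <- D[trn, trn]; diag(dtrn) <- Inf
    minWithin <- min(dtrn)
    minValToTrain <- min(D[val, trn])
    if (minWithin >= minValToTrain) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
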