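test_that("mean kNN distance matches hand enumeration and brute force", {
  train <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(knnMeanDistance(0.4, train, k = 1), 0.4)
  expect_equal(knnMeanDistance(0.4, train, k = 2), 0.5)
  # external query equal to a training row: distance 0
  expect_equal(knnMeanDistance(1, train, k = 1), 0)
  # training row with self-exclusion
  expect_equal(knnMeanDistance(matrix(0, 1, 1), train, k = 1,
                               selfIndex = 1L), 1)
  expect_error(knnMeanDistance(0.4, train, k = 3), "smaller")
  # brute-force agreement on random instances
  for (seed in 1:3) {
    X <- withr::with_seed(seed, matrix(rnorm(40 * 4), 40, 4))
    q <- withr::with_seed(seed + 50, matrix(rnorm(5 * 4), 5, 4))
    for (metric in c("euclidean", "manhattan")) {
      got <- knnMeanDistance(q, X, k = 3, metric = metric)
      want <- apply(q, 1, function(row) {
        d <- apply(X, 1, function(t)
          if (metric == "euclidean") sqrt(sum((row - t)^2))
          else sum(abs(row - t)))
        mean(sort(d)[1:3])
      })
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("percentile thresholds interpolate linearly with max at 1.0", {
  expect_equal(errorThreshold(c(1, 2, 3, 4), 1.0), 4)
  expect_equal(errorThreshold(c(1, 2, 3, 4), 0.5), 2.5)
  expect_equal(errorThreshold(c(0, 1), 0.75), 0.75)
  expect_equal(errorThreshold(rep(2, 6), 0.9), 2)
  expect_equal(errorThreshold(5, 0.65), 5)
  # sort-and-interpolate oracle
  x <- withr::with_seed(8, runif(31))
  for (p in c(0.65, 0.75, 0.9, 0.975, 1)) {
    xs <- sort(x)
    h <- (length(x) - 1) * p
    want <- xs[floor(h) + 1] + (h - floor(h)) *
      (xs[min(floor(h) + 2, length(x))] - xs[floor(h) + 1])
    expect_equal(errorThreshold(x, p), want, tolerance = 1e-12)
  }
})

test_that("AD metrics obey their defining identities", {
  bundle <- smallBundle()
  X <- bundle@trainX
  M <- adMetrics(X[1:10, ], bundle, trainIndex = 1:10)
  expect_identical(names(M), c("wrms1", "wrms2", "sim_nearest1",
                               "sim_nearest5", "tree_sd", "predicted"))
  expect_true(all(vapply(M, function(cl) all(is.finite(cl)), logical(1))))
  # nearest single distance never exceeds the mean of five
  expect_true(all(M$sim_nearest1 <= M$sim_nearest5 + 1e-12))
  # independent recomputation of wrms1/wrms2 from first principles
  sc <- bundle@scaling
  Xs <- sweep(sweep(X, 2, sc$center, "-"), 2, sc$sdev, "/")
  predT <- predictWithSpread(bundle, X)$prediction
  for (i in 1:5) {
    d <- sqrt(colSums((t(Xs) - Xs[i, ])^2))
    d[i] <- Inf
    ord <- order(d)[1:5]
    w <- 1 / (d[ord] + 1e-6); w <- w / sum(w)
    wrms1 <- sqrt(sum(w * (predT[i] - bundle@trainY[ord])^2))
    wrms2 <- sqrt(sum(w * (predT[ord] - bundle@trainY[ord])^2))
    expect_equal(M$wrms1[i], wrms1, tolerance = 1e-10)
    expect_equal(M$wrms2[i], wrms2, tolerance = 1e-10)
    expect_equal(M$sim_nearest1[i], min(d), tolerance = 1e-10)
    expect_equal(M$sim_nearest5[i], mean(d[ord]), tolerance = 1e-10)
  }
  # equidistant neighbours with unit residuals: wrms = 1 by hand
  w <- rep(0.2, 5)
  expect_equal(sqrt(sum(w * rep(1, 5)^2)), 1)
})

test_that("the error model reproduces degenerate targets and is seeded", {
  b <- smallBenchmark()
  yc <- rep(1.0, nrow(b$X))
  bundle0 <- trainForest(b$X, yc, config = rfConfig(n_trees = 40L,
                                                    seed = 2L))
  bundle0 <- trainErrorModel(bundle0, seed = 2L, cvFolds = 5L)
  pe <- aquatox:::predictError(bundle0, b$X)
  expect_equal(pe, rep(0, nrow(b$X)), tolerance = 1e-12)
  b1 <- trainErrorModel(smallBundle(), seed = 31L, cvFolds = 5L)
  b2 <- trainErrorModel(smallBundle(), seed = 31L, cvFolds = 5L)
  expect_identical(aquatox:::predictError(b1, b$X[1:20, ]),
                   aquatox:::predictError(b2, b$X[1:20, ]))
  expect_error(trainErrorModel(smallBundle(), cvErrors = 1:3),
               "length")
})

test_that("AD membership is the conjunction of distance and error checks", {
  bundle <- smallBundle()
  # mild thresholds: any training compound is inside
  d <- distanceThreshold(bundle, k = 1L, pct = 1.0)
  pe <- aquatox:::predictError(bundle, bundle@trainX,
                               trainIndex = seq_len(nrow(bundle@trainX)))
  bundle@ad <- new("ADConfig", metric = "euclidean", k = 1L,
                   tdPercentile = 1.0, tdValue = d$threshold,
                   tePercentile = 1.0, teValue = max(pe))
  dec <- assessAD(bundle@trainX[3, ], bundle, isTraining = TRUE,
                  trainIndex = 3L)
  expect_true(dec$inside)
  expect_identical(dec$inside, dec$distance_check && dec$error_check)
  # far outside the training hull: outside regardless of the error model
  far <- rep(50, ncol(bundle@trainX))
  decFar <- assessAD(far, bundle)
  expect_false(decFar$distance_check)
  expect_false(decFar$inside)
  # error check failing alone also excludes
  bundleTight <- bundle
  bundleTight@ad <- new("ADConfig", metric = "euclidean", k = 1L,
                        tdPercentile = 1.0, tdValue = d$threshold,
                        tePercentile = 0.9, teValue = -1)
  decT <- assessAD(bundle@trainX[3, ], bundleTight, isTraining = TRUE,
                   trainIndex = 3L)
  expect_true(decT$distance_check)
  expect_false(decT$error_check)
  expect_false(decT$inside)
})

test_that("grid selection covers 32 combinations with monotone coverage", {
  bundle <- smallBundle()
  grid <- defaultAdGrid()
  expect_identical(nrow(grid), 32L)
  sel <- selectAdConfig(bundle, grid = grid, cvFolds = 5L, seed = 4L)
  tab <- sel$table
  expect_identical(nrow(tab), 32L)
  # coverage 1 at the (1.0, 1.0) corner on the training set
  corner <- tab[tab$td_pct == 1 & tab$te_pct == 1, ]
  expect_true(all(corner$coverage == 1))
  # monotone non-increasing coverage along each threshold axis
  for (kk in unique(tab$k)) {
    for (te in unique(tab$te_pct)) {
      sub <- tab[tab$k == kk & tab$te_pct == te, ]
      sub <- sub[order(-sub$td_pct), ]
      expect_true(all(diff(sub$coverage) <= 1e-12))
    }
    for (td in unique(tab$td_pct)) {
      sub <- tab[tab$k == kk & tab$td_pct == td, ]
      sub <- sub[order(-sub$te_pct), ]
      expect_true(all(diff(sub$coverage) <= 1e-12))
    }
  }
  # the chosen configuration respects the coverage floor when feasible
  ad <- adConfig(sel$bundle)
  chosen <- tab[tab$k == ad@k & tab$td_pct == ad@tdPercentile &
                  tab$te_pct == ad@tePercentile, ]
  expect_gte(chosen$coverage, 0.75)
  expect_error(selectAdConfig(bundle, grid = defaultAdGrid()[0, ]), "empty")
})

test_that("leverage follows the hat-matrix identities", {
  X <- withr::with_seed(3, matrix(rnorm(60 * 4), 60, 4))
  lev <- leverageFlags(X)
  p1 <- ncol(X) + 1
  expect_equal(mean(lev$leverage), p1 / nrow(X), tolerance = 1e-9)
  # gross coordinate outlier is flagged; duplicate interior point is not
  X2 <- rbind(X, c(30, 30, 30, 30), X[5, ])
  lev2 <- leverageFlags(X2)
  expect_true(lev2$high_leverage[61])
  expect_false(lev2$high_leverage[62])
})
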