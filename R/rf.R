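# Random-forest activity model: bootstrap hyperparameter tuning, training,
# per-tree prediction spread, and k-fold cross-validated absolute errors.

#' Random-forest configuration
#'
#' @param n_trees number of trees.
#' @param max_features fraction of descriptors tried at each split
#'   (mapped to mtry), in (0, 1].
#' @param min_samples_leaf minimum terminal-node size.
#' @param bootstrap_rows fraction of training rows drawn (with
#'   replacement) per tree, in (0, 1].
#' @param seed RNG seed for fitting.
#' @return validated config list of class "rfConfig".
#' @export
rfConfig <- function(n_trees = 500L, max_features = 0.33,
                     min_samples_leaf = 5L, bootstrap_rows = 1.0,
                     seed = 1L) {
  cfg <- list(n_trees = as.integer(n_trees), max_features = max_features,
              min_samples_leaf = as.integer(min_samples_leaf),
              bootstrap_rows = bootstrap_rows, seed = as.integer(seed))
  if (cfg$n_trees < 1L) stop("n_trees must be positive", call. = FALSE)
  if (!is.finite(cfg$max_features) || cfg$max_features <= 0 ||
      cfg$max_features > 1)
    stop("max_features must be in (0, 1]", call. = FALSE)
  if (cfg$min_samples_leaf < 1L)
    stop("min_samples_leaf must be positive", call. = FALSE)
  if (!is.finite(cfg$bootstrap_rows) || cfg$bootstrap_rows <= 0 ||
      cfg$bootstrap_rows > 1)
    stop("bootstrap_rows must be in (0, 1]", call. = FALSE)
  class(cfg) <- "rfConfig"
  cfg
}

#' Default hyperparameter tuning grid
#'
#' Spans the per-tree feature fraction and row-sampling axes: n_trees in
#' {250, 500}, max_features in {0.2, 0.33, 0.6}, min_samples_leaf in
#' {1, 3, 5}, bootstrap_rows in {0.632, 1.0}.
#'
#' @return list of rfConfig objects (36 combinations).
#' @export
defaultTuningGrid <- function() {
  g <- expand.grid(n_trees = c(250L, 500L), max_features = c(0.2, 0.33, 0.6),
                   min_samples_leaf = c(1L, 3L, 5L),
                   bootstrap_rows = c(0.632, 1.0))
  lapply(seq_len(nrow(g)), function(i)
    rfConfig(g$n_trees[i], g$max_features[i], g$min_samples_leaf[i],
             g$bootstrap_rows[i]))
}

.fitRF <- function(X, y, config, seed = config$seed) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y", call. = FALSE)
  mtry <- max(1L, as.integer(round(config$max_features * ncol(X))))
  sampsize <- max(1L, as.integer(ceiling(config$bootstrap_rows * nrow(X))))
  withSeed(seed,
    suppressWarnings(   # degenerate (near-constant) responses are legal here
      randomForest::randomForest(x = X, y = y, ntree = config$n_trees,
                                 mtry = mtry,
                                 nodesize = config$min_samples_leaf,
                                 sampsize = sampsize, replace = TRUE,
                                 keep.inbag = TRUE)))
}

#' Tune random-forest hyperparameters by bootstrap cross-validation
#'
#' For every configuration in the grid, draws `B` bootstrap resamples of
#' the training rows (the same resamples for every configuration), fits
#' the forest on each resample and scores R-squared on the out-of-bag
#' rows. Returns the configuration with the highest mean R-squared,
#' together with the full score table.
#'
#' @param X training descriptor matrix.
#' @param y training responses.
#' @param grid non-empty list of rfConfig objects.
#' @param B number of bootstrap iterations (default 100).
#' @param seed RNG seed controlling the resamples.
#' @return list with `best` (rfConfig), `scores` (data.frame with one row
#'   per config: mean_r2 and the config fields), `table` (B x n_config
#'   matrix of per-iteration R-squared).
#' @export
tuneForest <- function(X, y, grid = defaultTuningGrid(), B = 100L,
                       seed = 1L) {
  if (!length(grid)) stop("empty tuning grid", call. = FALSE)
  for (g in grid) if (!inherits(g, "rfConfig"))
    stop("grid entries must be rfConfig objects", call. = FALSE)
  X <- as.matrix(X); n <- nrow(X)
  stopifnot(length(y) == n)
  resamples <- withSeed(seed, lapply(seq_len(B), function(b)
    sample.int(n, n, replace = TRUE)))
  fitSeeds <- withSeed(seed + 1L, sample.int(.Machine$integer.max - 1L, B))
  tab <- matrix(NA_real_, nrow = B, ncol = length(grid))
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    for (b in seq_len(B)) {
      idx <- resamples[[b]]
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) < 2L || stats::var(y[oob]) == 0) next
      rf <- .fitRF(X[idx, , drop = FALSE], y[idx], cfg, seed = fitSeeds[b])
      pred <- stats::predict(rf, X[oob, , drop = FALSE])
      tab[b, ci] <- regressionMetrics(y[oob], pred)$r2
    }
  }
  meanR2 <- colMeans(tab, na.rm = TRUE)
  best <- grid[[which.max(meanR2)]]
  scores <- do.call(rbind, lapply(seq_along(grid), function(ci)
    data.frame(n_trees = grid[[ci]]$n_trees,
               max_features = grid[[ci]]$max_features,
               min_samples_leaf = grid[[ci]]$min_samples_leaf,
               bootstrap_rows = grid[[ci]]$bootstrap_rows,
               mean_r2 = meanR2[ci])))
  list(best = best, scores = scores, table = tab)
}

#' Train the activity model
#'
#' Fits the random forest and assembles a \linkS4class{ToxModelBundle}
#' carrying everything later stages need: the selected descriptor names,
#' training data and autoscaling statistics (for neighbour distances), and
#' the response transform. The applicability domain and error model are
#' attached afterwards by [trainErrorModel()] and [selectAdConfig()].
#'
#' @param X training descriptor matrix (finalized; columns are the
#'   selected descriptors).
#' @param y training responses on the transformed scale.
#' @param config rfConfig.
#' @param transform \linkS4class{BoxCoxTransform} used on the response
#'   (identity placeholder by default).
#' @return a \linkS4class{ToxModelBundle}.
#' @export
trainForest <- function(X, y, config = rfConfig(),
                        transform = new("BoxCoxTransform", lambda = 1,
                                        meanT = 0, sdT = 1)) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("d%04d", seq_len(ncol(X)))
  rf <- .fitRF(X, y, config)
  sc <- colStats(X)
  new("ToxModelBundle", rf = rf, config = unclass(config),
      selectedDescriptors = colnames(X),
      transform = transform, trainX = X, trainY = as.numeric(y),
      scaling = sc, cvErrors = numeric(0), errorModel = NULL,
      ad = new("ADConfig"))
}

#' Predict with per-tree spread
#'
#' The ensemble prediction is the mean over trees; TREE_SD is the standard
#' deviation of the per-tree predictions (population denominator).
#'
#' @param bundle a \linkS4class{ToxModelBundle}.
#' @param X matrix whose columns are exactly the bundle's selected
#'   descriptors, in order.
#' @return data.frame with `prediction` and `tree_sd` (transformed units).
#' @export
predictWithSpread <- function(bundle, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), bundle@selectedDescriptors))
    stop("descriptor columns do not match the model: expected [",
         paste(bundle@selectedDescriptors, collapse = ", "), "]",
         call. = FALSE)
  pr <- stats::predict(bundle@rf, X, predict.all = TRUE)
  ind <- pr$individual
  mu <- rowMeans(ind)
  sdPop <- sqrt(rowMeans((ind - mu)^2))
  data.frame(prediction = as.numeric(pr$aggregate), tree_sd = sdPop,
             row.names = rownames(X))
}

#' Cross-validated absolute errors of the activity model
#'
#' Seeded, shuffled k-fold partition; each row's error is the absolute
#' difference between its observed response and the prediction of a model
#' trained without its fold. These errors are the dependent variable of
#' the error model.
#'
#' @param X training descriptor matrix.
#' @param y training responses.
#' @param config rfConfig for the fold models.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return list with `errors` (per-row absolute CV error), `predictions`
#'   and `folds`.
#' @export
cvAbsErrors <- function(X, y, config = rfConfig(), k = 10L, seed = 1L) {
  X <- as.matrix(X); n <- nrow(X)
  stopifnot(length(y) == n)
  if (k > n) stop("k must not exceed the number of rows", call. = FALSE)
  folds <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  pred <- rep(NA_real_, n)
  fitSeeds <- withSeed(seed + 1L, sample.int(.Machine$integer.max - 1L, k))
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    rf <- .fitRF(X[train, , drop = FALSE], y[train], config,
                 seed = fitSeeds[f])
    pred[test] <- stats::predict(rf, X[test, , drop = FALSE])
  }
  list(errors = abs(y - pred), predictions = pred, folds = folds)
}
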