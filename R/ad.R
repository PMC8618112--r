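# Dual applicability domain: kNN distance thresholds (structural domain)
# and a six-metric random-forest error model (reliability domain), with
# the 32-combination grid search and compromise selection.

#' Mean distance to the k nearest training compounds
#'
#' Operates on coordinates as given; callers autoscale descriptor space by
#' the training statistics first. For training compounds the compound
#' itself is excluded from its neighbour search (`selfIndex`); external
#' compounds use all training rows.
#'
#' @param x query matrix (rows = compounds) or single vector.
#' @param train training coordinate matrix.
#' @param k neighbour count; must be < nrow(train).
#' @param metric "euclidean" or "manhattan".
#' @param selfIndex optional integer vector, one per query row: index of
#'   the query inside `train` to exclude (NA for external compounds).
#' @return numeric vector of mean k-nearest-neighbour distances.
#' @export
knnMeanDistance <- function(x, train, k = 5L,
                            metric = c("euclidean", "manhattan"),
                            selfIndex = NULL) {
  metric <- match.arg(metric)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  train <- as.matrix(train)
  if (k >= nrow(train))
    stop("k must be smaller than the number of training compounds",
         call. = FALSE)
  D <- rowDistances(as.matrix(x), train, metric = metric)
  if (!is.null(selfIndex)) {
    stopifnot(length(selfIndex) == nrow(D))
    for (i in seq_len(nrow(D)))
      if (!is.na(selfIndex[i])) D[i, selfIndex[i]] <- Inf
  }
  apply(D, 1L, function(d) mean(sort(d)[seq_len(k)]))
}

# training-set mean-kNN distance distribution (self-excluded), in the
# bundle's autoscaled selected-descriptor space
.trainKnnDistances <- function(bundle, k, metric) {
  Xs <- scaleBy(bundle@trainX, bundle@scaling$center, bundle@scaling$sdev)
  knnMeanDistance(Xs, Xs, k = k, metric = metric,
                  selfIndex = seq_len(nrow(Xs)))
}

#' Distance threshold T_D
#'
#' Linear-interpolated percentile of the training-set mean-kNN distance
#' distribution (self-excluded); percentile 1.0 gives the maximum.
#'
#' @param bundle a \linkS4class{ToxModelBundle}.
#' @param k neighbour count (1 or 5).
#' @param metric distance metric.
#' @param pct percentile in (0, 1].
#' @return list with `threshold` and the training `distances`.
#' @export
distanceThreshold <- function(bundle, k = 5L,
                              metric = c("euclidean", "manhattan"),
                              pct = 0.95) {
  metric <- match.arg(metric)
  d <- .trainKnnDistances(bundle, k, metric)
  list(threshold = percentile(d, pct), distances = d)
}

#' Error threshold T_E
#'
#' Linear-interpolated percentile of the error-model-predicted absolute
#' errors of the training compounds; percentile 1.0 gives the maximum.
#'
#' @param predictedErrors predicted training errors.
#' @param pct percentile in (0, 1].
#' @return threshold value.
#' @export
errorThreshold <- function(predictedErrors, pct = 0.95) {
  percentile(predictedErrors, pct)
}

#' Six applicability-domain metrics
#'
#' For each query compound, finds its five nearest training neighbours by
#' Euclidean distance in the autoscaled selected-descriptor space and
#' computes: wRMS1, the weighted RMS difference between the target's
#' predicted activity and the observed activities of the neighbours;
#' wRMS2, the weighted RMS difference between the model's predictions for
#' those neighbours and their observed activities; SIMILARITYNEAREST1 and
#' SIMILARITYNEAREST5, the distance to the nearest neighbour and the mean
#' distance to the five; TREE_SD, the per-tree prediction spread; and
#' PREDICTED, the prediction itself. Weights are w_i = (1/(d_i + 1e-6)) /
#' sum_j (1/(d_j + 1e-6)), so nearer neighbours dominate.
#'
#' @param X query matrix (selected descriptors, in order).
#' @param bundle a \linkS4class{ToxModelBundle} (needs >= 5 training
#'   compounds).
#' @param trainIndex optional integer vector (one per query row): the
#'   row's index in the training set, excluded from its own neighbour
#'   search; NA for external compounds. `TRUE` is shorthand for
#'   `seq_len(nrow(X))` when `X` is the training matrix itself.
#' @return data.frame with columns wrms1, wrms2, sim_nearest1,
#'   sim_nearest5, tree_sd, predicted.
#' @export
adMetrics <- function(X, bundle, trainIndex = NULL) {
  X <- as.matrix(X)
  if (isTRUE(trainIndex)) trainIndex <- seq_len(nrow(X))
  nTrain <- nrow(bundle@trainX)
  if (nTrain < 5L + !is.null(trainIndex))
    stop("AD metrics need at least 5 training neighbours", call. = FALSE)
  Xs <- scaleBy(X, bundle@scaling$center, bundle@scaling$sdev)
  Ts <- scaleBy(bundle@trainX, bundle@scaling$center, bundle@scaling$sdev)
  D <- rowDistances(Xs, Ts, metric = "euclidean")
  if (!is.null(trainIndex)) {
    stopifnot(length(trainIndex) == nrow(D))
    for (i in seq_len(nrow(D)))
      if (!is.na(trainIndex[i])) D[i, trainIndex[i]] <- Inf
  }
  predQ <- predictWithSpread(bundle, X)
  predT <- predictWithSpread(bundle, bundle@trainX)$prediction
  out <- matrix(NA_real_, nrow(X), 6L,
                dimnames = list(rownames(X),
                                c("wrms1", "wrms2", "sim_nearest1",
                                  "sim_nearest5", "tree_sd", "predicted")))
  for (i in seq_len(nrow(X))) {
    ord <- order(D[i, ])[1:5]
    d <- D[i, ord]
    w <- 1 / (d + 1e-6); w <- w / sum(w)
    yNbr <- bundle@trainY[ord]
    pNbr <- predT[ord]
    out[i, ] <- c(sqrt(sum(w * (predQ$prediction[i] - yNbr)^2)),
                  sqrt(sum(w * (pNbr - yNbr)^2)),
                  d[1L], mean(d),
                  predQ$tree_sd[i], predQ$prediction[i])
  }
  as.data.frame(out)
}

#' Train the error model
#'
#' Fits a random forest regressing the activity model's cross-validated
#' absolute errors on the six AD metrics of the training compounds.
#' Predicted errors are clamped at zero. Returns the bundle with
#' `errorModel` and `cvErrors` attached.
#'
#' @param bundle a \linkS4class{ToxModelBundle}.
#' @param cvErrors per-row CV absolute errors from [cvAbsErrors()] (run
#'   internally when omitted).
#' @param config rfConfig for the error forest (defaults to the activity
#'   model's config).
#' @param seed RNG seed.
#' @param cvFolds folds for the internal [cvAbsErrors()] call.
#' @return updated \linkS4class{ToxModelBundle}.
#' @export
trainErrorModel <- function(bundle, cvErrors = NULL, config = NULL,
                            seed = 1L, cvFolds = 10L) {
  if (is.null(cvErrors))
    cvErrors <- cvAbsErrors(bundle@trainX, bundle@trainY,
                            config = do.call(rfConfig, bundle@config),
                            k = cvFolds, seed = seed)$errors
  if (length(cvErrors) != nrow(bundle@trainX))
    stop("cvErrors length does not match the training set", call. = FALSE)
  M <- adMetrics(bundle@trainX, bundle, trainIndex = TRUE)
  cfg <- if (is.null(config)) do.call(rfConfig, bundle@config) else config
  em <- .fitRF(as.matrix(M), cvErrors, cfg, seed = seed + 7L)
  bundle@errorModel <- em
  bundle@cvErrors <- as.numeric(cvErrors)
  bundle
}

# predicted absolute errors (clamped at 0) for rows of X
predictError <- function(bundle, X, trainIndex = NULL) {
  if (is.null(bundle@errorModel))
    stop("bundle has no error model; run trainErrorModel() first",
         call. = FALSE)
  M <- adMetrics(X, bundle, trainIndex = trainIndex)
  pmax(as.numeric(stats::predict(bundle@errorModel, as.matrix(M))), 0)
}

#' Default applicability-domain grid
#'
#' k in {1, 5} x T_D percentile in {1.0, 0.975, 0.95, 0.90} x T_E
#' percentile in {1.0, 0.90, 0.75, 0.65}, Euclidean metric: 32
#' combinations.
#'
#' @param metric distance metric (fixed Euclidean by default; Manhattan
#'   available).
#' @return data.frame with columns k, td_pct, te_pct, metric.
#' @export
defaultAdGrid <- function(metric = "euclidean") {
  g <- expand.grid(k = c(1L, 5L), td_pct = c(1.0, 0.975, 0.95, 0.90),
                   te_pct = c(1.0, 0.90, 0.75, 0.65),
                   KEEP.OUT.ATTRS = FALSE)
  g$metric <- metric
  g
}

#' Assess whether a compound is inside the applicability domain
#'
#' The distance check passes when the compound's mean k-nearest-neighbour
#' distance to the training set is at most T_D; the error check passes
#' when its error-model predicted absolute error is at most T_E. The
#' compound is inside the domain iff both pass.
#'
#' @param x descriptor vector or single-row matrix (selected descriptors).
#' @param bundle a \linkS4class{ToxModelBundle} with finalized ADConfig
#'   and error model.
#' @param isTraining TRUE when `x` is a training compound.
#' @param trainIndex the compound's row in the training set (self
#'   exclusion), when `isTraining`.
#' @return list: inside, distance_check, error_check, mean_knn_distance,
#'   predicted_error.
#' @export
assessAD <- function(x, bundle, isTraining = FALSE,
                     trainIndex = NA_integer_) {
  ad <- bundle@ad
  x <- matrix(as.numeric(x), nrow = 1L,
              dimnames = list(NULL, bundle@selectedDescriptors))
  xs <- scaleBy(x, bundle@scaling$center, bundle@scaling$sdev)
  Ts <- scaleBy(bundle@trainX, bundle@scaling$center, bundle@scaling$sdev)
  d <- knnMeanDistance(xs, Ts, k = ad@k, metric = ad@metric,
                       selfIndex = if (isTraining) trainIndex else NA)
  pe <- predictError(bundle, x,
                     trainIndex = if (isTraining) trainIndex else NULL)
  distanceCheck <- d <= ad@tdValue
  errorCheck <- pe <= ad@teValue
  list(inside = distanceCheck && errorCheck,
       distance_check = distanceCheck, error_check = errorCheck,
       mean_knn_distance = as.numeric(d), predicted_error = as.numeric(pe))
}

#' Select the applicability-domain configuration over the grid
#'
#' Evaluates every (k, T_D percentile, T_E percentile) combination on the
#' training set: thresholds from the training distributions, in-domain
#' membership of every training compound, coverage, and R2/MAE/RMSE of the
#' k-fold cross-validated predictions restricted to in-domain compounds.
#' The selected combination maximizes in-domain CV R2 among those with
#' coverage at least `coverageFloor`; ties go to higher coverage, then to
#' milder (higher) percentiles. If no combination reaches the floor, the
#' one with the highest coverage wins. Returns the bundle with the chosen
#' \linkS4class{ADConfig} attached, plus the full grid table.
#'
#' @param bundle a \linkS4class{ToxModelBundle} with an error model.
#' @param grid data.frame as from [defaultAdGrid()].
#' @param cvFolds folds for the CV predictions (default 10).
#' @param seed RNG seed for the CV partition.
#' @param coverageFloor minimum acceptable coverage (default 0.75).
#' @return list with `bundle` (AD attached) and `table` (one row per
#'   combination: k, td_pct, te_pct, td_value, te_value, coverage, r2,
#'   mae, rmse).
#' @export
selectAdConfig <- function(bundle, grid = defaultAdGrid(), cvFolds = 10L,
                           seed = 1L, coverageFloor = 0.75) {
  if (!nrow(grid)) stop("empty AD grid", call. = FALSE)
  if (is.null(bundle@errorModel))
    stop("bundle has no error model; run trainErrorModel() first",
         call. = FALSE)
  cv <- cvAbsErrors(bundle@trainX, bundle@trainY,
                    config = do.call(rfConfig, bundle@config),
                    k = cvFolds, seed = seed)
  pe <- predictError(bundle, bundle@trainX,
                     trainIndex = seq_len(nrow(bundle@trainX)))
  distCache <- list()
  n <- nrow(bundle@trainX)
  rows <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    k <- grid$k[gi]; metric <- grid$metric[gi]
    key <- paste(k, metric)
    if (is.null(distCache[[key]]))
      distCache[[key]] <- .trainKnnDistances(bundle, k, metric)
    d <- distCache[[key]]
    td <- percentile(d, grid$td_pct[gi])
    te <- percentile(pe, grid$te_pct[gi])
    inside <- d <= td & pe <= te
    cov <- mean(inside)
    if (sum(inside) >= 3L && stats::var(bundle@trainY[inside]) > 0) {
      mt <- regressionMetrics(bundle@trainY[inside],
                              cv$predictions[inside])
    } else mt <- list(r2 = NA_real_, mae = NA_real_, rmse = NA_real_)
    rows[[gi]] <- data.frame(k = k, metric = metric,
                             td_pct = grid$td_pct[gi],
                             te_pct = grid$te_pct[gi],
                             td_value = td, te_value = te, coverage = cov,
                             r2 = mt$r2, mae = mt$mae, rmse = mt$rmse)
  }
  tab <- do.call(rbind, rows)
  eligible <- which(tab$coverage >= coverageFloor & !is.na(tab$r2))
  pick <- if (length(eligible)) {
    e <- tab[eligible, ]
    ord <- order(-e$r2, -e$coverage, -(e$td_pct + e$te_pct))
    eligible[ord[1L]]
  } else which.max(tab$coverage)
  bundle@ad <- new("ADConfig", metric = tab$metric[pick],
                   k = as.integer(tab$k[pick]),
                   tdPercentile = tab$td_pct[pick],
                   tdValue = tab$td_value[pick],
                   tePercentile = tab$te_pct[pick],
                   teValue = tab$te_value[pick])
  list(bundle = bundle, table = tab)
}

#' Leverage values and high-leverage flags
#'
#' Hat-matrix diagonals h_i = x_i (X'X)^-1 x_i' with an intercept column
#' (pseudo-inverse when singular); a compound is flagged when h_i exceeds
#' 3(p+1)/n. Reporting-only: leverage does not enter the AD decision.
#'
#' @param trainX training descriptor matrix.
#' @param evalX optional matrix to evaluate (defaults to `trainX`).
#' @return data.frame with `leverage` and `high_leverage`.
#' @export
leverageFlags <- function(trainX, evalX = NULL) {
  X1 <- cbind(1, as.matrix(trainX))
  E1 <- if (is.null(evalX)) X1 else cbind(1, as.matrix(evalX))
  G <- crossprod(X1)
  Ginv <- tryCatch(solve(G), error = function(e) MASS::ginv(G))
  h <- rowSums((E1 %*% Ginv) * E1)
  cutoff <- 3 * ncol(X1) / nrow(X1)
  data.frame(leverage = h, high_leverage = h > cutoff)
}
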