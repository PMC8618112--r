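# Reporting statistics: R2 / MAE / RMSE, with and without the
# applicability domain, plus coverage.

#' Regression metrics
#'
#' R-squared is the determination coefficient 1 - SSres/SStot with SStot
#' about the observed mean; MAE the mean absolute error; RMSE the root
#' mean squared error. Zero-variance observations leave R-squared
#' undefined (NA, with a warning).
#'
#' @param obs observed values.
#' @param pred predicted values, same length.
#' @return list with `r2`, `mae`, `rmse`.
#' @export
regressionMetrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) > 0L)
  res <- obs - pred
  mae <- mean(abs(res))
  rmse <- sqrt(mean(res^2))
  sstot <- sum((obs - mean(obs))^2)
  r2 <- if (sstot == 0) {
    warning("zero-variance observations; R2 undefined")
    NA_real_
  } else 1 - sum(res^2) / sstot
  list(r2 = r2, mae = mae, rmse = rmse)
}

#' Evaluate a model on a dataset, with or without the applicability domain
#'
#' Predicts every compound, optionally restricts the metrics to compounds
#' inside the applicability domain (both the distance and the error-model
#' check must pass), and reports coverage.
#'
#' @param bundle a \linkS4class{ToxModelBundle} with AD attached when
#'   `applyAd = TRUE`.
#' @param X descriptor matrix (selected descriptors, in order).
#' @param y observed responses (transformed scale).
#' @param applyAd restrict metrics to in-domain compounds.
#' @param isTraining treat rows as training compounds (self-exclusion in
#'   neighbour searches).
#' @param subset label for the report ("train" or "validation").
#' @return list (EvaluationReport): r2, mae, rmse, coverage, n_total,
#'   n_in_ad, subset, ad_applied.
#' @export
evaluateWithAd <- function(bundle, X, y, applyAd = FALSE,
                           isTraining = FALSE,
                           subset = c("validation", "train")) {
  subset <- match.arg(subset)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  pred <- predictWithSpread(bundle, X)$prediction
  n <- nrow(X)
  if (!applyAd) {
    mt <- regressionMetrics(y, pred)
    return(list(r2 = mt$r2, mae = mt$mae, rmse = mt$rmse, coverage = 1,
                n_total = n, n_in_ad = n, subset = subset,
                ad_applied = FALSE))
  }
  inside <- vapply(seq_len(n), function(i)
    assessAD(X[i, , drop = FALSE], bundle,
             isTraining = isTraining,
             trainIndex = if (isTraining) i else NA_integer_)$inside,
    logical(1L))
  nIn <- sum(inside)
  if (nIn == 0L)
    return(list(r2 = NA_real_, mae = NA_real_, rmse = NA_real_,
                coverage = 0, n_total = n, n_in_ad = 0L, subset = subset,
                ad_applied = TRUE))
  mt <- regressionMetrics(y[inside], pred[inside])
  list(r2 = mt$r2, mae = mt$mae, rmse = mt$rmse, coverage = nIn / n,
       n_total = n, n_in_ad = nIn, subset = subset, ad_applied = TRUE)
}
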