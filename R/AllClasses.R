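#' @import methods
NULL

#' Box-Cox response transform
#'
#' Power transform (x^lambda - 1)/lambda (ln x at lambda = 0) fitted by
#' profile log-likelihood, together with the mean and standard deviation of
#' the transformed training responses used by the +/- 3 SD outlier rule.
#'
#' @slot lambda fitted power (unitless).
#' @slot meanT mean of the transformed values.
#' @slot sdT sample standard deviation (n - 1) of the transformed values.
#' @slot interval search interval that produced lambda.
#' @export
setClass("BoxCoxTransform",
  representation(lambda = "numeric", meanT = "numeric", sdT = "numeric",
                 interval = "numeric"),
  prototype(lambda = NA_real_, meanT = NA_real_, sdT = NA_real_,
            interval = c(-2, 2)),
  validity = function(object) {
    msg <- character(0)
    if (length(object@lambda) != 1L || !is.finite(object@lambda))
      msg <- c(msg, "lambda must be a single finite number")
    if (length(object@sdT) == 1L && is.finite(object@sdT) && object@sdT < 0)
      msg <- c(msg, "sdT must be >= 0")
    if (length(object@interval) != 2L || object@interval[1] >= object@interval[2])
      msg <- c(msg, "interval must be increasing length-2")
    else if (is.finite(object@lambda) &&
             (object@lambda < object@interval[1] - 1e-8 ||
              object@lambda > object@interval[2] + 1e-8))
      msg <- c(msg, "lambda outside its search interval")
    if (length(msg)) msg else TRUE
  })

#' Molecular descriptor matrix
#'
#' Compounds-by-descriptors numeric matrix with compound identifiers as row
#' names, unique descriptor names as column names, and a provenance string
#' naming the toolkit that produced the values.
#'
#' @slot values dense numeric matrix (compounds x descriptors), no missing
#'   values in a finalized matrix.
#' @slot provenance toolkit name/version string.
#' @slot pruneLog character log of pruning actions applied.
#' @export
setClass("DescriptorMatrix",
  representation(values = "matrix", provenance = "character",
                 pruneLog = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character(0)
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    if (is.null(rownames(v))) msg <- c(msg, "values must have compound row names")
    if (ncol(v) > 0 && is.null(colnames(v)))
      msg <- c(msg, "values must have descriptor column names")
    if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
      msg <- c(msg, "descriptor names must be unique")
    if (is.numeric(v) && any(!is.finite(v)))
      msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Curated endpoint dataset
#'
#' One consolidated, Box-Cox-transformed response per retained compound for
#' a single species/endpoint/duration combination, plus the per-compound
#' curation ledger (exclusions carry a reason).
#'
#' @slot endpoint endpoint label (EC50, LC50 or NOEC).
#' @slot species species label.
#' @slot trophicLevel one of alga, daphnid, fish.
#' @slot compounds data.frame with columns cas, smiles (normalized),
#'   neutralized_smiles, mw, response_mmol, response_transformed, retained,
#'   exclusion (NA when retained).
#' @slot transform fitted \linkS4class{BoxCoxTransform}.
#' @export
setClass("EndpointDataset",
  representation(endpoint = "character", species = "character",
                 trophicLevel = "character", compounds = "data.frame",
                 transform = "BoxCoxTransform"),
  validity = function(object) {
    cp <- object@compounds
    need <- c("cas", "smiles", "neutralized_smiles", "mw", "response_mmol",
              "response_transformed", "retained", "exclusion")
    msg <- character(0)
    if (!all(need %in% names(cp)))
      msg <- c(msg, paste("compounds must have columns:",
                          paste(setdiff(need, names(cp)), collapse = ", ")))
    else {
      ret <- cp$retained
      if (any(ret & !is.na(cp$exclusion)))
        msg <- c(msg, "retained compounds must not carry an exclusion reason")
      if (any(!ret & is.na(cp$exclusion)))
        msg <- c(msg, "excluded compounds must carry an exclusion reason")
      if (any(ret & (!is.finite(cp$response_mmol) | cp$response_mmol <= 0)))
        msg <- c(msg, "retained compounds need a positive response_mmol")
      if (any(ret & (!is.finite(cp$mw) | cp$mw <= 0)))
        msg <- c(msg, "retained compounds need a positive molecular weight")
    }
    if (length(msg)) msg else TRUE
  })

#' Applicability-domain configuration
#'
#' Distance and error thresholds defining the dual applicability domain:
#' a compound is inside the domain iff its mean k-nearest-neighbour
#' distance to the training set is at most `tdValue` AND its error-model
#' predicted absolute error is at most `teValue`.
#'
#' @slot metric distance metric, "euclidean" or "manhattan".
#' @slot k neighbour count used for the distance check (1 or 5).
#' @slot tdPercentile percentile of training mean-kNN distances defining
#'   `tdValue` (1.0, 0.975, 0.95 or 0.90).
#' @slot tdValue distance threshold (descriptor-space units).
#' @slot tePercentile percentile of training predicted errors defining
#'   `teValue` (1.0, 0.90, 0.75 or 0.65).
#' @slot teValue error threshold (transformed response units).
#' @export
setClass("ADConfig",
  representation(metric = "character", k = "integer",
                 tdPercentile = "numeric", tdValue = "numeric",
                 tePercentile = "numeric", teValue = "numeric"),
  prototype(metric = "euclidean", k = 5L, tdPercentile = 1.0,
            tdValue = Inf, tePercentile = 1.0, teValue = Inf),
  validity = function(object) {
    msg <- character(0)
    if (!object@metric %in% c("euclidean", "manhattan"))
      msg <- c(msg, "metric must be euclidean or manhattan")
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    for (p in c(object@tdPercentile, object@tePercentile))
      if (p <= 0 || p > 1) msg <- c(msg, "percentiles must be in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Trained QSAR model bundle
#'
#' The fitted random-forest activity model plus everything needed to
#' predict and to judge prediction reliability: selected descriptor names,
#' the response transform, training descriptor matrix and responses (for
#' neighbour-based applicability-domain metrics), scaling statistics, the
#' fitted error model, and the selected \linkS4class{ADConfig}.
#'
#' @slot rf fitted randomForest activity model.
#' @slot config list: n_trees, max_features, min_samples_leaf,
#'   bootstrap_rows, seed.
#' @slot selectedDescriptors descriptor names the model requires, in order.
#' @slot transform \linkS4class{BoxCoxTransform} applied to the response.
#' @slot trainX training descriptor matrix (selected descriptors only).
#' @slot trainY training responses on the transformed scale.
#' @slot scaling list(center, sdev) used to autoscale descriptor space for
#'   all distance computations.
#' @slot cvErrors per-row cross-validated absolute errors of the activity
#'   model (basis of the error model).
#' @slot errorModel fitted randomForest error model (or NULL before
#'   attachment).
#' @slot ad \linkS4class{ADConfig}.
#' @export
setClass("ToxModelBundle",
  representation(rf = "ANY", config = "list",
                 selectedDescriptors = "character",
                 transform = "BoxCoxTransform",
                 trainX = "matrix", trainY = "numeric", scaling = "list",
                 cvErrors = "numeric", errorModel = "ANY", ad = "ADConfig"),
  validity = function(object) {
    msg <- character(0)
    if (!identical(colnames(object@trainX), object@selectedDescriptors))
      msg <- c(msg, "trainX columns must equal selectedDescriptors, in order")
    if (nrow(object@trainX) != length(object@trainY))
      msg <- c(msg, "trainX rows must match trainY length")
    if (length(msg)) msg else TRUE
  })
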