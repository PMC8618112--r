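# Rational 80:20 split: PCA on the descriptor block, then iterative
# most-dissimilar sampling in (PC1, PC2, scaled response) space.

#' First two principal components of a descriptor matrix
#'
#' Columns are autoscaled before decomposition. The sign of each component
#' is fixed so that its largest-magnitude loading is positive, making
#' scores reproducible across runs and platforms.
#'
#' @param m a \linkS4class{DescriptorMatrix} (or numeric matrix) with at
#'   least two non-constant columns.
#' @return list with `scores` (n x 2), `explainedVariance` (length-2
#'   fractions of total variance) and `loadings`.
#' @export
pcaScores <- function(m) {
  v <- if (is(m, "DescriptorMatrix")) m@values else as.matrix(m)
  sds <- apply(v, 2L, stats::sd)
  v <- v[, sds > 0, drop = FALSE]
  if (ncol(v) < 2L)
    stop("PCA needs at least 2 non-constant descriptors", call. = FALSE)
  pc <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  if (length(pc$sdev) < 2L || pc$sdev[2L] <= 1e-8 * pc$sdev[1L])
    stop("descriptor matrix has rank < 2", call. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  scores <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explainedVariance = ev[1:2], loadings = rot)
}

#' Dissimilarity-based training/validation split
#'
#' Seeds the training set with five random compounds, then repeatedly adds
#' the compound most dissimilar from the current training pool in the
#' joint space of the two principal components and the autoscaled response
#' (weight 1 each), until the training set holds `frac` of the compounds
#' (round-half-up). The remainder forms the validation set. Scoring
#' "maxmin" adds the compound with the largest minimum distance to the
#' pool; "maxsum" the largest total distance. Ties go to the lowest
#' compound index.
#'
#' @param scores n x 2 PC score matrix from [pcaScores()].
#' @param y responses (transformed scale), length n.
#' @param frac training fraction in (0, 1); default 0.8.
#' @param seed RNG seed for the five initial compounds.
#' @param metric "euclidean" (default) or "manhattan".
#' @param scoring "maxmin" (default) or "maxsum".
#' @param ids optional compound identifiers (default rownames of scores).
#' @return list with `train_ids`, `valid_ids`, `train_idx`, `valid_idx`,
#'   `seed`, `metric`, `scoring`.
#' @export
dissimilaritySplit <- function(scores, y, frac = 0.8, seed = 1L,
                               metric = c("euclidean", "manhattan"),
                               scoring = c("maxmin", "maxsum"),
                               ids = NULL) {
  metric <- match.arg(metric); scoring <- match.arg(scoring)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(y) == n)
  if (n < 7L) stop("need at least 7 compounds to split", call. = FALSE)
  if (!is.finite(frac) || frac <= 0 || frac >= 1)
    stop("'frac' must be in (0, 1)", call. = FALSE)
  ids <- ids %||% rownames(scores) %||% as.character(seq_len(n))
  ysc <- as.numeric(scale(y))
  if (any(!is.finite(ysc))) ysc <- rep(0, n)   # constant response
  space <- cbind(scores, ysc)
  nTrain <- as.integer(roundHalfUp(frac * n))
  nTrain <- max(min(nTrain, n - 1L), 5L)
  pool <- withSeed(seed, sample.int(n, 5L))
  D <- rowDistances(space, space, metric = metric)
  while (length(pool) < nTrain) {
    rest <- setdiff(seq_len(n), pool)
    sc <- if (scoring == "maxmin")
      apply(D[rest, pool, drop = FALSE], 1L, min)
    else rowSums(D[rest, pool, drop = FALSE])
    pick <- rest[which.max(sc)]   # which.max: first (lowest index) wins ties
    pool <- c(pool, pick)
  }
  train <- sort(pool)
  valid <- setdiff(seq_len(n), train)
  list(train_ids = ids[train], valid_ids = ids[valid],
       train_idx = train, valid_idx = valid,
       seed = as.integer(seed), metric = metric, scoring = scoring)
}
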