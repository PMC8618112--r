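# Variable selection: genetic algorithm over descriptor subsets, and a
# three-phase random-forest importance procedure (thresholding,
# interpretation, prediction).

#' Genetic-algorithm settings
#'
#' @param populationSize chromosomes per generation.
#' @param generations number of generations.
#' @param subsetMin,subsetMax bounds on the descriptor-subset size.
#' @param crossoverP per-gene uniform crossover probability.
#' @param mutationP per-gene mutation probability.
#' @param tournamentSize tournament selection size.
#' @param elitism chromosomes copied unchanged to the next generation.
#' @param fitnessTrees trees in the fitness forest (out-of-bag R-squared
#'   of a forest on the subset is the fitness).
#' @return config list.
#' @export
gaConfig <- function(populationSize = 40L, generations = 30L,
                     subsetMin = 5L, subsetMax = 40L, crossoverP = 0.5,
                     mutationP = 0.02, tournamentSize = 3L, elitism = 2L,
                     fitnessTrees = 50L) {
  as.list(environment())
}

.repairMask <- function(mask, lo, hi) {
  size <- sum(mask)
  if (size < lo) {
    zeros <- which(!mask)
    mask[sample(zeros, lo - size)] <- TRUE
  } else if (size > hi) {
    ones <- which(mask)
    mask[sample(ones, size - hi)] <- FALSE
  }
  mask
}

#' Select descriptors with a genetic algorithm
#'
#' Binary chromosomes encode descriptor subsets within the configured size
#' bounds. Fitness is the out-of-bag R-squared of a random forest fitted
#' on the subset (a bootstrap cross-validation estimate); evaluations are
#' memoised. Tournament selection, uniform crossover, per-gene mutation,
#' elitism; the best-so-far trace is non-decreasing by construction.
#'
#' @param X descriptor matrix (matrix or \linkS4class{DescriptorMatrix}).
#' @param y responses, length nrow(X).
#' @param cfg settings from [gaConfig()].
#' @param seed RNG seed; identical (X, y, cfg, seed) give identical
#'   results.
#' @return list: method = "ga", selected_names, fitness, history
#'   (best-so-far per generation), seed.
#' @export
gaSelect <- function(X, y, cfg = gaConfig(), seed = 1L) {
  X <- if (is(X, "DescriptorMatrix")) X@values else as.matrix(X)
  p <- ncol(X)
  stopifnot(nrow(X) == length(y))
  if (p == 1L)
    return(list(method = "ga", selected_names = colnames(X),
                fitness = NA_real_, history = numeric(0),
                seed = as.integer(seed)))
  if (p < cfg$subsetMin)
    stop("fewer descriptors (", p, ") than the minimum subset size (",
         cfg$subsetMin, ")", call. = FALSE)
  lo <- cfg$subsetMin; hi <- min(cfg$subsetMax, p)
  cache <- new.env(parent = emptyenv())
  evalMask <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    Xi <- X[, mask, drop = FALSE]
    rf <- randomForest::randomForest(
      x = Xi, y = y, ntree = cfg$fitnessTrees,
      mtry = max(1L, floor(ncol(Xi) / 3)))
    fit <- rf$rsq[length(rf$rsq)]
    cache[[key]] <- fit
    fit
  }
  withSeed(seed, {
    pop <- lapply(seq_len(cfg$populationSize), function(i) {
      size <- sample(lo:hi, 1L)
      mask <- rep(FALSE, p); mask[sample.int(p, size)] <- TRUE
      mask
    })
    fitness <- vapply(pop, evalMask, numeric(1L))
    history <- numeric(cfg$generations)
    bestMask <- pop[[which.max(fitness)]]
    bestFit <- max(fitness)
    for (g in seq_len(cfg$generations)) {
      ord <- order(fitness, decreasing = TRUE)
      newPop <- pop[ord[seq_len(cfg$elitism)]]
      while (length(newPop) < cfg$populationSize) {
        pick <- function() {
          cand <- sample.int(length(pop), cfg$tournamentSize)
          pop[[cand[which.max(fitness[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        cross <- stats::runif(p) < cfg$crossoverP
        child <- ifelse(cross, p2, p1)
        mut <- stats::runif(p) < cfg$mutationP
        child <- xor(child, mut)
        child <- .repairMask(child, lo, hi)
        newPop[[length(newPop) + 1L]] <- child
      }
      pop <- newPop
      fitness <- vapply(pop, evalMask, numeric(1L))
      if (max(fitness) > bestFit) {
        bestFit <- max(fitness)
        bestMask <- pop[[which.max(fitness)]]
      }
      history[g] <- bestFit
    }
    list(method = "ga", selected_names = colnames(X)[bestMask],
         fitness = bestFit, history = history, seed = as.integer(seed))
  })
}

#' Three-phase importance-selection settings
#'
#' @param nForests forests averaged in the thresholding phase.
#' @param ntree trees per forest.
#' @param nested maximum number of nested models grown in the
#'   interpretation phase (caps runtime for very wide pools).
#' @param nForestsNested forests averaged per nested/stepwise model in
#'   the interpretation and prediction phases.
#' @return config list.
#' @export
vsurfConfig <- function(nForests = 25L, ntree = 100L, nested = 50L,
                        nForestsNested = 3L) {
  as.list(environment())
}

#' Select descriptors by the three-phase random-forest procedure
#'
#' Phase 1 (thresholding): variables are ranked by mean permutation
#' importance over `nForests` forests; those whose mean importance falls
#' below the minimum of a piecewise-constant (CART) fit to the importance
#' standard deviations are discarded. Phase 2 (interpretation): nested
#' forests over the ranked survivors; the prefix with the smallest
#' out-of-bag error is kept. Phase 3 (prediction): survivors are added
#' stepwise only when they reduce the error by more than a noise-scaled
#' margin (the mean error jump among variables beyond the interpretation
#' prefix).
#'
#' @param X descriptor matrix (matrix or \linkS4class{DescriptorMatrix}).
#' @param y responses.
#' @param cfg settings from [vsurfConfig()].
#' @param seed RNG seed.
#' @return list: method = "vsurf", selected_names (phase-3 set),
#'   interpretation_names, threshold_names, importance (mean/sd per
#'   variable), history (nested OOB errors), seed.
#' @export
vsurfSelect <- function(X, y, cfg = vsurfConfig(), seed = 1L) {
  X <- if (is(X, "DescriptorMatrix")) X@values else as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y))
  if (n < 10L) stop("too few rows for the configured forests", call. = FALSE)
  withSeed(seed, {
    # phase 1: importance ranking and variability threshold
    imps <- matrix(NA_real_, nrow = cfg$nForests, ncol = p,
                   dimnames = list(NULL, colnames(X)))
    for (r in seq_len(cfg$nForests)) {
      rf <- randomForest::randomForest(x = X, y = y, ntree = cfg$ntree,
                                       importance = TRUE)
      imps[r, ] <- randomForest::importance(rf, type = 1L, scale = FALSE)
    }
    viMean <- colMeans(imps)
    viSd <- apply(imps, 2L, stats::sd)
    ord <- order(viMean, decreasing = TRUE)
    rank <- seq_len(p)
    fitPw <- rpart::rpart(sd ~ rank,
                          data = data.frame(sd = viSd[ord], rank = rank))
    thr <- min(stats::predict(fitPw))
    keep1 <- colnames(X)[ord][viMean[ord] > thr & viMean[ord] > 0]
    if (!length(keep1)) keep1 <- colnames(X)[ord][1L]
    # phase 2: nested models over ranked survivors (errors averaged
    # over a few forests to stabilise the curve)
    oobErr <- function(vars) {
      mean(vapply(seq_len(cfg$nForestsNested), function(r) {
        rfj <- randomForest::randomForest(x = X[, vars, drop = FALSE],
                                          y = y, ntree = cfg$ntree)
        rfj$mse[length(rfj$mse)]
      }, numeric(1L)))
    }
    m <- min(length(keep1), cfg$nested)
    errs <- numeric(m)
    for (j in seq_len(m)) errs[j] <- oobErr(keep1[seq_len(j)])
    jStar <- which.min(errs)
    interp <- keep1[seq_len(jStar)]
    # phase 3: stepwise inclusion with noise-scaled margin: the mean
    # error jump among models beyond the interpretation prefix (the flat
    # tail of the nested-error curve); falls back to the last quarter of
    # the curve when the prefix reaches the end
    tailErr <- if (jStar < m) errs[jStar:m] else
      errs[max(1L, m - max(2L, m %/% 4)):m]
    margin <- if (length(tailErr) >= 2L) mean(abs(diff(tailErr))) else 0
    cur <- character(0); prevErr <- Inf
    for (v in interp) {
      err <- oobErr(c(cur, v))
      if (!length(cur) || prevErr - err > margin) {
        cur <- c(cur, v); prevErr <- err
      }
    }
    list(method = "vsurf", selected_names = cur,
         interpretation_names = interp, threshold_names = keep1,
         importance = data.frame(name = colnames(X), mean = viMean,
                                 sd = viSd, row.names = NULL),
         history = errs, seed = as.integer(seed))
  })
}
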