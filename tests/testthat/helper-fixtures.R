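# shared test fixtures, built once per run and cached

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# small regression benchmark with 3 informative variables
smallBenchmark <- function() {
  cached("bench", function()
    generateRegressionBenchmark(n = 200, p = 12, p_informative = 3,
                                noise_sd = 0.5, seed = 42))
}

# trained bundle with error model on the small benchmark
smallBundle <- function() {
  cached("bundle", function() {
    b <- smallBenchmark()
    bundle <- trainForest(b$X, b$y,
                          config = rfConfig(n_trees = 150L,
                                            max_features = 0.33,
                                            min_samples_leaf = 3L,
                                            seed = 5L))
    trainErrorModel(bundle, seed = 5L, cvFolds = 5L)
  })
}

# tiny record fixture shared by curation tests
smallRecordFixture <- function() {
  cached("records", function() {
    spec <- fixtureSpec(n_compounds = 60)
    lib <- generateCompoundLibrary(spec, seed = 3)
    gen <- generateToxicityRecords(lib, spec, seed = 3)
    list(spec = spec, lib = lib, gen = gen)
  })
}

# compose the modelling stages on a plain (X, y) benchmark: split,
# selection, tuning, training, AD, evaluation - used by recovery tests
runBenchmarkPipeline <- function(X, y, seed = 1L,
                                 selection = c("vsurf", "ga", "none"),
                                 tuneGrid = list(
                                   rfConfig(n_trees = 200L,
                                            max_features = 0.33,
                                            min_samples_leaf = 3L),
                                   rfConfig(n_trees = 200L,
                                            max_features = 0.6,
                                            min_samples_leaf = 1L)),
                                 tuneB = 10L, cvFolds = 10L) {
  selection <- match.arg(selection)
  pca <- pcaScores(X)
  sp <- dissimilaritySplit(pca$scores, y, frac = 0.8, seed = seed)
  Xtr <- X[sp$train_idx, , drop = FALSE]
  Xva <- X[sp$valid_idx, , drop = FALSE]
  ytr <- y[sp$train_idx]; yva <- y[sp$valid_idx]
  sel <- switch(selection,
    vsurf = {
      s <- vsurfSelect(Xtr, ytr,
                       cfg = vsurfConfig(nForests = 8L, ntree = 60L,
                                         nested = 20L),
                       seed = seed)
      s$selected_names <- s$interpretation_names   # as the pipeline does
      s
    },
    ga = gaSelect(Xtr, ytr,
                  cfg = gaConfig(populationSize = 24L, generations = 15L,
                                 subsetMin = 2L, subsetMax = 10L,
                                 fitnessTrees = 40L),
                  seed = seed),
    none = list(selected_names = colnames(X)))
  Xtr <- Xtr[, sel$selected_names, drop = FALSE]
  Xva <- Xva[, sel$selected_names, drop = FALSE]
  tuned <- tuneForest(Xtr, ytr, grid = tuneGrid, B = tuneB, seed = seed)
  cfg <- tuned$best; cfg$seed <- seed
  bundle <- trainForest(Xtr, ytr, config = cfg)
  bundle <- trainErrorModel(bundle, seed = seed, cvFolds = cvFolds)
  ad <- selectAdConfig(bundle, cvFolds = cvFolds, seed = seed)
  list(bundle = ad$bundle, adTable = ad$table, split = sp,
       selection = sel,
       validation = evaluateWithAd(ad$bundle, Xva, yva, applyAd = FALSE),
       validation_ad = evaluateWithAd(ad$bundle, Xva, yva, applyAd = TRUE))
}
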