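test_that("compound library hits its role fractions and parses fully", {
  spec <- fixtureSpec(n_compounds = 100, salt_fraction = 0.1,
                      excludable_fraction = 0.1, ionizable_fraction = 0.15)
  lib <- generateCompoundLibrary(spec, seed = 7)
  expect_identical(nrow(lib), 100L)
  counts <- table(lib$role)
  expect_lte(abs(counts[["salt"]] - 10L), 1L)
  expect_lte(abs(counts[["excludable"]] - 10L), 1L)
  expect_lte(abs(counts[["ionizable"]] - 15L), 1L)
  for (smi in lib$smiles) expect_true(validateSmiles(smi))
  # determinism
  lib2 <- generateCompoundLibrary(spec, seed = 7)
  expect_identical(lib, lib2)
  # no excludables: classification keeps everything modelable
  spec0 <- fixtureSpec(n_compounds = 30, excludable_fraction = 0)
  lib0 <- generateCompoundLibrary(spec0, seed = 2)
  for (smi in lib0$smiles) {
    std <- standardizeStructure(smi)
    expect_true(classifyStructure(std$neutralized_smiles)$keep)
  }
  expect_error(fixtureSpec(salt_fraction = 0.6, excludable_fraction = 0.5),
               "fractions")
})

test_that("record generation matches its bookkeeping contracts", {
  fx <- smallRecordFixture()
  gen <- fx$gen
  # deterministic regeneration
  gen2 <- generateToxicityRecords(fx$lib, fx$spec, seed = 3)
  expect_identical(gen$records, gen2$records)
  # zero spread: consolidation returns each compound's exact value
  spec0 <- fixtureSpec(n_compounds = 30, replicate_spread = 0,
                       censored_fraction = 0, ph_adjusted_fraction = 0,
                       inflated_fraction = 0, excludable_fraction = 0,
                       solubility_violation_fraction = 0,
                       outlier_fraction = 0)
  lib0 <- generateCompoundLibrary(spec0, seed = 5)
  gen0 <- generateToxicityRecords(lib0, spec0, seed = 5)
  bk <- gen0$bookkeeping$compounds
  for (i in seq_len(nrow(bk))) {
    vals <- gen0$records$value_mg_l[gen0$records$cas == bk$cas[i]] / bk$mw[i]
    expect_equal(consolidateReplicates(vals)$value, bk$true_mmol[i],
                 tolerance = 1e-9)
  }
  # fully censored records leave nothing for the filter to keep
  spec1 <- fixtureSpec(n_compounds = 20, censored_fraction = 1,
                       excludable_fraction = 0)
  lib1 <- generateCompoundLibrary(spec1, seed = 9)
  gen1 <- generateToxicityRecords(lib1, spec1, seed = 9)
  out <- filterValueRecords(gen1$records, defaultFilterCriteria("daphnid"))
  expect_identical(nrow(out$kept), 0L)
})

test_that("regression benchmark is seeded with recoverable signal", {
  b1 <- generateRegressionBenchmark(100, 10, 3, 0.5, seed = 1)
  b2 <- generateRegressionBenchmark(100, 10, 3, 0.5, seed = 1)
  expect_identical(b1$X, b2$X); expect_identical(b1$y, b2$y)
  expect_identical(b1$truth$informative_names, paste0("inf0", 1:3))
  # noiseless limit: a forest almost interpolates
  b0 <- generateRegressionBenchmark(300, 10, 3, 1e-9, seed = 4)
  m <- trainForest(b0$X, b0$y,
                   config = rfConfig(n_trees = 300L, max_features = 0.6,
                                     min_samples_leaf = 1L, seed = 1L))
  r2 <- regressionMetrics(b0$y,
                          predictWithSpread(m, b0$X)$prediction)$r2
  expect_gt(r2, 0.98)
  # no informative variables: even the best attainable predictor (the
  # training mean) gives validation R2 near zero
  r2s <- vapply(1:6, function(s) {
    bn <- generateRegressionBenchmark(200, 10, 0, 1, seed = 500 + s)
    idx <- seq_len(150)
    regressionMetrics(bn$y[-idx],
                      rep(mean(bn$y[idx]), 50))$r2
  }, numeric(1))
  expect_lt(abs(mean(r2s)), 0.15)
})
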