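mkRecord <- function(cas = "1-1-1", smiles = "CCO", endpoint = "EC50",
                     duration = 48, value = 1, qualifier = "exact",
                     ph = FALSE, sol = NA_real_) {
  data.frame(cas = cas, name = cas, smiles = smiles, endpoint = endpoint,
             species = "Daphnia magna", duration_h = duration,
             value_mg_l = value, qualifier = qualifier, ph_adjusted = ph,
             solubility_mg_l = sol, source = "test",
             stringsAsFactors = FALSE)
}

test_that("record filtering drops censored, off-window and pH-adjusted records", {
  crit <- defaultFilterCriteria("daphnid")
  recs <- rbind(mkRecord(cas = "a", qualifier = "greater_than"),
                mkRecord(cas = "b", qualifier = "less_than"),
                mkRecord(cas = "c", qualifier = "approximate"),
                mkRecord(cas = "d", qualifier = "range"),
                mkRecord(cas = "e", duration = 120),
                mkRecord(cas = "f", ph = TRUE),
                mkRecord(cas = "g"))
  out <- filterValueRecords(recs, crit)
  expect_identical(out$kept$cas, "g")
  expect_identical(out$audit$reason[out$audit$cas %in% c("a", "b", "c", "d")],
                   rep("censored", 4))
  expect_identical(out$audit$reason[out$audit$cas == "e"], "duration")
  expect_identical(out$audit$reason[out$audit$cas == "f"], "ph_adjusted")
  # every record appears exactly once in kept or audit
  expect_setequal(c(out$audit$row, which(recs$cas %in% out$kept$cas)),
                  seq_len(nrow(recs)))
  # unknown endpoint label is a configuration error
  expect_error(filterValueRecords(mkRecord(endpoint = "LOEC"), crit),
               "duration window")
  expect_error(filterValueRecords(mkRecord(qualifier = "maybe"), crit),
               "qualifier")
})

test_that("fish LC50 at 120 h falls outside the 96 h guideline window", {
  crit <- defaultFilterCriteria("fish")
  rec <- mkRecord(endpoint = "LC50", duration = 120)
  out <- filterValueRecords(rec, crit)
  expect_identical(out$audit$reason, "duration")
  out96 <- filterValueRecords(mkRecord(endpoint = "LC50", duration = 96),
                              crit)
  expect_identical(nrow(out96$audit), 0L)
})

test_that("mg/L to mmol/L conversion is exact division", {
  expect_identical(toMillimolar(5, 250), 0.02)
  expect_identical(toMillimolar(100, 100), 1)
  expect_equal(toMillimolar(1, 78.11), 1 / 78.11, tolerance = 1e-12)
  expect_error(toMillimolar(-1, 10), "positive")
  expect_error(toMillimolar(1, 0), "positive")
  # exactness property: round-trips to machine precision
  set.seed(1)
  v <- runif(200, 1e-6, 1e3); mw <- runif(200, 10, 900)
  expect_equal(toMillimolar(v, mw) * mw, v, tolerance = 1e-12)
})

test_that("replicate consolidation enforces the factor-of-10 rule", {
  r <- consolidateReplicates(c(1, 100))
  expect_false(r$ok)
  expect_equal(r$ratio, 100)
  forced <- consolidateReplicates(c(1, 100), enforceSpread = FALSE)
  expect_equal(forced$value, 10)
  single <- consolidateReplicates(0.5)
  expect_equal(single$value, 0.5)
  # boundary ratio exactly 10 passes ("within a factor of 10")
  expect_true(consolidateReplicates(c(0.2, 2))$ok)
  expect_error(consolidateReplicates(numeric(0)), "no replicate")
  # geometric mean of k copies of c equals c
  expect_equal(consolidateReplicates(rep(3.7, 5))$value, 3.7)
  # property: acceptance agrees with brute-force ratio check
  set.seed(7)
  for (i in 1:50) {
    vals <- exp(runif(sample(2:6, 1), -2, 2))
    expect_identical(consolidateReplicates(vals)$ok,
                     max(vals) / min(vals) <= 10 * (1 + 1e-9))
  }
})

test_that("solubility screen drops responses above solubility only", {
  expect_false(solubilityScreen(5, 1)$keep)
  expect_true(solubilityScreen(0.5, 1)$keep)
  absent <- solubilityScreen(5, NA)
  expect_true(absent$keep)
  expect_true(absent$warning)
})

test_that("curation is order-invariant and accounts for every compound", {
  fx <- smallRecordFixture()
  recs <- fx$gen$records
  cur1 <- curateRecords(recs, "EC50", "Daphnia magna", "daphnid")
  perm <- withr::with_seed(99, sample.int(nrow(recs)))
  cur2 <- curateRecords(recs[perm, ], "EC50", "Daphnia magna", "daphnid")
  r1 <- retainedCompounds(cur1$dataset)
  r2 <- retainedCompounds(cur2$dataset)
  expect_identical(r1$cas, r2$cas)
  expect_equal(r1$response_mmol, r2$response_mmol, tolerance = 1e-12)
  expect_equal(lambdaOf(cur1$dataset@transform),
               lambdaOf(cur2$dataset@transform), tolerance = 1e-9)
  # every library compound appears exactly once in the compound ledger
  expect_setequal(cur1$dataset@compounds$cas, unique(recs$cas))
  # exclusions carry reasons, retentions do not
  cp <- cur1$dataset@compounds
  expect_true(all(is.na(cp$exclusion[cp$retained])))
  expect_true(all(!is.na(cp$exclusion[!cp$retained])))
})
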