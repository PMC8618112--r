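test_that("descriptor matrix has a shared finite column set and is deterministic", {
  r <- computeDescriptors(c(ethane = "CC", ethanol = "CCO"))
  v <- descriptorValues(r$matrix)
  expect_identical(nrow(v), 2L)
  expect_true(all(is.finite(v)))
  expect_gt(ncol(v), 30)
  # determinism: same structure twice gives identical vectors
  r2 <- computeDescriptors(c(b1 = "c1ccccc1", b2 = "c1ccccc1"))
  v2 <- descriptorValues(r2$matrix)
  expect_identical(v2[1, ], v2[2, ])
  # repeated runs identical
  r3 <- computeDescriptors(c(ethane = "CC", ethanol = "CCO"))
  expect_identical(v, descriptorValues(r3$matrix))
})

test_that("compounds with uncomputable logP are dropped with a reason", {
  r <- computeDescriptors(c(ok = "CCO", sil = "CC[Si](C)(C)C"))
  expect_identical(r$dropped$id, "sil")
  expect_identical(r$dropped$reason, "alogp_not_computable")
  expect_identical(compoundIds(r$matrix), "ok")
  expect_error(computeDescriptors(character(0)), "no compounds")
})

test_that("constant-column pruning removes exactly the zero-variance columns", {
  m <- cbind(const = rep(1, 5), near = c(1, 1, 1.0001, 1, 1),
             var = 1:5)
  rownames(m) <- paste0("c", 1:5)
  dm <- new("DescriptorMatrix", values = m, provenance = "test",
            pruneLog = character(0))
  pruned <- pruneConstant(dm)
  expect_setequal(descriptorNames(pruned), c("near", "var"))
  expect_identical(nrow(descriptorValues(pruned)), 5L)
  # surviving values untouched
  expect_identical(descriptorValues(pruned)[, "var"], m[, "var"])
  allconst <- new("DescriptorMatrix",
                  values = matrix(1, 4, 2,
                                  dimnames = list(paste0("c", 1:4),
                                                  c("a", "b"))),
                  provenance = "test", pruneLog = character(0))
  expect_warning(empty <- pruneConstant(allconst), "constant")
  expect_identical(ncol(descriptorValues(empty)), 0L)
})

test_that("correlation pruning leaves no pair above the bound", {
  base <- withr::with_seed(11, matrix(rnorm(100 * 6), 100, 6))
  m <- cbind(base, dup = base[, 1], anti = -base[, 2] + 1e-8 * rnorm(100))
  colnames(m) <- c(paste0("v", 1:6), "dup", "anti")
  rownames(m) <- paste0("c", 1:100)
  dm <- new("DescriptorMatrix", values = m, provenance = "test",
            pruneLog = character(0))
  pruned <- pruneCorrelated(dm, rMax = 0.95)
  v <- descriptorValues(pruned)
  # exactly one of each duplicated/anticorrelated pair survives
  expect_identical(sum(c("v1", "dup") %in% colnames(v)), 1L)
  expect_identical(sum(c("v2", "anti") %in% colnames(v)), 1L)
  # independent random columns all survive
  expect_true(all(paste0("v", 3:6) %in% colnames(v)))
  # brute-force post-condition: no remaining pair with |r| > 0.95
  cm <- abs(cor(v)); diag(cm) <- 0
  expect_lt(max(cm), 0.95)
  # row count unchanged, values unmodified
  expect_identical(nrow(v), 100L)
  for (nm in colnames(v)) expect_identical(v[, nm], m[, nm])
})

test_that("correlation pruning is deterministic on random wide matrices", {
  for (seed in c(1, 2)) {
    X <- withr::with_seed(seed, {
      A <- matrix(rnorm(60 * 30), 60, 30)
      cbind(A, A[, 1:10] + 0.05 * matrix(rnorm(600), 60, 10))
    })
    colnames(X) <- sprintf("d%02d", seq_len(ncol(X)))
    rownames(X) <- sprintf("r%02d", seq_len(nrow(X)))
    dm <- new("DescriptorMatrix", values = X, provenance = "t",
              pruneLog = character(0))
    p1 <- pruneCorrelated(dm)
    p2 <- pruneCorrelated(dm)
    expect_identical(descriptorNames(p1), descriptorNames(p2))
    cm <- abs(cor(descriptorValues(p1))); diag(cm) <- 0
    expect_lt(max(cm), 0.95)
  }
})
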