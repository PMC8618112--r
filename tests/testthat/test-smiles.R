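test_that("SMILES validation accepts well-formed and rejects malformed input", {
  expect_true(validateSmiles("CCO"))
  expect_true(validateSmiles("c1ccc2ccccc2c1"))
  expect_true(validateSmiles("CC(=O)[O-].[Na+]"))
  expect_error(validateSmiles("C1CC1C("), class = "aquatox_parse_error")
  expect_error(validateSmiles("C1CC1C2"), class = "aquatox_parse_error")
  expect_error(validateSmiles(""), class = "aquatox_parse_error")
  expect_error(validateSmiles("not_a_smiles"), class = "aquatox_parse_error")
  err <- tryCatch(validateSmiles("C1CC1C("), error = identity)
  expect_identical(err$smiles, "C1CC1C(")
})

test_that("element extraction and component splitting read structures correctly", {
  expect_identical(smilesElements("CCO"), c("C", "C", "O"))
  expect_identical(smilesElements("c1ccncc1"),
                   c("C", "C", "C", "N", "C", "C"))
  expect_identical(smilesElements("[Na+].[Cl-]"), c("Na", "Cl"))
  expect_identical(smilesComponents("CC(=O)[O-].[Na+]"),
                   c("CC(=O)[O-]", "[Na+]"))
  expect_identical(smilesComponents("CCO"), "CCO")
  expect_identical(aquatox:::smilesNetCharge("CC(=O)[O-]"), -1L)
  expect_identical(aquatox:::smilesNetCharge("[Mg+2]"), 2L)
  expect_identical(aquatox:::smilesNetCharge("CCO"), 0L)
})

test_that("standardization strips counter-ions and neutralizes charges", {
  r <- standardizeStructure("CC(=O)[O-].[Na+]")
  expect_setequal(r$flags, c("salt_stripped", "neutralized"))
  expect_false(grepl("Na", r$neutralized_smiles))
  expect_false(grepl("-", r$neutralized_smiles, fixed = TRUE))

  r2 <- standardizeStructure("CCO")
  expect_identical(r2$neutralized_smiles, "CCO")
  expect_length(r2$flags, 0L)

  expect_error(standardizeStructure("C1CC1C("),
               class = "aquatox_parse_error")

  # zwitterion: neutralized in place, nothing stripped
  r3 <- standardizeStructure("[NH3+]CC(=O)[O-]")
  expect_identical(r3$flags, "neutralized")
  expect_false(grepl("+", r3$neutralized_smiles, fixed = TRUE))

  # algal mode: ionized form retained
  r4 <- standardizeStructure("[O-]c1ccccc1.[Na+]", neutralize = FALSE)
  expect_identical(r4$flags, "salt_stripped")
  expect_true(grepl("[O-]", r4$neutralized_smiles, fixed = TRUE))
})

test_that("structural exclusion taxonomy is deterministic and complete", {
  expect_identical(classifyStructure("[Na+].[Cl-]")$reason, "inorganic")
  expect_true(classifyStructure("CCO")$keep)
  expect_identical(classifyStructure("CCO.CCCCO")$reason, "mixture")
  expect_identical(classifyStructure("CC[Sn](CC)CC")$reason, "metal_complex")
  expect_identical(classifyStructure("O=S(=O)(O)O")$reason, "inorganic")
  expect_identical(classifyStructure("CCO",
                                     metadata = list(uvcb = TRUE))$reason,
                   "uvcb")
  expect_identical(
    classifyStructure("CCO", metadata = list(isomer_mixture = TRUE))$reason,
    "isomer_mixture")
  # repeated calls agree
  expect_identical(classifyStructure("CC[Sn](CC)CC"),
                   classifyStructure("CC[Sn](CC)CC"))
})

test_that("microspecies screen follows Henderson-Hasselbalch on plugin pKa", {
  expect_identical(microspeciesPhScreen("CCO"), "stable")
  # acetic acid: pKa 4.2, anionic at both pH 7.5 and 8.1
  expect_identical(microspeciesPhScreen("CC(=O)O"), "stable")
  # a phenol assigned pKa 7.8 crosses between the two media
  tbl <- defaultPkaTable()
  tbl$pka[tbl$group == "phenol"] <- 7.8
  expect_identical(microspeciesPhScreen("Oc1ccccc1", pkaTable = tbl),
                   "unstable")
  # default phenol pKa 9.9: protonated at both pH
  expect_identical(microspeciesPhScreen("Oc1ccccc1"), "stable")
  # plugin failure policy
  expect_identical(microspeciesPhScreen("not_a_smiles"), "unknown")
  expect_identical(microspeciesPhScreen("not_a_smiles",
                                        onFailure = "stable"), "stable")
})
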