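test_that("salt stripping keeps the dominant fragment and counts removals", {
  res <- strip_to_parent(c("CC(=O)O.[Na+]", "c1ccccc1", "C1CC1.Cl.Cl"))
  expect_equal(canonical_smiles(res$parent_smiles[1]), canonical_smiles("CC(=O)O"))
  expect_equal(res$n_fragments_removed[1], 1L)
  expect_equal(canonical_smiles(res$parent_smiles[2]), canonical_smiles("c1ccccc1"))
  expect_equal(res$n_fragments_removed[2], 0L)
  expect_equal(canonical_smiles(res$parent_smiles[3]), canonical_smiles("C1CC1"))
  # fragment-count oracle: dots in the input SMILES
  expect_equal(res$n_fragments_removed[3],
               lengths(strsplit("C1CC1.Cl.Cl", ".", fixed = TRUE)) - 1L)
})

test_that("unparseable and missing SMILES are rejected with reason codes, never dropped silently", {
  res <- standardize_compounds(data.frame(
    compound_id = c("a", "b", "c", "d"),
    smiles = c("C1CC", "   ", "not_a_smiles!!", "CCO")))
  expect_equal(sort(res$rejects$compound_id), c("a", "b", "c"))
  expect_true(all(res$rejects$reason %in% c("unparseable_smiles", "missing_smiles")))
  expect_equal(res$rejects$reason[res$rejects$compound_id == "b"], "missing_smiles")
  expect_equal(res$std$compound_id, "d")
  expect_equal(nrow(res$std) + nrow(res$rejects), 4L)
})

test_that("pH 7.4 ionization follows the documented rule table", {
  skip_if_not_installed("ChemmineR")
  has_group <- function(smi, smarts) {
    sdf <- ChemmineR::smiles2sdf(smi)
    as.integer(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE)) > 0
  }
  # deprotonated: carboxylic and sulfonic acids
  expect_true(has_group(ionize_ph74("CC(=O)O"), "[CX3](=O)[O-]"))
  expect_true(has_group(ionize_ph74("CCS(=O)(=O)O"), "S(=O)(=O)[O-]"))
  # protonated: aliphatic amine, amidine, guanidine
  expect_true(has_group(ionize_ph74("CCN"), "[NX4+]"))
  expect_true(has_group(ionize_ph74("CC(N)=N"), "[#7+]"))
  expect_true(has_group(ionize_ph74("NC(N)=N"), "[#7+]"))
  # neutral: aniline, amide, aromatic N-heterocycle, plain benzene
  expect_equal(ionize_ph74("Nc1ccccc1"), canonical_smiles("Nc1ccccc1"))
  expect_equal(ionize_ph74("CC(=O)N"), canonical_smiles("CC(=O)N"))
  expect_equal(ionize_ph74("c1ccncc1"), canonical_smiles("c1ccncc1"))
  expect_equal(ionize_ph74("c1ccccc1"), canonical_smiles("c1ccccc1"))
})

test_that("ionization is idempotent", {
  smis <- c("CC(=O)O", "CCN", "c1ccccc1", "NC(N)=N", "CCS(=O)(=O)O",
            "Cc1ccc(CCN)cc1C(=O)O")
  once <- ionize_ph74(smis)
  expect_identical(ionize_ph74(once), once)
})

test_that("std keys identify equivalent structures and separate distinct ones", {
  pairs <- list(c("OCC", "CCO"),
                c("c1ccccc1O", "Oc1ccccc1"),
                c("CC(N)C", "CC(C)N"),
                c("C(F)(F)F", "FC(F)F"),
                c("CC(=O)[O-]", "CC(=O)O"),
                c("c1ccc(cc1)C(=O)NC", "CNC(=O)c1ccccc1"))
  k1 <- make_std_key(vapply(pairs, `[`, "", 1L))
  k2 <- make_std_key(vapply(pairs, `[`, "", 2L))
  expect_identical(k1, k2)
  expect_equal(anyDuplicated(k1), 0L)  # no cross-collisions
})

test_that("standardization is deterministic and idempotent", {
  lib <- fx_library()
  smis <- lib$smiles[1:25]
  df <- data.frame(compound_id = paste0("c", 1:25), smiles = smis)
  a <- standardize_compounds(df)
  b <- standardize_compounds(df)
  expect_identical(a, b)
  # idempotence: standardizing a std_key reproduces it
  df2 <- data.frame(compound_id = paste0("c", 1:25), smiles = a$std$std_key)
  c2 <- standardize_compounds(df2)
  expect_identical(c2$std$std_key, a$std$std_key)
  # single-fragment postcondition
  expect_false(any(grepl(".", a$std$parent_smiles, fixed = TRUE)))
})

test_that("compound readers parse csv, smi and sdf inputs", {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = c("m1", "m2"), smi = c("CCO", "c1ccccc1")),
                   csv, row.names = FALSE)
  df <- read_compounds(csv, "csv", col_id = "id", col_smiles = "smi")
  expect_equal(df$smiles, c("CCO", "c1ccccc1"))
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO m1", "c1ccccc1 m2"), smi)
  expect_equal(read_compounds(smi, "smi")$compound_id, c("m1", "m2"))
  sdf <- tempfile(fileext = ".sdf")
  system2("obabel", c(smi, "-osdf", "-O", sdf), stdout = FALSE, stderr = FALSE)
  df3 <- read_compounds(sdf, "sdf")
  expect_equal(canonical_smiles(df3$smiles), canonical_smiles(c("CCO", "c1ccccc1")))
})
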