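small_catalogue <- function(descriptors = c("MolWt", "HeavyAtomCount",
                                            "NumHDonors"),
                            fingerprints = list()) {
  list(name = "test2d", version = "test", descriptors = descriptors,
       fingerprints = fingerprints)
}

test_that("counting descriptors behave like counts and rows are deterministic", {
  lig <- ligand_tbl(c("methane", "ethane", "ethane2"), c("C", "CC", "CC"))
  blk <- compute_2d3d(lig, small_catalogue())
  m <- blk$matrix
  expect_equal(m["ethane", "HeavyAtomCount"] - m["methane", "HeavyAtomCount"],
               1)
  # identical molecules featurize identically
  expect_equal(m["ethane", ], m["ethane2", ])
})

test_that("molecular weight column matches independently summed atomic masses", {
  lig <- ligand_tbl(c("methane", "ethanol", "benzene", "water", "acetic"),
                    c("C", "CCO", "c1ccccc1", "O", "CC(=O)O"))
  blk <- compute_2d3d(lig, small_catalogue())
  # hand-computed from atomic masses C 12.011, H 1.008, O 15.999
  expect_equal(unname(blk$matrix[, "MolWt"]),
               c(16.043, 46.069, 78.114, 18.015, 60.052), tolerance = 1e-3)
})

test_that("columns non-finite for any ligand are dropped and recorded", {
  lig <- ligand_tbl(c("na", "ethane"), c("[Na+]", "CC"))
  cat <- small_catalogue(c("MolWt", "BCUT2D_MWHI"))
  expect_message(blk <- compute_2d3d(lig, cat), "dropped")
  expect_false("BCUT2D_MWHI" %in% colnames(blk$matrix))
  expect_true("BCUT2D_MWHI" %in% blk$dropped_features)
  expect_true("MolWt" %in% colnames(blk$matrix))
})

test_that("unparseable SMILES is a hard error naming the ligand", {
  lig <- ligand_tbl("bad", "C(C")
  expect_error(compute_2d3d(lig, small_catalogue()), "bad")
})

test_that("fingerprint columns fold to the declared bit lengths", {
  lig <- ligand_tbl(c("a", "b"), c("CCO", "c1ccccc1"))
  blk <- compute_2d3d(lig, small_catalogue(
    "MolWt", list(list(name = "morgan", radius = 2, n_bits = 64))))
  expect_equal(ncol(blk$matrix), 1 + 64)
  expect_true(all(blk$matrix[, -1] %in% c(0, 1)))
})

test_that("R-group blocks featurize the substructure, not the whole ligand", {
  lig <- ligand_tbl(c("a", "b"), c("Cc1ccncc1", "CCc1ccncc1"),
                    rgroup_smiles = c("C", "CC"))
  blk <- rgroup_block(lig, small_catalogue())
  expect_equal(blk$matrix[, "HeavyAtomCount"], c(a = 1, b = 2))
  lig$rgroup_smiles <- NA_character_
  expect_error(rgroup_block(lig, small_catalogue()), "rgroup_smiles")
})

test_that("packaged fixture molecules parse, contain the core and carry coords", {
  fix <- fixture_molecules()
  expect_equal(nrow(fix), 20L)
  expect_true(all(nzchar(smiles_canonicalize(fix$smiles))))
  match <- run_chem_op("substructure", query = attr(fix, "core"),
                       smiles = as.list(fix$smiles))
  expect_true(all(unlist(match$match)))
  atoms <- read_sdf_atoms(attr(fix, "sdf_path"))
  expect_setequal(unique(atoms$ligand_id), fix$ligand_id)
})

test_that("external feature blocks are reordered to library order", {
  lib <- ligand_tbl(c("a", "b", "c"), c("C", "CC", "CCC"))
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(ligand_id = c("c", "a", "b"),
                                  f1 = c(3, 1, 2), f2 = c(30, 10, 20)), csv)
  blk <- attach_external_block(csv, "external:PLEC", lib)
  expect_equal(unname(blk$matrix[, "f1"]), c(1, 2, 3))
  expect_equal(block_ids(blk), c("a", "b", "c"))
})

test_that("external blocks error on missing ligands and warn on extras", {
  lib <- ligand_tbl(c("a", "b"), c("C", "CC"))
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(ligand_id = "a", f1 = 1), csv)
  expect_error(attach_external_block(csv, "x", lib), "b")
  readr::write_csv(tibble::tibble(ligand_id = c("a", "b", "zz"),
                                  f1 = 1:3), csv)
  expect_warning(blk <- attach_external_block(csv, "x", lib), "ignored")
  expect_equal(nrow(blk$matrix), 2L)
})

test_that("standardization is fitted on the declared set only and inverts", {
  m <- cbind(shifted = c(rep(0, 5), rep(10, 5)), const = rep(3, 10),
             spread = 1:10)
  blk <- feature_block(m, sprintf("l%02d", 1:10))
  fit_ids <- sprintf("l%02d", 1:5)
  std <- standardize_block(blk, fit_ids)
  fit_rows <- std$matrix[fit_ids, ]
  expect_lt(max(abs(colMeans(fit_rows)[c("shifted", "spread")])), 1e-8)
  expect_equal(unname(apply(fit_rows, 2, sd)[c("spread")]), 1,
               tolerance = 1e-6)
  # constant column centered, left unscaled
  expect_equal(unname(std$matrix[, "const"]), rep(0, 10))
  # rows outside the fitting set are NOT zero mean: no leakage
  expect_gt(abs(mean(std$matrix[6:10, "shifted"])), 1)
  # round trip on the original scale
  back <- unstandardize_block(std)
  expect_equal(back$matrix, blk$matrix, tolerance = 1e-10)
})

test_that("feature blocks round-trip through their CSV dialect", {
  blk <- feature_block(matrix(rnorm(12), 4, dimnames = list(NULL,
                                                            c("a", "b", "c"))),
                       sprintf("l%d", 1:4), name = "latent")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_feature_block(blk, csv)
  back <- read_feature_block(csv, name = "latent")
  expect_equal(back$matrix, blk$matrix)
  expect_equal(block_ids(back), block_ids(blk))
})
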