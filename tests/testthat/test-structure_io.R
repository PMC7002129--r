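make_cofactor_model <- function() {
  # 3 CLA rings plus one fake carotenoid residue (two carbon atoms)
  toy <- build_toy_structure(list(
    placement(resno = 1, translation = c(0, 0, 0)),
    placement(resno = 2, translation = c(20, 0, 0)),
    placement(resno = 3, translation = c(40, 0, 0))))
  bcr <- data.frame(
    record_type = "HETATM", chain_id = "A", residue_name = "BCR",
    residue_number = 50L, insertion_code = "",
    atom_name = c("C1", "C2"), element = "C",
    x = c(60, 61.4), y = 0, z = 0, occupancy = 1, b_factor = 0,
    alt_loc = "", stringsAsFactors = FALSE)
  m <- toy$model
  m$atoms <- rbind(m$atoms, bcr)
  m
}

test_that("census classifies toy cofactors and ignores protein", {
  m <- make_cofactor_model()
  cen <- census(m)
  expect_identical(unname(cen[["CHL_A"]]), 3L)
  expect_identical(unname(cen[["CAROTENOID"]]), 1L)
  expect_identical(chlorophyll_total(cen), 3L)
  # protein residues never enter the cofactor census
  pep <- build_toy_peptide("SGT", chain = "P")
  cen2 <- census(combine_models(m, pep))
  expect_identical(as.integer(cen2), as.integer(cen))
})

test_that("census respects monomer chain selection and flags absent chains", {
  m <- make_cofactor_model()
  m2 <- m
  m2$atoms$chain_id[m2$atoms$residue_number == 3] <- "B"
  expect_identical(unname(census(m2, monomer_chains = "A")[["CHL_A"]]), 2L)
  expect_identical(unname(census(m2, monomer_chains = c("A", "B"))[["CHL_A"]]),
                   3L)
  expect_error(census(m2, monomer_chains = "Q"), "absent")
})

test_that("census is invariant to atom order and consistent chain renaming", {
  m <- make_cofactor_model()
  shuffled <- m
  set.seed(1)
  shuffled$atoms <- shuffled$atoms[sample(nrow(shuffled$atoms)), ]
  expect_identical(as.integer(census(shuffled)), as.integer(census(m)))
  renamed <- m
  renamed$atoms$chain_id <- "Q"
  expect_identical(as.integer(census(renamed, monomer_chains = "Q")),
                   as.integer(census(m, monomer_chains = "A")))
})

test_that("unknown chlorophyll-like ligand codes warn instead of silent OTHER", {
  expect_warning(out <- classify_residue("BCL"), "chlorophyll-like")
  expect_identical(out, "OTHER")
  expect_silent(expect_identical(classify_residue("XYZ"), "OTHER"))
  # and the table is user-extensible
  tab <- ligand_code_table(BCL = "CHL_A")
  expect_identical(unname(classify_residue("BCL", tab)), "CHL_A")
  expect_error(ligand_code_table(BCL = "NOT_A_TYPE"), "unknown pigment")
})

test_that("PDB read/write round trip preserves counts and coordinates", {
  m <- make_cofactor_model()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- quiet_read(f)
  expect_identical(nrow(m2$atoms), nrow(m$atoms))
  expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                    as.matrix(m$atoms[, c("x", "y", "z")]))), 1e-3)
  # idempotence: a second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, f2)
  m3 <- quiet_read(f2)
  expect_identical(m3$atoms[, c("x", "y", "z")],
                   m2$atoms[, c("x", "y", "z")])
})

test_that("per-residue scalar replaces B-factors, with sentinel for gaps", {
  m <- make_cofactor_model()
  keys <- unique(residue_keys(m))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f, per_residue_scalar = setNames(rep(0.5, length(keys)),
                                                      keys))
  m2 <- quiet_read(f)
  expect_true(all(m2$atoms$b_factor == 0.5))
  expect_warning(
    write_structure(m, f, per_residue_scalar = setNames(0.5, keys[1])),
    "missing")
  m3 <- quiet_read(f)
  expect_true(all(m3$atoms$b_factor %in% c(0, 0.5)))
  # clamping
  write_structure(m, f, per_residue_scalar = setNames(
    rep(1e6, length(keys)), keys))
  expect_true(all(quiet_read(f)$atoms$b_factor <= 999.99))
})

test_that("empty and malformed files are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), f)
  expect_error(quiet_read(f), "zero atoms|unreadable")
  expect_error(quiet_read(tempfile()), "not found")
})

test_that("mmCIF atom_site records parse equivalently to PDB", {
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_toy", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "HETATM 1 MG MG . CLA A 101 ? 1.500 -2.250 3.000 1.00 20.00",
    "HETATM 2 C C1 . CLA A 101 ? 2.500 -1.250 3.125 1.00 20.00",
    "ATOM   3 N N  . SER A 1   ? 0.000 0.000 0.000 0.50 10.00",
    "#"), cif)
  m <- quiet_read(cif)
  expect_identical(m$source_format, "mmcif")
  expect_identical(nrow(m$atoms), 3L)
  expect_identical(m$atoms$element[1], "Mg")
  expect_equal(m$atoms$x, c(1.5, 2.5, 0))
  expect_identical(unname(census(m)[["CHL_A"]]), 1L)
})

test_that("alternate locations keep the highest-occupancy copy", {
  a <- data.frame(
    record_type = "HETATM", chain_id = "A", residue_name = "CLA",
    residue_number = 1L, insertion_code = "",
    atom_name = "MG", element = "Mg",
    x = c(0, 5), y = 0, z = 0, occupancy = c(0.4, 0.6),
    b_factor = 0, alt_loc = c("A", "B"), stringsAsFactors = FALSE)
  kept <- chlfsites:::apply_altloc_policy(a)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$x, 5)
  # occupancy tie: alphabetical alt-loc wins
  a$occupancy <- c(0.5, 0.5)
  expect_identical(chlfsites:::apply_altloc_policy(a)$alt_loc, "A")
})
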