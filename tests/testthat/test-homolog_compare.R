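test_that("Kabsch recovers planted rigid transforms", {
  set.seed(7)
  X <- matrix(rnorm(60, sd = 5), 20, 3)
  expect_lte(kabsch_superpose(X, X)$rmsd, 1e-12)
  expect_equal(kabsch_superpose(X, X)$rotation, diag(3),
               tolerance = 1e-9)
  R <- rotation_about_axis(c(0, 0, 1), 90)
  Y <- sweep(X %*% t(R), 2, c(4, -2, 9), "+")
  sup <- kabsch_superpose(X, Y)
  expect_lte(sup$rmsd, 1e-9)
  expect_equal(sup$rotation, R, tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-12)
})

test_that("Kabsch rmsd equals directly evaluated post-fit residuals", {
  set.seed(8)
  X <- matrix(rnorm(300, sd = 8), 100, 3)
  R <- rotation_about_axis(c(1, -1, 2), 37)
  Y <- sweep(X %*% t(R), 2, c(1, 2, 3), "+") + matrix(rnorm(300, sd = 0.1),
                                                      100, 3)
  sup <- kabsch_superpose(X, Y)
  fitted <- apply_superposition(X, sup)
  rmsd_direct <- sqrt(mean(rowSums((fitted - Y)^2)))
  expect_equal(sup$rmsd, rmsd_direct, tolerance = 1e-12)
  # rmsd invariant under rigid pre-transformation of the query
  X2 <- sweep(X %*% t(rotation_about_axis(c(3, 1, 0), 140)), 2,
              c(-20, 5, 7), "+")
  expect_equal(kabsch_superpose(X2, Y)$rmsd, sup$rmsd, tolerance = 1e-9)
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), ">= 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               "differ in length")
})

test_that("site matching classifies conserved, lost and gained pigments", {
  tr <- matrix(c(0, 0, 0, 20, 0, 0, 40, 0, 0), 3, 3, byrow = TRUE)
  ref <- toy_chl_model(tr, start_resno = 1118L)
  expect_identical(unique(match_pigment_sites(ref, ref)$status),
                   "conserved")
  expect_true(all(match_pigment_sites(ref, ref)$mg_displacement < 1e-9))
  # delete one pigment from the query copy
  del <- ref
  del$atoms <- del$atoms[del$atoms$residue_number != 1119, ]
  mp <- match_pigment_sites(del, ref)
  expect_identical(sum(mp$status == "lost"), 1L)
  expect_identical(mp$reference_site[mp$status == "lost"], "A:1119:")
  # add a pigment 10 A from anything
  add <- combine_models(ref, toy_chl_model(matrix(c(0, 10, 0), 1),
                                           start_resno = 500L))
  mp2 <- match_pigment_sites(add, ref)
  expect_identical(sum(mp2$status == "gained"), 1L)
  expect_identical(mp2$query_site[mp2$status == "gained"], "A:500:")
})

test_that("greedy matching equals exhaustive optimal matching", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(3:6, 1)
    tr <- cbind(20 * seq_len(n), runif(n, -3, 3), runif(n, -3, 3))
    ref <- toy_chl_model(tr, start_resno = 1L)
    # jitter each site within the cutoff, drop one, gain one
    trq <- tr + matrix(runif(3 * n, -0.4, 0.4), n, 3)
    qry <- toy_chl_model(trq[-1, , drop = FALSE], start_resno = 101L)
    qry <- combine_models(qry, toy_chl_model(matrix(c(10, 15, 0), 1),
                                             start_resno = 300L))
    mp <- match_pigment_sites(qry, ref)
    qchl <- chlorophyll_residues(qry); rchl <- chlorophyll_residues(ref)
    qmg <- chlfsites:::mg_positions(qry, qchl)
    rmg <- chlfsites:::mg_positions(ref, rchl)
    oracle <- oracle_best_matching(oracle_pair_dists(qmg, rmg), 2.5)
    cons <- mp[mp$status == "conserved", ]
    expect_identical(nrow(cons), oracle$count)
    got <- sort(paste(cons$query_site, cons$reference_site))
    want <- sort(paste(qchl$key[oracle$pairs$q], rchl$key[oracle$pairs$r]))
    expect_identical(got, want)
  }
})

test_that("site labels follow the reference-numbering convention", {
  ref <- toy_chl_model(matrix(c(0, 0, 0, 20, 0, 0), 2, 3, byrow = TRUE),
                       start_resno = 1120L)  # residues 1120, 1121
  ref$atoms$residue_number[ref$atoms$residue_number == 1121] <- 1402L
  qry <- combine_models(ref, toy_chl_model(matrix(c(40, 0, 0), 1),
                                           start_resno = 77L))
  lab <- transfer_site_labels(match_pigment_sites(qry, ref))
  expect_identical(lab$label[lab$query_site == "A:1120:"], "A20")
  expect_identical(lab$label[lab$query_site == "A:1402:"], "A02")
  expect_identical(lab$label[lab$query_site == "A:77:"], "Anew1")
})

test_that("axial-ligand changes across conserved sites are detected", {
  mk <- function(axial) build_toy_structure(list(placement(
    resno = 1, axial = axial)))$model
  his <- list(residue_name = "HIS", atom_name = "NE2", distance = 2.15)
  ref <- mk(his)
  expect_false(any(compare_axial_ligands(
    match_pigment_sites(ref, ref), ref, ref)$changed))
  # His removed in the query
  qry <- mk(NULL)
  chg <- compare_axial_ligands(match_pigment_sites(qry, ref), qry, ref)
  expect_identical(chg$query_class, "none")
  expect_identical(chg$reference_class, "HIS_SIDECHAIN")
  expect_true(chg$changed)
  # phosphatidylglycerol headgroup coordination is representable
  lhg <- mk(list(residue_name = "LHG", atom_name = "O1", distance = 2.6))
  chg2 <- compare_axial_ligands(match_pigment_sites(lhg, ref), lhg, ref)
  expect_identical(chg2$query_class, "LIPID_HEADGROUP")
  expect_true(chg2$changed)
})

test_that("Calpha pairing drives superposition of homolog models", {
  pep <- build_toy_peptide("ACDEFGHIKLMNPQRSTVWY", chain = "A")
  R <- rotation_about_axis(c(1, 1, 0), 65)
  moved <- transform_model(pep, R, c(5, -8, 2))
  moved$atoms$chain_id <- "Q"  # paralog chain name differs
  pc <- paired_ca_coords(moved, pep, chain_pairing = c(Q = "A"))
  expect_identical(nrow(pc$query), 20L)
  sup <- kabsch_superpose(pc$query, pc$reference)
  expect_lte(sup$rmsd, 1e-9)
})

test_that("site-change flags capture gains, axial changes and lost neighbours", {
  tr <- matrix(c(0, 0, 0, 0, 0, 6, 40, 0, 0), 3, 3, byrow = TRUE)
  ref <- toy_chl_model(tr, start_resno = 1L)
  # query: site 2 lost, a new site gained far away, all else unchanged
  qry <- combine_models(
    toy_chl_model(tr[c(1, 3), , drop = FALSE], start_resno = 101L),
    toy_chl_model(matrix(c(80, 0, 0), 1), start_resno = 300L))
  mp <- match_pigment_sites(qry, ref)
  ax <- compare_axial_ligands(mp, qry, ref)
  fl <- derive_site_change_flags(mp, ax, qry, ref)
  expect_true(fl[["A:101:"]])    # its neighbour (6 A away) was lost
  expect_false(fl[["A:102:"]])   # nothing changed within 10 A
  expect_true(fl[["A:300:"]])    # gained: reference lacks the site
})
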