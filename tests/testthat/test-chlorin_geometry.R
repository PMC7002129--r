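base_model <- function(...) build_toy_structure(list(...))$model

test_that("ring mapping tolerates missing nitrogens but not missing MG", {
  m <- base_model(placement(resno = 1))
  drop_atom <- function(model, name) {
    model$atoms <- model$atoms[model$atoms$atom_name != name, ]
    model
  }
  expect_warning(ring <- map_ring_atoms(drop_atom(m, "N21"), "A:1:"),
                 "unmapped")
  expect_false("N21" %in% rownames(ring$positions))
  expect_lte(fit_plane(ring)$rms, 1e-9)
  expect_error(map_ring_atoms(drop_atom(m, "MG"), "A:1:"), "MG")
  # >4 unmapped macrocycle atoms is fatal
  m5 <- m
  m5$atoms <- m5$atoms[!m5$atoms$atom_name %in%
                         c("N21", "N22", "N23", "N24", "C10"), ]
  expect_error(map_ring_atoms(m5, "A:1:"), "unmapped")
})

test_that("ring bond lengths outside the covalent envelope are rejected", {
  m <- base_model(placement(resno = 1))
  m$atoms[, c("x", "y", "z")] <- m$atoms[, c("x", "y", "z")] * 1.3
  expect_error(map_ring_atoms(m, "A:1:"), "ring bond")
})

test_that("plane fit is rigid-motion invariant and matches a direct oracle", {
  m <- base_model(placement(resno = 1))
  ring <- map_ring_atoms(m, "A:1:")
  # displace one atom 0.5 A along the normal
  i <- which(m$atoms$atom_name == "C5")
  m$atoms$z[i] <- m$atoms$z[i] + 0.5
  ring2 <- map_ring_atoms(m, "A:1:")
  pl <- fit_plane(ring2)
  xyz <- ring2$positions[rownames(ring2$positions) != "MG", ]
  expect_equal(pl$rms, oracle_plane_rms(xyz, pl$normal, pl$centroid),
               tolerance = 1e-12)
  expect_gt(pl$rms, 0.05)
  # rigid motion leaves the rms unchanged
  R <- rotation_about_axis(c(1, 2, 3), 77)
  mt <- transform_model(m, R, c(10, -4, 2))
  expect_equal(fit_plane(map_ring_atoms(mt, "A:1:"))$rms, pl$rms,
               tolerance = 1e-9)
  expect_error(fit_plane(matrix(0, 2, 3)), ">= 3")
})

test_that("interplane angles fold into [0, 90] and recover planted rotations", {
  expect_equal(interplane_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  # normals 150 degrees apart fold to 30
  n2 <- c(sin(150 * pi / 180), 0, cos(150 * pi / 180))
  expect_equal(interplane_angle(c(0, 0, 1), n2), 30, tolerance = 1e-9)
  m <- base_model(
    placement(resno = 1),
    placement(resno = 2, translation = c(0, 0, 7),
              rotation = list(axis = c(1, 0, 0), angle_deg = 25)))
  p1 <- fit_plane(map_ring_atoms(m, "A:1:"))
  p2 <- fit_plane(map_ring_atoms(m, "A:2:"))
  expect_equal(interplane_angle(p1, p2), 25, tolerance = 1e-6)
  expect_identical(interplane_angle(p1, p2), interplane_angle(p2, p1))
  # property: random rotations always land in [0, 90]
  set.seed(4)
  for (k in 1:20) {
    pl <- fit_plane(ring_coords_of(m, "A:1:") %*%
                      t(rotation_about_axis(rnorm(3), runif(1, 0, 360))))
    ang <- interplane_angle(p1, pl)
    expect_gte(ang, 0); expect_lte(ang, 90)
  }
})

test_that("C2 substituent location demands a unique covalent neighbour", {
  m <- base_model(placement(resno = 1))
  ring <- map_ring_atoms(m, "A:1:")
  sub <- locate_c2_substituent(ring)
  expect_identical(sub$atom_name, "C21")
  expect_equal(attr(sub, "bond_length"), 1.5, tolerance = 1e-12)
  m_del <- m; m_del$atoms <- m_del$atoms[m_del$atoms$atom_name != "C21", ]
  expect_error(locate_c2_substituent(map_ring_atoms(m_del, "A:1:")),
               "no substituent")
  # second heavy atom planted 1.5 A from C2 makes the call ambiguous
  c2 <- as.numeric(m$atoms[m$atoms$atom_name == "C2", c("x", "y", "z")])
  extra <- m$atoms[m$atoms$atom_name == "C21", ]
  extra$atom_name <- "C22"
  extra[, c("x", "y", "z")] <- c2 + c(0, 0, 1.5)
  m_amb <- m; m_amb$atoms <- rbind(m_amb$atoms, extra)
  expect_error(locate_c2_substituent(map_ring_atoms(m_amb, "A:1:")),
               "ambiguous")
})

test_that("stacking multimers obey the Mg cutoff and label components", {
  m2 <- base_model(placement(resno = 1),
                   placement(resno = 2, translation = c(0, 0, 6)))
  st <- find_stacking_multimers(m2)
  expect_identical(nrow(st$pairs), 1L)
  expect_equal(st$pairs$mg_dist, 6, tolerance = 1e-9)
  expect_lt(st$pairs$angle_deg, 1e-6)
  expect_identical(sort(unique(st$components$size)), 2L)
  m_far <- base_model(placement(resno = 1),
                      placement(resno = 2, translation = c(0, 0, 12)))
  expect_identical(nrow(find_stacking_multimers(m_far)$pairs), 0L)
  # chain of three at 6 A spacing forms one trimer component
  m3 <- base_model(placement(resno = 1),
                   placement(resno = 2, translation = c(0, 0, 6)),
                   placement(resno = 3, translation = c(0, 0, 12)))
  st3 <- find_stacking_multimers(m3)
  expect_identical(nrow(st3$pairs), 2L)
  expect_identical(unique(st3$components$size), 3L)
  # invariance to atom enumeration order
  shuf <- m3; set.seed(2); shuf$atoms <- shuf$atoms[sample(nrow(shuf$atoms)), ]
  expect_identical(find_stacking_multimers(shuf)$pairs, st3$pairs)
})

test_that("axial ligand detection classifies and sorts by distance", {
  m <- base_model(placement(
    resno = 1, axial = list(residue_name = "HIS", atom_name = "NE2",
                            distance = 2.15)))
  lig <- detect_axial_ligands(m, "A:1:")
  expect_identical(nrow(lig), 1L)
  expect_identical(lig$class, "HIS_SIDECHAIN")
  expect_equal(lig$distance, 2.15, tolerance = 1e-9)
  # water and lipid-headgroup classes
  mw <- base_model(placement(
    resno = 1, axial = list(residue_name = "HOH", atom_name = "O",
                            distance = 2.3)))
  expect_identical(detect_axial_ligands(mw, "A:1:")$class, "WATER")
  ml <- base_model(placement(
    resno = 1, axial = list(residue_name = "LHG", atom_name = "O1",
                            distance = 2.6)))
  expect_identical(detect_axial_ligands(ml, "A:1:")$class,
                   "LIPID_HEADGROUP")
  # nothing within the window -> empty
  m0 <- base_model(placement(resno = 1))
  expect_identical(nrow(detect_axial_ligands(m0, "A:1:")), 0L)
  # another chlorophyll's atoms are never axial ligands
  m2 <- base_model(placement(resno = 1),
                   placement(resno = 2, translation = c(0, 0, 2.8)))
  expect_identical(nrow(detect_axial_ligands(m2, "A:1:")), 0L)
})

test_that("formyl probe point matches independent vector arithmetic", {
  m <- base_model(placement(resno = 1, rotation = list(axis = c(2, 1, 1),
                                                       angle_deg = 40),
                            translation = c(3, -2, 5)))
  ring <- map_ring_atoms(m, "A:1:")
  cr <- c2_crowding(m, ring)
  c2 <- ring$positions["C2", ]
  sub <- as.numeric(locate_c2_substituent(ring)[1, c("x", "y", "z")])
  probe_oracle <- sub + 1.2 * (sub - c2) / sqrt(sum((sub - c2)^2))
  expect_equal(cr$probe_point, probe_oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(cr$n, 0L)
  # plant a clash exactly 2.0 A from the probe point
  clash <- m$atoms[1, ]
  clash$chain_id <- "Z"; clash$residue_number <- 999L
  clash$residue_name <- "ALA"; clash$atom_name <- "CB"
  clash[, c("x", "y", "z")] <- probe_oracle + c(0, 0, 2)
  mc <- m; mc$atoms <- rbind(mc$atoms, clash)
  cr2 <- c2_crowding(mc, map_ring_atoms(mc, "A:1:"))
  expect_identical(cr2$n, 1L)
  expect_equal(cr2$min_dist, 2.0, tolerance = 1e-9)
})

test_that("reported distances agree with a brute-force pairwise oracle", {
  tb <- build_toy_structure(list(
    placement(resno = 1,
              donors = list(list(residue_name = "SER", atom_name = "OG",
                                 distance = 3.0, direction = c(0, 1, 1))),
              axial = list(residue_name = "HIS", atom_name = "NE2",
                           distance = 2.4)),
    placement(resno = 2, translation = c(0, 5, 5),
              rotation = list(axis = c(0, 1, 0), angle_deg = 30))))
  m <- tb$model
  ring <- map_ring_atoms(m, "A:1:")
  sub <- as.matrix(locate_c2_substituent(ring)[1, c("x", "y", "z")])
  probes <- m$atoms[m$atoms$chain_id == "Z", c("x", "y", "z")]
  od <- oracle_pair_dists(as.matrix(probes), sub)
  sc <- scan_c2_environment(m, "A:1:")
  expect_equal(sort(sc$donors$distance),
               sort(od[od >= 2.4 & od <= 3.5]), tolerance = 1e-12)
  mg <- as.matrix(m$atoms[m$atoms$atom_name == "MG" &
                            m$atoms$residue_number == 1, c("x", "y", "z")])
  oda <- oracle_pair_dists(as.matrix(probes), mg)
  lig <- detect_axial_ligands(m, "A:1:")
  expect_equal(sort(lig$distance), sort(oda[oda >= 1.9 & oda <= 3.0]),
               tolerance = 1e-12)
})
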