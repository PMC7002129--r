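# Seeded generators for toy photosystem-like structures with full ground
# truth: idealized chlorin macrocycles placed rigidly in space, planted
# hydrogen-bond donors at exact distances, planted axial ligands, and toy
# peptide chains. These stand in for cryo-EM/x-ray depositions so every
# downstream operation can be scored offline.

DEFAULT_SEED <- 7521L

#' Idealized chlorin macrocycle template
#'
#' A planar 24-atom macrocycle (C1-C20 on a ring, N21-N24 inner) plus the
#' central MG and a single substituent carbon (C21) attached 1.50 A from
#' C2 -- the position where chlorophyll f carries its formyl group. The 20
#' ring carbons sit on a circle with consecutive spacing 1.45 A (within
#' the 1.33-1.55 A bond-length envelope); the template is exactly planar
#' so plane-fit residuals are analytically zero.
#'
#' @return Data frame: `atom_name`, `element`, `x`, `y`, `z`.
#' @export
ideal_chlorin_template <- function() {
  bond <- 1.45
  r_c <- bond / (2 * sin(pi / 20))
  ang_c <- (0:19) * (2 * pi / 20)
  carbons <- data.frame(atom_name = paste0("C", 1:20), element = "C",
                        x = r_c * cos(ang_c), y = r_c * sin(ang_c), z = 0,
                        stringsAsFactors = FALSE)
  ang_n <- (c(1.5, 6.5, 11.5, 16.5)) * (2 * pi / 20)
  nitro <- data.frame(atom_name = paste0("N", 21:24), element = "N",
                      x = 2.05 * cos(ang_n), y = 2.05 * sin(ang_n), z = 0,
                      stringsAsFactors = FALSE)
  mg <- data.frame(atom_name = "MG", element = "Mg", x = 0, y = 0, z = 0,
                   stringsAsFactors = FALSE)
  sub_ang <- ang_c[2]  # C2 direction
  sub <- data.frame(atom_name = "C21", element = "C",
                    x = (r_c + 1.50) * cos(sub_ang),
                    y = (r_c + 1.50) * sin(sub_ang), z = 0,
                    stringsAsFactors = FALSE)
  rbind(carbons, nitro, mg, sub)
}

#' Rotation matrix about an axis
#'
#' @param axis 3-vector (need not be unit length).
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

as_rotation <- function(rotation) {
  if (is.null(rotation)) return(diag(3))
  if (is.matrix(rotation)) {
    stopifnot(all(dim(rotation) == c(3, 3)))
    if (abs(det(rotation) - 1) > 1e-6 ||
        max(abs(crossprod(rotation) - diag(3))) > 1e-6)
      stop("rotation is not a proper rotation matrix")
    return(rotation)
  }
  rotation_about_axis(rotation$axis, rotation$angle_deg)
}

#' One pigment placement for [build_toy_structure()]
#'
#' @param chain Chain id of the pigment residue.
#' @param resno Residue number.
#' @param resname Residue code (default `CLA`).
#' @param rotation `NULL`, a 3x3 rotation matrix, or
#'   `list(axis=, angle_deg=)`.
#' @param translation 3-vector (A); this is where MG lands.
#' @param donors List of planted donor probes:
#'   `list(residue_name=, atom_name=, distance=, direction=)` with the
#'   direction in the template frame (rotated with the pigment); the probe
#'   atom is placed at exactly `distance` A from the C2-substituent atom.
#' @param axial Optional planted axial ligand
#'   `list(residue_name=, atom_name=, distance=, side=+1)`, placed along
#'   the ring normal at `distance` A from MG.
#' @return A placement spec (list).
#' @export
placement <- function(chain = "A", resno = 1L, resname = "CLA",
                      rotation = NULL, translation = c(0, 0, 0),
                      donors = list(), axial = NULL) {
  stopifnot(length(translation) == 3)
  for (d in donors)
    stopifnot(d$distance > 0, length(d$direction) == 3,
              sum(d$direction^2) > 0)
  if (!is.null(axial)) stopifnot(axial$distance > 0)
  list(chain = chain, resno = as.integer(resno), resname = resname,
       rotation = as_rotation(rotation), translation = translation,
       donors = donors, axial = axial)
}

#' Build a toy structure from placement specs
#'
#' Places rigid copies of the ideal chlorin template, plants donor and
#' axial-ligand probe atoms at exact distances, and returns the model
#' together with ground-truth tables (planted donor distances, axial
#' ligands, Mg-Mg stacking pairs and their connected components) so that
#' downstream operations can be scored without re-deriving geometry.
#' Probe atoms are emitted as single-atom residues on chain `Z`.
#'
#' @param placements List of [placement()] specs.
#' @param path Optional PDB output path.
#' @param mg_cutoff Mg-Mg cutoff (A) used for the ground-truth stacking
#'   pair list (default 9).
#' @return List: `model` (a `structure_model`), `truth` (list of
#'   `pigments`, `donors`, `axial`, `pairs`, `components` data frames).
#' @export
build_toy_structure <- function(placements, path = NULL, mg_cutoff = 9) {
  template <- ideal_chlorin_template()
  tcoord <- as.matrix(template[, c("x", "y", "z")])
  sub_idx <- which(template$atom_name == "C21")
  c2_idx <- which(template$atom_name == "C2")
  atoms <- list(); pig <- list(); don <- list(); axi <- list()
  probe_no <- 900L
  for (p in placements) {
    R <- p$rotation
    xyz <- tcoord %*% t(R)
    xyz <- sweep(xyz, 2, p$translation, "+")
    atoms[[length(atoms) + 1L]] <- data.frame(
      record_type = "HETATM", chain_id = p$chain, residue_name = p$resname,
      residue_number = p$resno, insertion_code = "",
      atom_name = template$atom_name, element = template$element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, b_factor = 0, alt_loc = "", stringsAsFactors = FALSE)
    key <- paste(p$chain, p$resno, "", sep = ":")
    normal <- R %*% c(0, 0, 1)
    pig[[length(pig) + 1L]] <- data.frame(
      key = key, chain_id = p$chain, residue_number = p$resno,
      residue_name = p$resname,
      mg_x = p$translation[1], mg_y = p$translation[2],
      mg_z = p$translation[3],
      nx = normal[1], ny = normal[2], nz = normal[3],
      stringsAsFactors = FALSE)
    sub_pos <- xyz[sub_idx, ]
    for (d in p$donors) {
      dir <- as.numeric(R %*% (d$direction / sqrt(sum(d$direction^2))))
      pos <- sub_pos + d$distance * dir
      probe_no <- probe_no + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        record_type = if (d$residue_name %in% AMINO3) "ATOM" else "HETATM",
        chain_id = "Z", residue_name = d$residue_name,
        residue_number = probe_no, insertion_code = "",
        atom_name = d$atom_name,
        element = element_from_name(d$atom_name, d$residue_name),
        x = pos[1], y = pos[2], z = pos[3],
        occupancy = 1, b_factor = 0, alt_loc = "",
        stringsAsFactors = FALSE)
      don[[length(don) + 1L]] <- data.frame(
        pigment = key, donor_key = paste("Z", probe_no, "", sep = ":"),
        residue_name = d$residue_name, atom_name = d$atom_name,
        distance = d$distance, stringsAsFactors = FALSE)
    }
    if (!is.null(p$axial)) {
      side <- if (is.null(p$axial$side)) 1 else sign(p$axial$side)
      pos <- p$translation + p$axial$distance * side * as.numeric(normal)
      probe_no <- probe_no + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        record_type = if (p$axial$residue_name %in% AMINO3) "ATOM"
                      else "HETATM",
        chain_id = "Z", residue_name = p$axial$residue_name,
        residue_number = probe_no, insertion_code = "",
        atom_name = p$axial$atom_name,
        element = element_from_name(p$axial$atom_name,
                                    p$axial$residue_name),
        x = pos[1], y = pos[2], z = pos[3],
        occupancy = 1, b_factor = 0, alt_loc = "",
        stringsAsFactors = FALSE)
      axi[[length(axi) + 1L]] <- data.frame(
        pigment = key, ligand_key = paste("Z", probe_no, "", sep = ":"),
        residue_name = p$axial$residue_name,
        atom_name = p$axial$atom_name,
        distance = p$axial$distance, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, atoms)
  pig <- do.call(rbind, pig)
  # overlap guard: pigment heavy atoms must not collide
  pmask <- atoms$chain_id != "Z"
  pid <- residue_keys(NULL, atoms)[pmask]
  xyz <- as.matrix(atoms[pmask, c("x", "y", "z")])
  if (length(unique(pid)) > 1) {
    dm <- as.matrix(stats::dist(xyz))
    same <- outer(pid, pid, "==")
    if (any(dm[!same] < 1.0))
      stop("overlapping placements: inter-pigment atom distance < 1 A")
  }
  mg <- as.matrix(pig[, c("mg_x", "mg_y", "mg_z")])
  pairs <- data.frame(site_a = character(), site_b = character(),
                      mg_dist = numeric())
  n <- nrow(pig)
  if (n > 1) {
    dm <- as.matrix(stats::dist(mg))
    idx <- which(upper.tri(dm) & dm <= mg_cutoff, arr.ind = TRUE)
    if (nrow(idx))
      pairs <- data.frame(site_a = pig$key[idx[, 1]],
                          site_b = pig$key[idx[, 2]],
                          mg_dist = dm[idx], stringsAsFactors = FALSE)
  }
  comp <- connected_components(pig$key, pairs[, c("site_a", "site_b")])
  model <- new_structure_model(atoms, "synthetic")
  if (!is.null(path)) write_structure(model, path)
  list(model = model,
       truth = list(pigments = pig,
                    donors = if (length(don)) do.call(rbind, don) else NULL,
                    axial = if (length(axi)) do.call(rbind, axi) else NULL,
                    pairs = pairs, components = comp))
}

# union-find over node labels given an edge table
connected_components <- function(nodes, edges) {
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    i <- find(match(edges[k, 1], nodes))
    j <- find(match(edges[k, 2], nodes))
    if (i != j) parent[j] <- i
  }
  root <- vapply(seq_along(nodes), find, 1L)
  comp_id <- match(root, unique(root))
  size <- as.integer(table(comp_id)[comp_id])
  data.frame(site = nodes, component = comp_id, size = size,
             stringsAsFactors = FALSE)
}

#' Random placement spec
#'
#' Draws `n_pigments` well-separated rigid placements (spacing large
#' relative to typical site-matching cutoffs) with randomized orientations
#' and, optionally, planted donors at randomized distances. Reproducible
#' from the seed.
#'
#' @param n_pigments Number of pigments.
#' @param seed RNG seed (default 7521).
#' @param spacing Minimum Mg-Mg spacing in A (default 20).
#' @param donor_distances Optional list (recycled over pigments) of donor
#'   distance vectors; `NULL` plants no donors.
#' @param donor_residue,donor_atom Probe identity (default Tyr OH).
#' @return List of [placement()] specs.
#' @export
random_placement_spec <- function(n_pigments = 3, seed = DEFAULT_SEED,
                                  spacing = 20, donor_distances = NULL,
                                  donor_residue = "TYR",
                                  donor_atom = "OH") {
  set.seed(seed)
  specs <- vector("list", n_pigments)
  for (i in seq_len(n_pigments)) {
    axis <- stats::rnorm(3)
    donors <- list()
    if (!is.null(donor_distances)) {
      dd <- donor_distances[[(i - 1) %% length(donor_distances) + 1]]
      for (d in dd)
        donors[[length(donors) + 1L]] <-
          list(residue_name = donor_residue, atom_name = donor_atom,
               distance = d, direction = stats::rnorm(3))
    }
    specs[[i]] <- placement(
      chain = "A", resno = 100L + i,
      rotation = list(axis = axis, angle_deg = stats::runif(1, 0, 360)),
      translation = c(i * spacing, stats::runif(1, -2, 2),
                      stats::runif(1, -2, 2)),
      donors = donors)
  }
  specs
}

# side-chain donor atom carried by each residue type, for toy peptides
SIDECHAIN_PROBE <- c(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                     GLN = "NE2", LYS = "NZ", ARG = "NE", HIS = "NE2")

#' Build a toy peptide chain
#'
#' An extended backbone (N, CA, C, O per residue, 3.8 A rise along x) with
#' a single representative side-chain donor atom for Ser/Thr/Tyr/Asn/Gln/
#' Lys/Arg/His. Used as a protein stand-in for donor enumeration,
#' conservation mapping and Calpha superposition.
#'
#' @param sequence One-letter amino acid string.
#' @param chain Chain id.
#' @param start First residue number.
#' @param origin 3-vector origin.
#' @param rise Per-residue translation along x (A).
#' @return A `structure_model`.
#' @export
build_toy_peptide <- function(sequence, chain = "A", start = 1L,
                              origin = c(0, 0, 0), rise = 3.8) {
  aa1 <- strsplit(toupper(sequence), "")[[1]]
  map1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  if (any(!aa1 %in% names(map1to3)))
    stop("illegal amino acid letter(s): ",
         paste(unique(aa1[!aa1 %in% names(map1to3)]), collapse = ""))
  rows <- list()
  for (i in seq_along(aa1)) {
    res3 <- map1to3[[aa1[i]]]
    resno <- start + i - 1L
    # mild helical twist keeps Calpha traces non-collinear
    base <- origin + c((i - 1) * rise, 1.5 * sin(i * 1.7),
                       1.5 * cos(i * 1.7))
    at <- rbind(
      data.frame(atom_name = "N",  element = "N", dx = 0.0, dy = 0, dz = 0),
      data.frame(atom_name = "CA", element = "C", dx = 1.2, dy = 0.6, dz = 0),
      data.frame(atom_name = "C",  element = "C", dx = 2.4, dy = 0, dz = 0),
      data.frame(atom_name = "O",  element = "O", dx = 2.4, dy = -1.2, dz = 0))
    if (res3 %in% names(SIDECHAIN_PROBE))
      at <- rbind(at, data.frame(atom_name = SIDECHAIN_PROBE[[res3]],
                                 element = substr(SIDECHAIN_PROBE[[res3]],
                                                  1, 1),
                                 dx = 1.2, dy = 2.1, dz = 0))
    rows[[i]] <- data.frame(
      record_type = "ATOM", chain_id = chain, residue_name = res3,
      residue_number = resno, insertion_code = "",
      atom_name = at$atom_name, element = at$element,
      x = base[1] + at$dx, y = base[2] + at$dy, z = base[3] + at$dz,
      occupancy = 1, b_factor = 0, alt_loc = "", stringsAsFactors = FALSE)
  }
  new_structure_model(do.call(rbind, rows), "synthetic")
}

#' Combine structure models
#'
#' @param ... `structure_model` objects.
#' @return A single `structure_model` with concatenated atoms.
#' @export
combine_models <- function(...) {
  models <- list(...)
  stopifnot(all(vapply(models, inherits, TRUE, "structure_model")))
  atoms <- do.call(rbind, lapply(models, function(m) m$atoms))
  new_structure_model(atoms, "synthetic")
}

#' Apply a rigid transform to a model
#'
#' @param model A `structure_model`.
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector.
#' @return Transformed `structure_model`.
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Random protein sequence
#'
#' @param n Length.
#' @param seed RNG seed.
#' @return One-letter amino acid string.
#' @export
random_protein_sequence <- function(n, seed = DEFAULT_SEED) {
  set.seed(seed)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

#' Substitute residues of a sequence at random positions
#'
#' Emulates paralog divergence: `n_substitutions` positions are replaced
#' by a different amino acid. Reproducible from the seed.
#'
#' @param sequence One-letter amino acid string.
#' @param n_substitutions Number of positions to mutate.
#' @param seed RNG seed.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(sequence, n_substitutions,
                            seed = DEFAULT_SEED) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(sequence, "")[[1]]
  stopifnot(n_substitutions <= length(ch))
  set.seed(seed)
  pos <- sample(length(ch), n_substitutions)
  for (p in pos) ch[p] <- sample(setdiff(aa, ch[p]), 1)
  paste(ch, collapse = "")
}
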