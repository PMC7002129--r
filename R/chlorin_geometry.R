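# Per-chlorophyll geometry: macrocycle mapping to IUPAC positions, ring
# plane fitting, C2-substituent location, stacked multimer detection,
# magnesium axial ligands and steric crowding at C2.

RING_POSITIONS <- c(paste0("C", 1:20), paste0("N", 21:24))

#' Ring atom-name tables
#'
#' Maps IUPAC macrocycle positions (C1..C20, N21..N24, MG) to atom names.
#' `"iupac"` is the naming used by the synthetic generator; `"pdb_chl"`
#' follows the PDB chemical-component convention for chlorophylls (rings
#' A-D as C1A..C4D, meso carbons CHA..CHD, pyrrole nitrogens NA..ND).
#'
#' @param style `"iupac"` or `"pdb_chl"`.
#' @return Named character vector: position -> atom name.
#' @export
ring_atom_table <- function(style = c("iupac", "pdb_chl")) {
  style <- match.arg(style)
  if (style == "iupac")
    return(setNames(c(RING_POSITIONS, "MG"), c(RING_POSITIONS, "MG")))
  setNames(
    c("C1A", "C2A", "C3A", "C4A", "CHB", "C1B", "C2B", "C3B", "C4B", "CHC",
      "C1C", "C2C", "C3C", "C4C", "CHD", "C1D", "C2D", "C3D", "C4D", "CHA",
      "NA", "NB", "NC", "ND", "MG"),
    c(RING_POSITIONS, "MG"))
}

#' Map a chlorophyll residue onto IUPAC ring positions
#'
#' Builds a `chlorin_ring`: the macrocycle heavy atoms keyed by IUPAC
#' position plus the full residue atom table (for substituent searches).
#' MG must be present and at least 20 of the 24 macrocycle positions must
#' map; consecutive mapped ring-carbon distances are validated against
#' the 1.2-1.7 A covalent envelope.
#'
#' @param model A `structure_model`.
#' @param key Residue key (see [residue_keys()]).
#' @param name_table A [ring_atom_table()], or `"auto"` to pick whichever
#'   style maps more atoms.
#' @return A `chlorin_ring` object.
#' @export
map_ring_atoms <- function(model, key, name_table = "auto") {
  at <- residue_atoms(model, key)
  if (nrow(at) == 0) stop("no atoms for residue ", key)
  if (identical(name_table, "auto")) {
    hits <- vapply(c("iupac", "pdb_chl"), function(s)
      sum(ring_atom_table(s) %in% at$atom_name), 1L)
    name_table <- ring_atom_table(names(which.max(hits)))
  }
  idx <- match(name_table, at$atom_name)
  mapped <- setNames(idx, names(name_table))
  if (is.na(mapped["MG"])) stop("MG missing in residue ", key)
  ring_idx <- mapped[RING_POSITIONS]
  n_unmapped <- sum(is.na(ring_idx))
  if (n_unmapped > 4)
    stop(n_unmapped, " of 24 macrocycle atoms unmapped in residue ", key)
  if (n_unmapped > 0)
    warning("residue ", key, ": ", n_unmapped,
            " macrocycle atom(s) unmapped; ring still valid")
  coords <- as.matrix(at[, c("x", "y", "z")])
  # covalent sanity along the C1..C20 cycle where both ends are mapped
  cpos <- mapped[paste0("C", 1:20)]
  for (i in 1:20) {
    j <- if (i == 20) 1 else i + 1
    if (!is.na(cpos[i]) && !is.na(cpos[j])) {
      d <- sqrt(sum((coords[cpos[i], ] - coords[cpos[j], ])^2))
      if (d < 1.2 || d > 1.7)
        stop(sprintf("residue %s: ring bond C%d-C%d is %.2f A (outside 1.2-1.7)",
                     key, i, j, d))
    }
  }
  ok <- !is.na(mapped)
  pos_coords <- coords[mapped[ok], , drop = FALSE]
  rownames(pos_coords) <- names(mapped)[ok]
  structure(list(key = key,
                 positions = pos_coords,
                 ring_atom_names = at$atom_name[mapped[ok]],
                 atoms = at),
            class = "chlorin_ring")
}

ring_coords <- function(ring) {
  ring$positions[rownames(ring$positions) %in% RING_POSITIONS, ,
                 drop = FALSE]
}

#' Least-squares ring plane
#'
#' Fits a plane through all mapped macrocycle heavy atoms (the
#' smallest-variance direction of the centered coordinates, via SVD) and
#' reports the rms out-of-plane deviation. Using all macrocycle atoms
#' rather than the four nitrogens makes the fit robust to missing atoms.
#'
#' @param ring A `chlorin_ring`, or an n x 3 coordinate matrix.
#' @return A `ring_plane`: list(`normal` unit 3-vector, `centroid`,
#'   `rms` in A).
#' @export
fit_plane <- function(ring) {
  xyz <- if (inherits(ring, "chlorin_ring")) ring_coords(ring)
         else as.matrix(ring)
  if (nrow(xyz) < 3) stop("plane fit needs >= 3 atoms")
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  sv <- svd(centered)
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  d <- as.numeric(centered %*% normal)
  structure(list(normal = normal, centroid = centroid,
                 rms = sqrt(mean(d^2))),
            class = "ring_plane")
}

#' Angle between two ring planes
#'
#' Folded into `[0, 90]` degrees (normal sign is arbitrary); symmetric in
#' its arguments.
#'
#' @param a,b `ring_plane` objects (or unit normals).
#' @return Angle in degrees.
#' @export
interplane_angle <- function(a, b) {
  na <- if (inherits(a, "ring_plane")) a$normal else a / sqrt(sum(a^2))
  nb <- if (inherits(b, "ring_plane")) b$normal else b / sqrt(sum(b^2))
  cosang <- abs(sum(na * nb))
  acos(pmin(1, cosang)) * 180 / pi
}

#' Locate the C2 substituent atom
#'
#' The unique non-ring heavy atom covalently attached to the C2 ring
#' carbon (within `bond_cutoff`, default 1.8 A -- a C-C bond is ~1.5 A).
#' For chlorophyll a this is the methyl carbon; for chlorophyll f it is
#' the formyl carbon.
#'
#' @param ring A `chlorin_ring` with C2 mapped.
#' @param bond_cutoff Covalent attachment cutoff (A).
#' @return One-row data frame (atom record) of the substituent atom.
#' @export
locate_c2_substituent <- function(ring, bond_cutoff = 1.8) {
  stopifnot(inherits(ring, "chlorin_ring"))
  if (!"C2" %in% rownames(ring$positions))
    stop("C2 not mapped in residue ", ring$key)
  c2 <- ring$positions["C2", ]
  at <- ring$atoms
  heavy <- at$element != "H" & !(at$atom_name %in% ring$ring_atom_names)
  cand <- at[heavy, , drop = FALSE]
  if (nrow(cand) == 0) stop("no substituent at C2 of ", ring$key)
  d <- sqrt((cand$x - c2[1])^2 + (cand$y - c2[2])^2 + (cand$z - c2[3])^2)
  hit <- which(d <= bond_cutoff)
  if (length(hit) == 0) stop("no substituent at C2 of ", ring$key)
  if (length(hit) > 1) stop("ambiguous C2 substituent of ", ring$key, ": ",
                            paste(cand$atom_name[hit], collapse = ", "))
  out <- cand[hit, , drop = FALSE]
  attr(out, "bond_length") <- unname(d[hit])
  out
}

#' Chlorophyll residues of a model
#'
#' @param model A `structure_model`.
#' @param table Ligand code table.
#' @return Residue table restricted to chlorophyll-type residues.
#' @export
chlorophyll_residues <- function(model, table = ligand_code_table()) {
  res <- residue_table(model)
  type <- suppressWarnings(classify_residue(res$residue_name, table))
  res$pigment_type <- type
  res[type %in% CHLOROPHYLL_TYPES, , drop = FALSE]
}

mg_positions <- function(model, chl) {
  a <- model$atoms
  key <- residue_keys(model)
  out <- matrix(NA_real_, nrow(chl), 3,
                dimnames = list(chl$key, c("x", "y", "z")))
  for (i in seq_len(nrow(chl))) {
    sel <- key == chl$key[i] & toupper(a$atom_name) == "MG"
    if (any(sel)) out[i, ] <- as.numeric(a[which(sel)[1], c("x", "y", "z")])
  }
  out
}

#' Find stacked chlorophyll multimers
#'
#' Emits a pair for every two chlorophylls whose Mg-Mg distance is within
#' `mg_cutoff`, annotated with the interplane angle and the minimum
#' ring-ring heavy-atom distance, and labels connected components
#' (monomer/dimer/trimer/...). Stacked, near-parallel pairs are the
#' low-energy "red" antenna candidates. There is no community-standard
#' numeric cutoff for "stacked"; the 9 A default captures adjacent-ring
#' pairs while excluding lattice neighbours, and is configurable.
#'
#' @param model A `structure_model`.
#' @param mg_cutoff Mg-Mg distance cutoff (A).
#' @param table Ligand code table.
#' @return List: `pairs` (site_a, site_b, mg_dist, angle_deg,
#'   min_ring_dist), `components` (site, component, size).
#' @export
find_stacking_multimers <- function(model, mg_cutoff = 9,
                                    table = ligand_code_table()) {
  chl <- chlorophyll_residues(model, table)
  if (nrow(chl) == 0) stop("no chlorophylls in model")
  chl <- chl[order(chl$key), , drop = FALSE]  # enumeration-order invariance
  mg <- mg_positions(model, chl)
  keep <- !is.na(mg[, 1])
  chl <- chl[keep, , drop = FALSE]; mg <- mg[keep, , drop = FALSE]
  rings <- lapply(chl$key, function(k) map_ring_atoms(model, k))
  planes <- lapply(rings, fit_plane)
  coords <- lapply(rings, ring_coords)
  pairs <- list()
  n <- nrow(chl)
  if (n > 1) {
    dm <- as.matrix(stats::dist(mg))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (dm[i, j] <= mg_cutoff) {
        cross <- sqrt(outer(rowSums(coords[[i]]^2), rowSums(coords[[j]]^2),
                            "+") - 2 * coords[[i]] %*% t(coords[[j]]))
        pairs[[length(pairs) + 1L]] <- data.frame(
          site_a = chl$key[i], site_b = chl$key[j], mg_dist = dm[i, j],
          angle_deg = interplane_angle(planes[[i]], planes[[j]]),
          min_ring_dist = min(cross), stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(site_a = character(), site_b = character(),
                           mg_dist = numeric(), angle_deg = numeric(),
                           min_ring_dist = numeric())
  comp <- connected_components(chl$key, pairs[, c("site_a", "site_b")])
  list(pairs = pairs, components = comp)
}

AXIAL_CLASSES <- c("HIS_SIDECHAIN", "WATER", "BACKBONE_CARBONYL",
                   "SIDECHAIN_O", "LIPID_HEADGROUP", "OTHER")

classify_axial_atom <- function(residue_name, atom_name, element) {
  ifelse(residue_name == "HIS" & atom_name %in% c("ND1", "NE2"),
         "HIS_SIDECHAIN",
  ifelse(residue_name %in% c("HOH", "WAT") & element == "O", "WATER",
  ifelse(residue_name %in% AMINO3 & atom_name %in% c("O", "OXT"),
         "BACKBONE_CARBONYL",
  ifelse(residue_name %in% AMINO3 & element == "O", "SIDECHAIN_O",
  ifelse(residue_name %in% c("LHG", "LMG") & element %in% c("O", "P"),
         "LIPID_HEADGROUP", "OTHER")))))
}

#' Detect magnesium axial ligands
#'
#' Non-pigment heavy atoms within a distance window of the chlorophyll's
#' central Mg, classified (His side chain, water, backbone carbonyl,
#' side-chain oxygen, lipid headgroup, other) and sorted by distance. The
#' default 1.9-3.0 A window brackets Mg-N/Mg-O coordination distances.
#'
#' @param model A `structure_model`.
#' @param pigment_key Residue key of the chlorophyll.
#' @param window Length-2 numeric distance window (A).
#' @param table Ligand code table (to exclude other chlorophylls).
#' @return Data frame: ligand_key, residue_name, atom_name, class,
#'   distance. May have zero rows.
#' @export
detect_axial_ligands <- function(model, pigment_key, window = c(1.9, 3.0),
                                 table = ligand_code_table()) {
  a <- model$atoms
  key <- residue_keys(model)
  mg_sel <- key == pigment_key & toupper(a$atom_name) == "MG"
  if (!any(mg_sel)) stop("pigment ", pigment_key, " has no MG")
  mg <- as.numeric(a[which(mg_sel)[1], c("x", "y", "z")])
  type <- suppressWarnings(classify_residue(a$residue_name, table))
  excl <- key == pigment_key | type %in% CHLOROPHYLL_TYPES
  cand <- a[!excl & a$element != "H", , drop = FALSE]
  ckey <- key[!excl & a$element != "H"]
  d <- sqrt((cand$x - mg[1])^2 + (cand$y - mg[2])^2 + (cand$z - mg[3])^2)
  in_win <- d >= window[1] & d <= window[2]
  out <- data.frame(ligand_key = ckey[in_win],
                    residue_name = cand$residue_name[in_win],
                    atom_name = cand$atom_name[in_win],
                    class = classify_axial_atom(cand$residue_name[in_win],
                                                cand$atom_name[in_win],
                                                cand$element[in_win]),
                    distance = d[in_win], stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Steric crowding at the C2 formyl position
#'
#' Models the oxygen a formyl group would add: a probe point 1.2 A beyond
#' the C2 substituent carbon along the C2 -> substituent direction (a
#' linear simplification of the sp2 geometry, configurable via
#' `extension`). Reports all heavy atoms outside the pigment itself within
#' `probe_radius` of that point -- crowding that would clash with, or
#' already participates in, neighbouring coordination argues against
#' placing a formyl group there.
#'
#' @param model A `structure_model`.
#' @param ring A `chlorin_ring` of the pigment.
#' @param probe_radius Contact radius around the probe point (A).
#' @param extension Probe extension beyond the substituent carbon (A).
#' @return List: `probe_point`, `n`, `min_dist` (NA if none), `contacts`
#'   data frame.
#' @export
c2_crowding <- function(model, ring, probe_radius = 3.0, extension = 1.2) {
  sub <- locate_c2_substituent(ring)
  c2 <- ring$positions["C2", ]
  sp <- as.numeric(sub[1, c("x", "y", "z")])
  dir <- sp - c2
  dir <- dir / sqrt(sum(dir^2))
  probe <- sp + extension * dir
  a <- model$atoms
  key <- residue_keys(model)
  cand <- a[key != ring$key & a$element != "H", , drop = FALSE]
  ckey <- key[key != ring$key & a$element != "H"]
  d <- sqrt((cand$x - probe[1])^2 + (cand$y - probe[2])^2 +
            (cand$z - probe[3])^2)
  hit <- d <= probe_radius
  contacts <- data.frame(residue_key = ckey[hit],
                         residue_name = cand$residue_name[hit],
                         atom_name = cand$atom_name[hit],
                         distance = d[hit], stringsAsFactors = FALSE)
  contacts <- contacts[order(contacts$distance), , drop = FALSE]
  list(probe_point = probe, n = nrow(contacts),
       min_dist = if (nrow(contacts)) contacts$distance[1] else NA_real_,
       contacts = contacts)
}
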