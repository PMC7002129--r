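# Rigid superposition of homologous photosystem structures, pigment-site
# correspondence (conserved/lost/gained), reference-style site labelling
# and axial-ligand change detection. Protein Calpha atoms drive the
# superposition; the pigments themselves are never fit targets, because
# pigment differences are the measurement.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the rms distance
#' between paired coordinates (reflection-corrected SVD). The transform
#' maps `query` onto `reference`.
#'
#' @param query,reference n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear).
#' @return A `superposition`: list(`rotation` 3x3 with det +1,
#'   `translation`, `rmsd`, `n`).
#' @export
kabsch_superpose <- function(query, reference) {
  X <- as.matrix(query); Y <- as.matrix(reference)
  stopifnot(ncol(X) == 3, ncol(Y) == 3)
  if (nrow(X) != nrow(Y)) stop("paired coordinate lists differ in length")
  if (nrow(X) < 3) stop("need >= 3 paired atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv_x <- svd(Xc)
  if (sv_x$d[2] < 1e-8 * max(sv_x$d[1], 1))
    stop("degenerate (collinear) configuration")
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cy - as.numeric(R %*% cx)
  fitted <- sweep(X %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n = nrow(X)),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param sup A `superposition`.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Paired Calpha coordinates of two models
#'
#' Pairs residues across two models by chain pairing and residue number
#' (after an optional offset), returning the Calpha coordinate matrices
#' that drive [kabsch_superpose()]. Chain pairings are supplied
#' explicitly (e.g. PsaA2 -> PsaA) to avoid guessing paralogy.
#'
#' @param query,reference `structure_model` objects.
#' @param chain_pairing Named character: query chain -> reference chain.
#' @param offset Integer added to query residue numbers before matching.
#' @return List of matrices `query`, `reference`.
#' @export
paired_ca_coords <- function(query, reference,
                             chain_pairing = NULL, offset = 0L) {
  qa <- query$atoms; ra <- reference$atoms
  qca <- qa[qa$atom_name == "CA" & qa$residue_name %in% AMINO3, ]
  rca <- ra[ra$atom_name == "CA" & ra$residue_name %in% AMINO3, ]
  if (is.null(chain_pairing)) {
    shared <- intersect(unique(qca$chain_id), unique(rca$chain_id))
    chain_pairing <- setNames(shared, shared)
  }
  qs <- list(); rs <- list()
  for (qc in names(chain_pairing)) {
    rc <- chain_pairing[[qc]]
    q1 <- qca[qca$chain_id == qc, ]
    r1 <- rca[rca$chain_id == rc, ]
    m <- match(q1$residue_number + offset, r1$residue_number)
    ok <- !is.na(m)
    qs[[qc]] <- as.matrix(q1[ok, c("x", "y", "z")])
    rs[[qc]] <- as.matrix(r1[m[ok], c("x", "y", "z")])
  }
  list(query = do.call(rbind, qs), reference = do.call(rbind, rs))
}

#' Match pigment sites between two structures
#'
#' After transforming the query's chlorophyll Mg positions into the
#' reference frame, pairs sites greedily by ascending Mg-Mg distance
#' under `cutoff` (each site used once). Unmatched reference sites are
#' `lost` in the query; unmatched query sites are `gained`.
#'
#' @param query,reference `structure_model` objects.
#' @param sup A `superposition` mapping query onto reference (or `NULL`
#'   if frames already agree).
#' @param cutoff Same-site Mg-Mg cutoff (A), default 2.5.
#' @param table Ligand code table.
#' @return Data frame: query_site, reference_site, status
#'   (conserved/lost/gained), mg_displacement.
#' @export
match_pigment_sites <- function(query, reference, sup = NULL,
                                cutoff = 2.5,
                                table = ligand_code_table()) {
  qchl <- chlorophyll_residues(query, table)
  rchl <- chlorophyll_residues(reference, table)
  qmg <- mg_positions(query, qchl)
  rmg <- mg_positions(reference, rchl)
  qok <- !is.na(qmg[, 1]); rok <- !is.na(rmg[, 1])
  qchl <- qchl[qok, , drop = FALSE]; qmg <- qmg[qok, , drop = FALSE]
  rchl <- rchl[rok, , drop = FALSE]; rmg <- rmg[rok, , drop = FALSE]
  if (!is.null(sup)) qmg <- apply_superposition(qmg, sup)
  nq <- nrow(qchl); nr <- nrow(rchl)
  dm <- matrix(Inf, nq, nr)
  if (nq && nr)
    dm <- sqrt(outer(rowSums(qmg^2), rowSums(rmg^2), "+") -
               2 * qmg %*% t(rmg))
  qfree <- rep(TRUE, nq); rfree <- rep(TRUE, nr)
  matches <- list()
  repeat {
    dmf <- dm; dmf[!qfree, ] <- Inf; dmf[, !rfree] <- Inf
    if (!length(dmf) || min(dmf) > cutoff) break
    ij <- which(dmf == min(dmf), arr.ind = TRUE)[1, ]
    matches[[length(matches) + 1L]] <- data.frame(
      query_site = qchl$key[ij[1]], reference_site = rchl$key[ij[2]],
      status = "conserved", mg_displacement = dm[ij[1], ij[2]],
      stringsAsFactors = FALSE)
    qfree[ij[1]] <- FALSE; rfree[ij[2]] <- FALSE
  }
  out <- if (length(matches)) do.call(rbind, matches)
         else data.frame(query_site = character(),
                         reference_site = character(),
                         status = character(),
                         mg_displacement = numeric())
  if (any(rfree))
    out <- rbind(out, data.frame(query_site = NA_character_,
                                 reference_site = rchl$key[rfree],
                                 status = "lost",
                                 mg_displacement = NA_real_))
  if (any(qfree))
    out <- rbind(out, data.frame(query_site = qchl$key[qfree],
                                 reference_site = NA_character_,
                                 status = "gained",
                                 mg_displacement = NA_real_))
  rownames(out) <- NULL
  out
}

#' Transfer reference-style site labels onto query pigments
#'
#' Conserved sites get the community label: reference chain letter plus
#' the last two digits of the reference residue number (the pigment
#' numbered 1120 on chain A becomes "A20"; 1402 becomes "A02"). Gained
#' pigments, absent from the reference, get `<chain>new<i>` with a
#' sequential suffix.
#'
#' @param correspondences Output of [match_pigment_sites()].
#' @return Data frame `query_site`, `label` (one row per query pigment).
#' @export
transfer_site_labels <- function(correspondences) {
  cons <- correspondences[correspondences$status == "conserved", ,
                          drop = FALSE]
  gained <- correspondences[correspondences$status == "gained", ,
                            drop = FALSE]
  lab <- character(0); qs <- character(0)
  if (nrow(cons)) {
    parts <- strsplit(cons$reference_site, ":", fixed = TRUE)
    lab <- vapply(parts, function(p)
      sprintf("%s%02d", p[1], as.integer(p[2]) %% 100), "")
    qs <- cons$query_site
  }
  if (nrow(gained)) {
    gained <- gained[order(gained$query_site), , drop = FALSE]
    ch <- vapply(strsplit(gained$query_site, ":", fixed = TRUE),
                 `[`, "", 1)
    lab <- c(lab, paste0(ch, "new", stats::ave(seq_along(ch), ch,
                                               FUN = seq_along)))
    qs <- c(qs, gained$query_site)
  }
  data.frame(query_site = qs, label = lab, stringsAsFactors = FALSE)
}

#' Compare axial ligands across conserved pigment sites
#'
#' For every conserved site, reports the nearest axial-ligand class in
#' each model (or `"none"`) and whether it changed -- e.g. an axial His
#' lost in the far-red structure, or a phosphatidylglycerol-headgroup
#' ligand replaced.
#'
#' @param correspondences Output of [match_pigment_sites()].
#' @param query,reference `structure_model` objects.
#' @param window Axial distance window (A).
#' @param table Ligand code table.
#' @return Data frame: query_site, reference_site, query_class,
#'   reference_class, changed.
#' @export
compare_axial_ligands <- function(correspondences, query, reference,
                                  window = c(1.9, 3.0),
                                  table = ligand_code_table()) {
  cons <- correspondences[correspondences$status == "conserved", ,
                          drop = FALSE]
  top_class <- function(model, key) {
    lig <- detect_axial_ligands(model, key, window = window, table = table)
    if (nrow(lig)) lig$class[1] else "none"
  }
  qc <- vapply(cons$query_site, function(k) top_class(query, k), "")
  rc <- vapply(cons$reference_site, function(k) top_class(reference, k), "")
  data.frame(query_site = cons$query_site,
             reference_site = cons$reference_site,
             query_class = unname(qc), reference_class = unname(rc),
             changed = unname(qc != rc), stringsAsFactors = FALSE)
}

#' Derive per-pigment site-change flags
#'
#' Assembles the structural-change evidence stream consumed by
#' [rank_chlf_candidates()]: a query pigment is flagged when it is absent
#' from the reference (gained), when its axial-ligand class changed, or
#' when a pigment site was lost or gained within `radius` of it.
#'
#' @param correspondences Output of [match_pigment_sites()].
#' @param axial_changes Output of [compare_axial_ligands()] (may be
#'   `NULL`).
#' @param query,reference `structure_model` objects.
#' @param radius Neighbourhood radius (A), default 10.
#' @param table Ligand code table.
#' @return Named logical vector keyed by query pigment residue key.
#' @export
derive_site_change_flags <- function(correspondences, axial_changes,
                                     query, reference, radius = 10,
                                     table = ligand_code_table()) {
  qchl <- chlorophyll_residues(query, table)
  rchl <- chlorophyll_residues(reference, table)
  qmg <- mg_positions(query, qchl)
  rmg <- mg_positions(reference, rchl)
  cons <- correspondences[correspondences$status == "conserved", ,
                          drop = FALSE]
  lost <- correspondences$reference_site[correspondences$status == "lost"]
  gained <- correspondences$query_site[correspondences$status == "gained"]
  flags <- setNames(rep(FALSE, nrow(qchl)), qchl$key)
  flags[gained[gained %in% names(flags)]] <- TRUE
  if (!is.null(axial_changes) && nrow(axial_changes))
    flags[axial_changes$query_site[axial_changes$changed]] <- TRUE
  near <- function(x, ys) {
    if (!nrow(ys)) return(FALSE)
    any(sqrt(rowSums(sweep(ys, 2, x)^2)) <= radius)
  }
  lost_mg <- rmg[rchl$key %in% lost, , drop = FALSE]
  gained_mg <- qmg[qchl$key %in% gained, , drop = FALSE]
  for (i in seq_len(nrow(cons))) {
    qk <- cons$query_site[i]
    r_xyz <- rmg[match(cons$reference_site[i], rchl$key), ]
    q_xyz <- qmg[match(qk, qchl$key), ]
    if (near(r_xyz, lost_mg) || near(q_xyz, gained_mg))
      flags[qk] <- TRUE
  }
  flags
}
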