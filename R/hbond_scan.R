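# Hydrogen-bond donor scanning around the chlorin C2 substituent and
# ranking of candidate chlorophyll f binding sites. Chlorophyll f differs
# from Chl a only by a C2 formyl group, invisible at ~3 A resolution, so
# an in-place donor poised to hydrogen-bond a formyl oxygen is the key
# structural evidence for assigning a site to Chl f.

DONOR_CLASSES <- c("SIDECHAIN_HYDROXYL", "SIDECHAIN_AMIDE_N",
                   "SIDECHAIN_BASIC_N", "HIS_N", "BACKBONE_AMIDE_N",
                   "WATER_O", "OTHER_POLAR")

donor_class_of <- function(residue_name, atom_name, element) {
  aa <- residue_name %in% AMINO3
  ifelse(aa & ((residue_name == "SER" & atom_name == "OG") |
               (residue_name == "THR" & atom_name == "OG1") |
               (residue_name == "TYR" & atom_name == "OH")),
         "SIDECHAIN_HYDROXYL",
  ifelse(aa & ((residue_name == "ASN" & atom_name == "ND2") |
               (residue_name == "GLN" & atom_name == "NE2")),
         "SIDECHAIN_AMIDE_N",
  ifelse(aa & ((residue_name == "LYS" & atom_name == "NZ") |
               (residue_name == "ARG" &
                atom_name %in% c("NE", "NH1", "NH2"))),
         "SIDECHAIN_BASIC_N",
  ifelse(aa & residue_name == "HIS" & atom_name %in% c("ND1", "NE2"),
         "HIS_N",
  ifelse(aa & atom_name == "N", "BACKBONE_AMIDE_N",
  ifelse(residue_name %in% c("HOH", "WAT") & element == "O", "WATER_O",
         NA_character_))))))
}

#' Enumerate hydrogen-bond donor atoms
#'
#' All atoms of the model matching the donor table: Ser/Thr/Tyr hydroxyl
#' oxygens, Asn/Gln amide nitrogens, Lys/Arg basic nitrogens, His ring
#' nitrogens, every backbone amide nitrogen, and water oxygens.
#'
#' @param model A `structure_model`.
#' @return Data frame: residue_key, residue_name, atom_name, class, x, y,
#'   z; one row per donor atom.
#' @export
enumerate_donors <- function(model) {
  a <- model$atoms
  cls <- donor_class_of(a$residue_name, a$atom_name, a$element)
  sel <- !is.na(cls)
  data.frame(residue_key = residue_keys(model)[sel],
             residue_name = a$residue_name[sel],
             atom_name = a$atom_name[sel],
             class = cls[sel],
             x = a$x[sel], y = a$y[sel], z = a$z[sel],
             stringsAsFactors = FALSE)
}

#' Scan the C2 environment of one chlorophyll for donors
#'
#' Distances are measured from donor atoms to the C2-substituent heavy
#' atom, which proxies the formyl oxygen when the site is modelled as
#' Chl a (the true formyl oxygen would sit up to ~0.5 A further out).
#' Donors within `window` (default 2.4-3.5 A, bracketing observed
#' 2.5-3.47 A interactions) are reported sorted by distance, flagged
#' `strong` at <= `strong_cutoff`. No donor-hydrogen angle criterion is
#' applied: the coordinate models carry no hydrogens, so the scan is
#' distance-only. Backbone/side-chain carbonyl oxygens within the window
#' are reported separately as non-donor polar contacts; they never enter
#' the donor list.
#'
#' @param model A `structure_model`.
#' @param pigment_key Residue key of the chlorophyll.
#' @param window Length-2 donor distance window (A).
#' @param strong_cutoff "Strong" flag cutoff (A), default 3.2.
#' @param ring Optional precomputed `chlorin_ring`.
#' @return A `formyl_site_candidate`: list(site, donors, polar_contacts,
#'   min_dist).
#' @export
scan_c2_environment <- function(model, pigment_key, window = c(2.4, 3.5),
                                strong_cutoff = 3.2, ring = NULL) {
  if (is.null(ring)) ring <- map_ring_atoms(model, pigment_key)
  sub <- locate_c2_substituent(ring)
  sp <- as.numeric(sub[1, c("x", "y", "z")])
  don <- enumerate_donors(model)
  don <- don[don$residue_key != pigment_key, , drop = FALSE]
  d <- sqrt((don$x - sp[1])^2 + (don$y - sp[2])^2 + (don$z - sp[3])^2)
  keep <- d >= window[1] & d <= window[2]
  donors <- don[keep, c("residue_key", "residue_name", "atom_name",
                        "class"), drop = FALSE]
  donors$distance <- d[keep]
  donors$strong <- donors$distance <= strong_cutoff
  donors <- donors[order(donors$distance), , drop = FALSE]
  rownames(donors) <- NULL
  # carbonyl oxygens: polar contacts worth reporting, but not donors
  a <- model$atoms
  key <- residue_keys(model)
  carb <- a$residue_name %in% AMINO3 & a$atom_name %in% c("O", "OXT") &
    key != pigment_key
  cd <- sqrt((a$x[carb] - sp[1])^2 + (a$y[carb] - sp[2])^2 +
             (a$z[carb] - sp[3])^2)
  ck <- cd >= window[1] & cd <= window[2]
  polar <- data.frame(residue_key = key[carb][ck],
                      residue_name = a$residue_name[carb][ck],
                      atom_name = a$atom_name[carb][ck],
                      distance = cd[ck], stringsAsFactors = FALSE)
  polar <- polar[order(polar$distance), , drop = FALSE]
  structure(list(site = pigment_key, donors = donors,
                 polar_contacts = polar,
                 min_dist = if (nrow(donors)) donors$distance[1]
                            else NA_real_),
            class = "formyl_site_candidate")
}

hbond_term <- function(min_dist, full = 2.6, zero = 3.5) {
  ifelse(is.na(min_dist), 0, pmin(1, pmax(0, (zero - min_dist) /
                                               (zero - full))))
}

#' Rank candidate chlorophyll f sites
#'
#' Combines three evidence streams into an explicit additive score per
#' chlorophyll site:
#' \deqn{score = w_1\,\mathrm{hbond} + w_2\,(1 - \mathrm{conservation})
#'   + w_3\,\mathrm{site\_change}}
#' where the H-bond term is 1 for a donor at <= 2.6 A, decaying linearly
#' to 0 at 3.5 A; the conservation term rewards locally divergent
#' sequence; and the site-change flag marks a changed axial ligand, a
#' lost/gained neighbouring site, or absence of the site from the
#' reference. Any missing evidence stream contributes 0. This additive
#' formalization makes the qualitative weighing of evidence reproducible;
#' it is a scoring convention, not a fitted model.
#'
#' @param model A `structure_model`.
#' @param conservation Named numeric in `[0,1]` keyed by pigment residue
#'   key (local environment identity); may be `NULL`.
#' @param site_change Named logical keyed by pigment residue key; may be
#'   `NULL`.
#' @param weights Length-3 non-negative weights (default `c(1,1,1)`).
#' @param window,strong_cutoff Passed to [scan_c2_environment()].
#' @param labels Optional named character: residue key -> site label.
#' @param table Ligand code table.
#' @return Data frame sorted by decreasing score (ties alphabetical by
#'   site label): site, n_donors, min_dist, conservation, site_change,
#'   hbond_term, conservation_term, change_term, score.
#' @export
rank_chlf_candidates <- function(model, conservation = NULL,
                                 site_change = NULL, weights = c(1, 1, 1),
                                 window = c(2.4, 3.5), strong_cutoff = 3.2,
                                 labels = NULL,
                                 table = ligand_code_table()) {
  if (length(weights) != 3 || any(weights < 0))
    stop("weights must be 3 non-negative numbers")
  chl <- chlorophyll_residues(model, table)
  if (nrow(chl) == 0) stop("no chlorophylls in model")
  rows <- lapply(chl$key, function(k) {
    cand <- scan_c2_environment(model, k, window = window,
                                strong_cutoff = strong_cutoff)
    cons <- if (!is.null(conservation) && k %in% names(conservation))
      conservation[[k]] else NA_real_
    chg <- if (!is.null(site_change) && k %in% names(site_change))
      isTRUE(site_change[[k]]) else NA
    hb <- hbond_term(cand$min_dist, full = 2.6, zero = window[2])
    ct <- if (is.na(cons)) 0 else 1 - cons
    st <- if (is.na(chg)) 0 else as.numeric(chg)
    data.frame(site = if (!is.null(labels) && k %in% names(labels))
                 labels[[k]] else k,
               residue_key = k,
               n_donors = nrow(cand$donors), min_dist = cand$min_dist,
               conservation = cons, site_change = chg,
               hbond_term = hb, conservation_term = ct, change_term = st,
               score = weights[1] * hb + weights[2] * ct + weights[3] * st,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a candidate table as TSV and/or JSON
#'
#' @param candidates Output of [rank_chlf_candidates()].
#' @param tsv,json Optional output paths.
#' @return `candidates`, invisibly.
#' @export
write_candidates <- function(candidates, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    write.table(candidates, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  if (!is.null(json))
    jsonlite::write_json(candidates, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(candidates)
}
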