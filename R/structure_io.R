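# Reading/writing coordinate files and classifying cofactor residues.
# PDB parsing is delegated to bio3d; mmCIF atom_site loops are parsed here
# (no installed R package reads mmCIF coordinates).

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "MSE", "SEC", "PYL")

# Residue codes the PDB chemical dictionary uses for chlorin-family pigments.
# An unlisted member of this family must warn (never silently become OTHER).
CHLORIN_FAMILY_CODES <- c("CLA", "CL0", "CHL", "F6C", "CL1", "CL2", "CL7",
                          "BCL", "BCB", "PHO", "PEO", "G9R", "07D")

#' Pigment type vocabulary
#'
#' Cofactor classes used throughout the package. Chlorophyll totals are the
#' sum of `CHL_A`, `CHL_A_PRIME`, `CHL_F` and `CHL_B`.
#'
#' @return Character vector of pigment type names.
#' @export
pigment_types <- function() {
  c("CHL_A", "CHL_A_PRIME", "CHL_F", "CHL_B", "CAROTENOID", "PHYLLOQUINONE",
    "PG_LIPID", "MGDG_LIPID", "DETERGENT", "FE4S4", "WATER", "OTHER")
}

CHLOROPHYLL_TYPES <- c("CHL_A", "CHL_A_PRIME", "CHL_F", "CHL_B")

#' Ligand code table
#'
#' Maps heteroatom residue codes to pigment types. The default covers the
#' vocabulary of cyanobacterial photosystem depositions (1JB0 and kin):
#' CLA (Chl a), CL0 (Chl a'), CHL (Chl b), F6C (Chl f), BCR/ECN
#' (carotenoids), PQN/PHQ (phylloquinone), LHG (phosphatidylglycerol),
#' LMG (monogalactosyl diglyceride), LMT (beta-DM detergent), SF4
#' (4Fe-4S cluster), HOH (water). Fully overrideable because ligand vocabularies
#' differ between depositions.
#'
#' @param ... Named character entries overriding or extending the default,
#'   e.g. `ligand_code_table(ZZZ = "CHL_F")`.
#' @return Named character vector: residue code -> pigment type.
#' @export
ligand_code_table <- function(...) {
  tab <- c(CLA = "CHL_A", CL0 = "CHL_A_PRIME", CHL = "CHL_B", F6C = "CHL_F",
           BCR = "CAROTENOID", ECN = "CAROTENOID",
           PQN = "PHYLLOQUINONE", PHQ = "PHYLLOQUINONE",
           LHG = "PG_LIPID", LMG = "MGDG_LIPID", LMT = "DETERGENT",
           SF4 = "FE4S4", HOH = "WATER")
  extra <- c(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("ligand code overrides must be named")
    bad <- setdiff(extra, pigment_types())
    if (length(bad))
      stop("unknown pigment type(s): ", paste(bad, collapse = ", "))
    tab[names(extra)] <- extra
  }
  tab
}

#' Classify a residue code into a pigment type
#'
#' @param residue_name Residue code(s) (3-5 characters).
#' @param table Ligand code table from [ligand_code_table()].
#' @return Character vector of pigment types. Amino acids and codes absent
#'   from the table map to `OTHER`; unlisted chlorin-family codes warn.
#' @export
classify_residue <- function(residue_name, table = ligand_code_table()) {
  out <- unname(table[residue_name])
  unknown <- is.na(out)
  chlorin_like <- unknown & residue_name %in% CHLORIN_FAMILY_CODES
  if (any(chlorin_like))
    warning("chlorophyll-like residue code(s) not in ligand table: ",
            paste(unique(residue_name[chlorin_like]), collapse = ", "),
            " (classified OTHER; extend ligand_code_table())")
  out[unknown] <- "OTHER"
  out
}

element_from_name <- function(atom_name, residue_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- c("MG", "FE", "ZN", "MN", "CU", "NI", "CL", "BR", "SE", "NA", "CD")
  el <- substr(nm, 1, 1)
  # two-letter metals/halogens only outside protein residues, where CA/CB
  # etc. are carbons
  idx <- nm %in% two & !(residue_name %in% AMINO3)
  el[idx] <- paste0(substr(nm[idx], 1, 1), tolower(substr(nm[idx], 2, 2)))
  el
}

new_structure_model <- function(atoms, source_format, monomer_chains = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("record_type", "chain_id", "residue_name", "residue_number",
            "insertion_code", "atom_name", "element", "x", "y", "z",
            "occupancy", "b_factor", "alt_loc")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_format = source_format,
                 monomer_chains = monomer_chains),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  res <- unique(residue_keys(x))
  cat(sprintf("structure_model: %d atoms, %d residues, chains %s (%s)\n",
              nrow(x$atoms), length(res),
              paste(sort(unique(x$atoms$chain_id)), collapse = ""),
              x$source_format))
  invisible(x)
}

#' Residue keys of a structure
#'
#' Keys are `chain:resno:ins` and are unique within a model.
#'
#' @param model A `structure_model`.
#' @param atoms Optional atom subset (data frame) to key instead.
#' @return Character vector, one entry per atom row.
#' @export
residue_keys <- function(model, atoms = NULL) {
  a <- if (is.null(atoms)) model$atoms else atoms
  paste(a$chain_id, a$residue_number, a$insertion_code, sep = ":")
}

# one row per residue: key, chain, resno, ins, resname
residue_table <- function(model) {
  a <- model$atoms
  key <- residue_keys(model)
  first <- !duplicated(key)
  data.frame(key = key[first], chain_id = a$chain_id[first],
             residue_number = a$residue_number[first],
             insertion_code = a$insertion_code[first],
             residue_name = a$residue_name[first],
             stringsAsFactors = FALSE)
}

residue_atoms <- function(model, key) {
  model$atoms[residue_keys(model) == key, , drop = FALSE]
}

# Alt-loc policy: per (residue, atom name) keep the highest-occupancy
# location; ties broken by alphabetical alt-loc id. Deterministic census.
apply_altloc_policy <- function(atoms) {
  id <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
              atoms$atom_name, sep = ":")
  ord <- order(id, -atoms$occupancy, atoms$alt_loc)
  keep <- sort(ord[!duplicated(id[ord])])  # winners, in file order
  atoms[keep, , drop = FALSE]
}

#' Read a coordinate file
#'
#' Parses ATOM/HETATM records from PDB (via bio3d) or mmCIF (built-in
#' `atom_site` reader), applies the alternate-location policy (highest
#' occupancy wins, ties by alphabetical alt-loc id) and returns a
#' `structure_model`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param monomer_chains Optional character vector naming the chains of one
#'   biological monomer (used as the default census selection).
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           monomer_chains = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  atoms <- switch(format,
                  pdb = read_pdb_atoms(path),
                  mmcif = read_mmcif_atoms(path))
  if (nrow(atoms) == 0) stop("zero atoms in ", path)
  atoms <- apply_altloc_policy(atoms)
  message(sprintf("read %d atoms (%s) from %s", nrow(atoms), format,
                  basename(path)))
  new_structure_model(atoms, format, monomer_chains)
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
                  error = function(e) stop("unreadable PDB file: ", path,
                                           " (", conditionMessage(e), ")"))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("zero atoms in ", path)
  el <- a$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(a))
  el <- ifelse(is.na(el) | !nzchar(trimws(el)),
               element_from_name(a$elety, a$resid), trimws(el))
  data.frame(record_type = a$type,
             chain_id = ifelse(is.na(a$chain), "", a$chain),
             residue_name = a$resid,
             residue_number = a$resno,
             insertion_code = ifelse(is.na(a$insert), "", a$insert),
             atom_name = a$elety,
             element = el,
             x = a$x, y = a$y, z = a$z,
             occupancy = ifelse(is.na(a$o), 1, a$o),
             b_factor = ifelse(is.na(a$b), 0, a$b),
             alt_loc = ifelse(is.na(a$alt), "", a$alt),
             stringsAsFactors = FALSE)
}

cif_blank <- function(x) ifelse(x %in% c(".", "?"), "", x)

# Minimal mmCIF atom_site reader: locates the loop_ whose data items are
# _atom_site.*, then splits each row on whitespace (quoted tokens honoured).
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tagged <- grep("^_atom_site\\.", lines)
  if (!length(tagged)) stop("no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[tagged]))
  body_start <- max(tagged) + 1
  rows <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^(#|loop_|_[A-Za-z]|data_)", ln)) break
    rows <- c(rows, ln)
  }
  if (!length(rows)) stop("zero atoms in ", path)
  toks <- lapply(rows, function(ln) {
    m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", ln)[[1]]
    gsub("^['\"]|['\"]$", "", regmatches(ln, list(m))[[1]])
  })
  nf <- length(fields)
  ok <- vapply(toks, length, 1L) == nf
  if (!all(ok)) stop("malformed mmCIF atom_site rows in ", path)
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- fields
  pick <- function(primary, fallback) {
    if (primary %in% names(tab)) tab[[primary]]
    else if (fallback %in% names(tab)) tab[[fallback]]
    else rep("", nrow(tab))
  }
  resname <- cif_blank(pick("auth_comp_id", "label_comp_id"))
  aname <- cif_blank(pick("auth_atom_id", "label_atom_id"))
  el <- cif_blank(pick("type_symbol", "type_symbol"))
  el <- ifelse(nzchar(el),
               paste0(substr(el, 1, 1), tolower(substring(el, 2))),
               element_from_name(aname, resname))
  occ <- suppressWarnings(as.numeric(cif_blank(pick("occupancy", "occupancy"))))
  b <- suppressWarnings(as.numeric(cif_blank(pick("B_iso_or_equiv",
                                                  "B_iso_or_equiv"))))
  data.frame(record_type = pick("group_PDB", "group_PDB"),
             chain_id = cif_blank(pick("auth_asym_id", "label_asym_id")),
             residue_name = resname,
             residue_number = as.integer(cif_blank(pick("auth_seq_id",
                                                        "label_seq_id"))),
             insertion_code = cif_blank(pick("pdbx_PDB_ins_code",
                                             "pdbx_PDB_ins_code")),
             atom_name = aname,
             element = el,
             x = as.numeric(tab$Cartn_x),
             y = as.numeric(tab$Cartn_y),
             z = as.numeric(tab$Cartn_z),
             occupancy = ifelse(is.na(occ), 1, occ),
             b_factor = ifelse(is.na(b), 0, b),
             alt_loc = cif_blank(pick("label_alt_id", "label_alt_id")),
             stringsAsFactors = FALSE)
}

#' Pigment cofactor census
#'
#' Counts residues of each pigment type, optionally restricted to a monomer
#' chain selection. Chlorophyll and carotenoid totals as reported for
#' photosystem monomers are available through [chlorophyll_total()] and the
#' returned vector. Counts report file contents verbatim; no reconciliation
#' of assembly-level bookkeeping is attempted.
#'
#' @param model A `structure_model`.
#' @param table Ligand code table.
#' @param monomer_chains Optional chain subset; defaults to the model's
#'   `monomer_chains` or all chains.
#' @return Named integer vector over [pigment_types()], class
#'   `pigment_census`.
#' @export
census <- function(model, table = ligand_code_table(),
                   monomer_chains = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(monomer_chains)) monomer_chains <- model$monomer_chains
  res <- residue_table(model)
  if (!is.null(monomer_chains)) {
    absent <- setdiff(monomer_chains, unique(model$atoms$chain_id))
    if (length(absent))
      stop("monomer chains absent from model: ",
           paste(absent, collapse = ", "))
    res <- res[res$chain_id %in% monomer_chains, , drop = FALSE]
  }
  cof <- res[!(res$residue_name %in% AMINO3), , drop = FALSE]
  types <- classify_residue(cof$residue_name, table)
  counts <- setNames(integer(length(pigment_types())), pigment_types())
  tb <- table(types)
  counts[names(tb)] <- as.integer(tb)
  structure(counts, class = c("pigment_census", "integer"))
}

#' @export
print.pigment_census <- function(x, ...) {
  nz <- x[x > 0]
  for (nm in names(nz)) cat(sprintf("%-14s %d\n", nm, nz[[nm]]))
  cat(sprintf("%-14s %d\n", "chlorophylls", chlorophyll_total(x)))
  invisible(x)
}

#' Total chlorophyll count of a census
#'
#' @param counts A `pigment_census`.
#' @return Integer: CHL_A + CHL_A_PRIME + CHL_F + CHL_B.
#' @export
chlorophyll_total <- function(counts) {
  sum(counts[CHLOROPHYLL_TYPES])
}

#' Write a census as TSV and/or JSON
#'
#' @param counts A `pigment_census`.
#' @param tsv,json Optional output paths.
#' @return The census, invisibly.
#' @export
write_census <- function(counts, tsv = NULL, json = NULL) {
  df <- data.frame(pigment_type = names(counts),
                   count = as.integer(counts))
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(as.list(setNames(as.integer(counts),
                                          names(counts))),
                         json, auto_unbox = TRUE, pretty = TRUE)
  invisible(counts)
}

#' Write a structure as PDB
#'
#' Optionally replaces the B-factor column with a per-residue scalar (e.g.
#' a conservation track for structure-viewer colouring), clamped to
#' `[0, 999.99]`. Residues missing from the scalar map get 0.00 with a
#' warning.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @param per_residue_scalar Optional named numeric vector keyed by residue
#'   key (see [residue_keys()]).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, per_residue_scalar = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  b <- a$b_factor
  if (!is.null(per_residue_scalar)) {
    key <- residue_keys(model)
    b <- unname(per_residue_scalar[key])
    if (anyNA(b)) {
      warning(sum(is.na(b[!duplicated(key)])),
              " residue(s) missing from scalar map; B-factor set to 0.00")
      b[is.na(b)] <- 0
    }
    b <- pmin(pmax(b, 0), 999.99)
  }
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = a$record_type,
                     resno = a$residue_number,
                     resid = a$residue_name,
                     eleno = seq_len(nrow(a)),
                     elety = a$atom_name,
                     chain = a$chain_id,
                     insert = ifelse(nzchar(a$insertion_code),
                                     a$insertion_code, NA),
                     o = a$occupancy, b = b,
                     elesy = a$element)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
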