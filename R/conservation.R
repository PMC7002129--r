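# Sequence conservation: global alignment (Needleman-Wunsch with affine
# gaps, BLOSUM62), pairwise identity matrices, windowed per-residue
# identity tracks, and mapping of tracks onto pigment environments. The
# aligner itself is implemented in this package (src/nw_affine.cpp) so
# the alignment behaviour is fully reproducible.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Bundled BLOSUM62 substitution matrix
#'
#' 20 amino acids plus X, as integer log-odds scores.
#'
#' @return Numeric matrix with dimnames.
#' @export
blosum62 <- function() {
  path <- system.file("extdata", "blosum62.txt", package = "chlfsites")
  m <- as.matrix(read.table(path, header = TRUE, check.names = FALSE,
                            row.names = 1))
  storage.mode(m) <- "double"
  m
}

check_sequence <- function(s, who = "sequence") {
  if (!is.character(s) || length(s) != 1 || !nzchar(s))
    stop(who, " must be a non-empty string")
  ch <- strsplit(toupper(s), "")[[1]]
  bad <- setdiff(unique(ch), c(AA20, "X"))
  if (length(bad))
    stop(who, " contains illegal character(s): ",
         paste(bad, collapse = ""))
  ch
}

#' Global alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch alignment under the Gotoh three-state
#' recursion: a gap of length L costs `gap_open + (L-1)*gap_extend`.
#' Traceback is deterministic (diagonal > up > left on ties).
#'
#' @param a,b Amino acid strings (20 residues + X).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @return A `pairwise_alignment`: list(`a`, `b` gapped strings of equal
#'   length, `score`).
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 10,
                         gap_extend = 0.5) {
  ca <- check_sequence(a, "a"); cb <- check_sequence(b, "b")
  alph <- rownames(matrix)
  ia <- match(ca, alph); ib <- match(cb, alph)
  res <- .nw_affine_cpp(ia, ib, matrix, gap_open, gap_extend)
  tochar <- function(v) paste(c("-", alph)[v + 1], collapse = "")
  ag <- tochar(res$a); bg <- tochar(res$b)
  stopifnot(gsub("-", "", ag) == paste(ca, collapse = ""),
            gsub("-", "", bg) == paste(cb, collapse = ""))
  structure(list(a = ag, b = bg, score = res$score),
            class = "pairwise_alignment")
}

aln_cols <- function(aln) {
  list(a = strsplit(aln$a, "")[[1]], b = strsplit(aln$b, "")[[1]])
}

#' Percent identity of an alignment
#'
#' `aligned_columns` (default) divides identities by the number of
#' alignment columns excluding terminal gap overhangs; `shorter_seq`
#' divides by the length of the shorter input. The two diverge when one
#' sequence overhangs the other.
#'
#' @param aln A `pairwise_alignment`.
#' @param mode `"aligned_columns"` or `"shorter_seq"`.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(aln,
                             mode = c("aligned_columns", "shorter_seq")) {
  mode <- match.arg(mode)
  cc <- aln_cols(aln)
  ident <- cc$a == cc$b & cc$a != "-"
  if (mode == "shorter_seq") {
    denom <- min(sum(cc$a != "-"), sum(cc$b != "-"))
  } else {
    both <- which(cc$a != "-" & cc$b != "-")
    if (!length(both)) return(0)
    denom <- max(both) - min(both) + 1
    ident <- ident[min(both):max(both)]
  }
  100 * sum(ident) / denom
}

#' All-vs-all identity matrix
#'
#' Symmetric percent-identity matrix with a diagonal of 100, in the style
#' of the subunit identity tables used to compare far-red paralogs with
#' their white-light counterparts.
#'
#' @param records Named character vector of sequences (names are ids).
#' @param mode Passed to [percent_identity()].
#' @param ... Passed to [global_align()].
#' @return Symmetric numeric matrix.
#' @export
identity_matrix <- function(records, mode = "aligned_columns", ...) {
  if (length(records) < 2) stop("need >= 2 sequences")
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids))
    stop("records must have unique ids")
  n <- length(records)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pid <- percent_identity(global_align(records[[i]], records[[j]], ...),
                            mode = mode)
    m[i, j] <- m[j, i] <- pid
  }
  m
}

#' Windowed per-residue identity track
#'
#' For each residue of the query (the alignment's first sequence): the
#' fraction of identical columns in a centered window of alignment
#' columns (truncated at the ends). Gap columns count as mismatches.
#' This is the per-residue conservation signal used for
#' structure-mapped colouring of far-red paralogs.
#'
#' @param aln A `pairwise_alignment`.
#' @param window Odd window width >= 1 (default 11).
#' @return Numeric vector in `[0,1]`, one entry per ungapped query
#'   residue.
#' @export
windowed_identity <- function(aln, window = 11) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  cc <- aln_cols(aln)
  col_id <- as.numeric(cc$a == cc$b & cc$a != "-")
  L <- length(col_id)
  h <- (window - 1) / 2
  qpos <- which(cc$a != "-")
  vapply(qpos, function(c0) {
    lo <- max(1, c0 - h); hi <- min(L, c0 + h)
    mean(col_id[lo:hi])
  }, 1)
}

#' Map an identity track onto model residues
#'
#' @param track Numeric track from [windowed_identity()] (one value per
#'   ungapped query residue).
#' @param chain Chain id the track belongs to.
#' @param start_resno Residue number of the first track position
#'   (author numbering; use the offset to handle partial models).
#' @return Data frame: chain_id, residue_number, identity.
#' @export
track_to_residues <- function(track, chain, start_resno = 1L) {
  data.frame(chain_id = chain,
             residue_number = seq(start_resno,
                                  length.out = length(track)),
             identity = as.numeric(track), stringsAsFactors = FALSE)
}

#' Mean conservation of a pigment's protein environment
#'
#' Mean identity-track value over residues having any atom within
#' `radius` of any macrocycle atom of the pigment.
#'
#' @param model A `structure_model`.
#' @param pigment_key Residue key of the pigment.
#' @param track_map Data frame from [track_to_residues()] (rows may cover
#'   several chains).
#' @param radius Environment radius in A (default 8).
#' @return Fraction in `[0,1]`.
#' @export
local_environment_identity <- function(model, pigment_key, track_map,
                                       radius = 8) {
  ring <- map_ring_atoms(model, pigment_key)
  rxyz <- ring_coords(ring)
  a <- model$atoms
  tkey <- paste(track_map$chain_id, track_map$residue_number)
  akey <- paste(a$chain_id, a$residue_number)
  sel <- akey %in% tkey
  if (!any(sel)) stop("track maps to no residues present in the model")
  axyz <- as.matrix(a[sel, c("x", "y", "z")])
  d2 <- outer(rowSums(axyz^2), rowSums(rxyz^2), "+") -
    2 * axyz %*% t(rxyz)
  near <- apply(d2, 1, min) <= radius^2
  near_res <- unique(akey[sel][near])
  if (!length(near_res)) stop("no track residues within ", radius,
                              " A of pigment ", pigment_key)
  mean(track_map$identity[tkey %in% near_res])
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fa <- bio3d::read.fasta(path)
  seqs <- apply(fa$ali, 1, function(r)
    paste(r[r != "-" & !is.na(r)], collapse = ""))
  setNames(toupper(seqs), fa$id)
}
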