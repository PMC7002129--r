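# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: alignment scores come from exhaustive enumeration of
# move sequences, matchings from exhaustive search over injective
# pairings, and geometric quantities from direct vector arithmetic.

# Maximum global alignment score by enumerating every gapped alignment.
# Affine convention: a gap of length L costs open + (L-1)*extend.
oracle_nw_score <- function(a, b, mat, open, extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    if (i <= n)
      best <- max(best, -(if (identical(last, "X")) extend else open) +
                    rec(i + 1, j, "X"))
    if (j <= m)
      best <- max(best, -(if (identical(last, "Y")) extend else open) +
                    rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "none")
}

random_aa <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# Exhaustive optimal partial matching under a cutoff: maximize the number
# of matched pairs, then minimize the total distance. dm is query x ref.
oracle_best_matching <- function(dm, cutoff) {
  nq <- nrow(dm); nr <- ncol(dm)
  best <- list(count = -1, total = Inf, pairs = NULL)
  rec <- function(i, used, pairs, total) {
    if (i > nq) {
      cnt <- nrow(pairs)
      if (cnt > best$count ||
          (cnt == best$count && total < best$total)) {
        best <<- list(count = cnt, total = total, pairs = pairs)
      }
      return(invisible())
    }
    rec(i + 1, used, pairs, total)  # leave query i unmatched
    for (j in seq_len(nr)) {
      if (!used[j] && dm[i, j] <= cutoff) {
        used[j] <- TRUE
        rec(i + 1, used, rbind(pairs, data.frame(q = i, r = j)),
            total + dm[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, nr), data.frame(q = integer(), r = integer()), 0)
  best
}

# rms of point-plane distances, from the plane parameters directly
oracle_plane_rms <- function(xyz, normal, centroid) {
  d <- as.matrix(sweep(xyz, 2, centroid)) %*% (normal / sqrt(sum(normal^2)))
  sqrt(mean(d^2))
}

# all pairwise distances between two coordinate sets, elementwise loops
oracle_pair_dists <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    out[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  out
}

# a small chlorophyll-only model given translations (one CLA per row)
toy_chl_model <- function(translations, chain = "A", start_resno = 1L) {
  specs <- lapply(seq_len(nrow(translations)), function(i)
    placement(chain = chain, resno = start_resno + i - 1L,
              translation = translations[i, ]))
  build_toy_structure(specs)$model
}

quiet_read <- function(...) suppressMessages(read_structure(...))

# macrocycle coordinates of one pigment (MG excluded)
ring_coords_of <- function(model, key) {
  ring <- map_ring_atoms(model, key)
  ring$positions[rownames(ring$positions) != "MG", , drop = FALSE]
}
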