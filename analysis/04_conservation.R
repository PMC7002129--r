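#!/usr/bin/env Rscript
# Stage 4: sequence conservation. Aligns each far-red paralog with its
# white-light counterpart (Needleman-Wunsch, affine gaps, BLOSUM62),
# builds the identity matrix, derives windowed per-residue identity
# tracks for the query chains, and writes a track-coloured PDB (identity
# in the B-factor column) for structure viewers.
# Outputs: results/identity_matrix.tsv, results/track_<chain>.tsv,
#          results/structures/frl_query_conservation.pdb

suppressMessages(library(chlfsites))

seqs <- c(read_sequences("results/sequences/psaJ_paralogs.fasta"),
          read_sequences("results/sequences/core_paralogs.fasta"))
im <- identity_matrix(seqs)
write.table(round(im, 1), "results/identity_matrix.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
cat("pairwise identity: J2 vs J1 =", round(im["J2", "J1"], 1),
    "% ; P2 vs P1 =", round(im["P2", "P1"], 1), "%\n")

query <- suppressMessages(
  read_structure("results/structures/frl_query.pdb"))

tracks <- list()
for (pair in list(c("J2", "J1", "J"), c("P2", "P1", "P"))) {
  al <- global_align(seqs[[pair[1]]], seqs[[pair[2]]])
  trk <- windowed_identity(al, window = 11)
  tm <- track_to_residues(trk, chain = pair[3])
  tracks[[pair[3]]] <- tm
  write.table(tm, sprintf("results/track_%s.tsv", pair[3]), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
track_map <- do.call(rbind, tracks)

# colour the query by conservation through the B-factor channel
scal <- setNames(track_map$identity,
                 paste(track_map$chain_id, track_map$residue_number, "",
                       sep = ":"))
suppressWarnings(write_structure(
  query, "results/structures/frl_query_conservation.pdb",
  per_residue_scalar = scal))

# local environment identity per pigment (NA where no peptide in range)
chl <- chlorophyll_residues(query)
env <- vapply(chl$key, function(k)
  tryCatch(local_environment_identity(query, k, track_map),
           error = function(e) NA_real_), 1)
write.table(data.frame(site = chl$key, environment_identity = env),
            "results/environment_identity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("pigment environment identity:\n")
print(round(env, 3))
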