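#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# Two structures stand in for the white-light reference photosystem and
# its far-red-acclimated counterpart:
#   * reference: a stacked chlorophyll trio (A18/A20/A21, one
#     phosphatidylglycerol-coordinated), a dimer (A33/A34), two isolated
#     antenna sites and two B-chain sites; two peptide chains (J near
#     site B30, P near A25).
#   * query: the same system after far-red remodelling -- site A18 and
#     its lipid are gone, A21 has lost its axial His, A34 is gone
#     (dimer -> monomer), and hydrogen-bond donors appear by the C2
#     substituents of A20 (water), B30 (Tyr hydroxyl, 2.5 A) and B37
#     (backbone amide). The whole query is rigidly rotated/translated so
#     that the later superposition stage does real work.
# Peptide paralogs: chain J diverges strongly (~40% of positions
# substituted), chain P weakly (~7%).
#
# Outputs: results/structures/*.pdb, results/sequences/*.fasta,
#          results/structures/ground_truth.json

suppressMessages(library(chlfsites))
dir.create("results/structures", recursive = TRUE, showWarnings = FALSE)
dir.create("results/sequences", recursive = TRUE, showWarnings = FALSE)

his <- list(residue_name = "HIS", atom_name = "NE2", distance = 2.15)

ref_placements <- list(
  placement("A", 1118, translation = c(0, 0, -6),
            axial = list(residue_name = "LHG", atom_name = "O1",
                         distance = 2.6)),
  placement("A", 1120, translation = c(0, 0, 0)),
  placement("A", 1121, translation = c(0, 0, 6), axial = his),
  placement("A", 1133, translation = c(30, 0, 0)),
  placement("A", 1134, translation = c(30, 0, 6), axial = his),
  placement("A", 1125, translation = c(60, 0, 0), axial = his),
  placement("B", 1130, translation = c(0, 40, 0)),
  placement("B", 1137, translation = c(30, 40, 0), axial = his))

ref_build <- build_toy_structure(ref_placements)
seq_J <- random_protein_sequence(24, seed = 101)
seq_P <- random_protein_sequence(30, seed = 102)
pep_J <- build_toy_peptide(seq_J, chain = "J", origin = c(6, 33, 3))
pep_P <- build_toy_peptide(seq_P, chain = "P", origin = c(52, 6, 3))
reference <- combine_models(ref_build$model, pep_J, pep_P)

qry_placements <- list(
  placement("A", 20, translation = c(0, 0, 0),
            donors = list(list(residue_name = "HOH", atom_name = "O",
                               distance = 2.7, direction = c(1, 1, 1)))),
  placement("A", 21, translation = c(0, 0, 6)),  # axial His lost
  placement("A", 33, translation = c(30, 0, 0)),
  placement("A", 25, translation = c(60, 0, 0), axial = his),
  placement("B", 30, translation = c(0, 40, 0),
            donors = list(list(residue_name = "TYR", atom_name = "OH",
                               distance = 2.5, direction = c(1, 0.5, 1)))),
  placement("B", 37, translation = c(30, 40, 0),
            donors = list(list(residue_name = "GLY", atom_name = "N",
                               distance = 3.1, direction = c(0, 1, 1)))))

qry_build <- build_toy_structure(qry_placements)
seq_J2 <- mutate_sequence(seq_J, 10, seed = 201)  # ~40% divergent paralog
seq_P2 <- mutate_sequence(seq_P, 2, seed = 202)   # near-identical core
pep_J2 <- build_toy_peptide(seq_J2, chain = "J", origin = c(6, 33, 3))
pep_P2 <- build_toy_peptide(seq_P2, chain = "P", origin = c(52, 6, 3))
query <- combine_models(qry_build$model, pep_J2, pep_P2)
query <- transform_model(query,
                         rotation_about_axis(c(1, 2, 0.5), 33),
                         c(12, -7, 20))

write_structure(reference, "results/structures/wl_reference.pdb")
write_structure(query, "results/structures/frl_query.pdb")

writeLines(c(">J1", seq_J, ">J2", seq_J2),
           "results/sequences/psaJ_paralogs.fasta")
writeLines(c(">P1", seq_P, ">P2", seq_P2),
           "results/sequences/core_paralogs.fasta")

jsonlite::write_json(
  list(reference = ref_build$truth[c("pigments", "pairs", "components")],
       query = qry_build$truth[c("pigments", "donors", "pairs")],
       planted = list(lost_sites = c("A:1118:", "A:1134:"),
                      axial_lost = "A:1121:",
                      donor_sites = c("A:20:", "B:30:", "B:37:"))),
  "results/structures/ground_truth.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat("Built reference (", nrow(reference$atoms), "atoms ) and query (",
    nrow(query$atoms), "atoms ).\n")
cat("Planted: 2 lost sites, 1 lost axial His, donors at A20/B30/B37.\n")
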