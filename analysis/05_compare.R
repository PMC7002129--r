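#!/usr/bin/env Rscript
# Stage 5: homologous-structure comparison. Superposes the far-red query
# onto the white-light reference using paired Calpha atoms only (the
# pigments are the measurement, never fit targets), matches chlorophyll
# sites by nearest-Mg under 2.5 A, transfers reference-style site labels
# (chain letter + last two digits of the reference identifier), and
# tabulates axial-ligand changes.
# Outputs: results/superposition.json, results/correspondence.tsv,
#          results/site_labels.tsv, results/axial_changes.tsv

suppressMessages(library(chlfsites))

ref <- suppressMessages(
  read_structure("results/structures/wl_reference.pdb"))
qry <- suppressMessages(
  read_structure("results/structures/frl_query.pdb"))

pc <- paired_ca_coords(qry, ref, chain_pairing = c(J = "J", P = "P"))
sup <- kabsch_superpose(pc$query, pc$reference)
cat(sprintf("Calpha superposition: n=%d, rmsd=%.3g A\n", sup$n, sup$rmsd))
jsonlite::write_json(list(rotation = sup$rotation,
                          translation = sup$translation,
                          rmsd = sup$rmsd, n = sup$n),
                     "results/superposition.json", digits = NA,
                     matrix = "rowmajor")

mp <- match_pigment_sites(qry, ref, sup)
write.table(mp, "results/correspondence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, na = "")
cat(sprintf("sites: %d conserved, %d lost, %d gained\n",
            sum(mp$status == "conserved"), sum(mp$status == "lost"),
            sum(mp$status == "gained")))

labels <- transfer_site_labels(mp)
write.table(labels, "results/site_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# axial comparison needs both models in the same frame for nothing --
# ligand detection is per-model, so it runs on the native coordinates
ax <- compare_axial_ligands(mp, qry, ref)
write.table(ax, "results/axial_changes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
chg <- ax[ax$changed, ]
cat("axial changes:",
    if (nrow(chg)) paste(sprintf("%s (%s -> %s)",
                                 labels$label[match(chg$query_site,
                                                    labels$query_site)],
                                 chg$reference_class, chg$query_class),
                         collapse = "; ")
    else "none", "\n")
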