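#!/usr/bin/env Rscript
# Stage 3: chlorin geometry. Ring-plane fits, stacked multimer detection
# (Mg-Mg <= 9 A) and axial-ligand inventories for both structures. The
# far-red query should show the stacked trio reduced to a dimer, the
# dimer reduced to a monomer, and the A21 axial His gone.
# Outputs: results/stacking_<model>.tsv, results/axial_<model>.tsv

suppressMessages(library(chlfsites))

for (name in c("wl_reference", "frl_query")) {
  m <- suppressMessages(
    read_structure(file.path("results/structures", paste0(name, ".pdb"))))
  st <- find_stacking_multimers(m)
  write.table(st$pairs, sprintf("results/stacking_%s.tsv", name),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sizes <- table(st$components$size[!duplicated(st$components$component)])
  cat(sprintf("%s multimers:", name))
  for (s in names(sizes)) cat(sprintf(" %d x size-%s", sizes[[s]], s))
  cat("\n")
  chl <- chlorophyll_residues(m)
  ax <- do.call(rbind, lapply(chl$key, function(k) {
    lig <- detect_axial_ligands(m, k)
    if (!nrow(lig)) return(data.frame(site = k, class = "none",
                                      distance = NA_real_))
    data.frame(site = k, class = lig$class[1], distance = lig$distance[1])
  }))
  write.table(ax, sprintf("results/axial_%s.tsv", name), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s axial ligands: %s\n", name,
              paste(sprintf("%s=%s", ax$site, ax$class), collapse = " ")))
}
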