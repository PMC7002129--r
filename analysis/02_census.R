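#!/usr/bin/env Rscript
# Stage 2: pigment cofactor census of both structures.
# Counts residues per pigment class (chlorophylls, carotenoids, quinones,
# lipids, clusters) exactly as deposited -- the far-red query should show
# two fewer chlorophyll sites than the reference.
# Outputs: results/census_<model>.tsv / .json

suppressMessages(library(chlfsites))
dir.create("results", showWarnings = FALSE)

for (name in c("wl_reference", "frl_query")) {
  m <- read_structure(file.path("results/structures",
                                paste0(name, ".pdb")))
  cen <- census(m)
  write_census(cen, tsv = sprintf("results/census_%s.tsv", name),
               json = sprintf("results/census_%s.json", name))
  cat(sprintf("%s: %d chlorophylls, %d cofactor residues total\n",
              name, chlorophyll_total(cen), sum(cen)))
}
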