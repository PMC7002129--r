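#!/usr/bin/env Rscript
# Stage 6: the chlorophyll f site scan. For every chlorophyll in the
# far-red query, scans the C2-substituent environment for hydrogen-bond
# donors and combines three evidence streams -- donor distance, local
# sequence divergence (stage 4) and structural site changes (stage 5) --
# into a ranked candidate table. The planted far-red sites (B30 with its
# Tyr hydroxyl at 2.5 A, A20, B37, A21) should lead the ranking.
# Outputs: results/chlf_candidates.tsv / .json

suppressMessages(library(chlfsites))

qry <- suppressMessages(
  read_structure("results/structures/frl_query.pdb"))
ref <- suppressMessages(
  read_structure("results/structures/wl_reference.pdb"))

env <- read.table("results/environment_identity.tsv", header = TRUE,
                  sep = "\t")
conservation <- setNames(env$environment_identity, env$site)

mp <- read.table("results/correspondence.tsv", header = TRUE, sep = "\t",
                 na.strings = "")
ax <- read.table("results/axial_changes.tsv", header = TRUE, sep = "\t")
flags <- derive_site_change_flags(mp, ax, qry, ref)

labels_df <- read.table("results/site_labels.tsv", header = TRUE,
                        sep = "\t")
labels <- setNames(labels_df$label, labels_df$query_site)

rk <- rank_chlf_candidates(qry, conservation = conservation,
                           site_change = flags, labels = labels)
write_candidates(rk, tsv = "results/chlf_candidates.tsv",
                 json = "results/chlf_candidates.json")
cat("chlorophyll f candidate ranking:\n")
print(rk[, c("site", "n_donors", "min_dist", "conservation",
             "site_change", "score")], digits = 3)
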