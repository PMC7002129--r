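#!/usr/bin/env Rscript
# Stage 7: internal-standard HPLC quantitation. Simulates chromatogram
# sets at the measured far-red pigment stoichiometry (89.1 Chl a, 7.1
# Chl f, 2 phylloquinone, carotenoids at beta-carotene/echinenone 1.82),
# writes the traces as CSV, then runs the full deconvolution ->
# Beer-Lambert -> internal-standard pipeline and renormalizes the
# chlorophyll copies to an assumed 90-chlorophyll total.
# Outputs: results/chromatograms/*.csv, results/stoichiometry.json

suppressMessages(library(chlfsites))
dir.create("results/chromatograms", recursive = TRUE,
           showWarnings = FALSE)

meas <- c(chl_a = 89.1, chl_f = 7.1, phylloquinone = 2,
          beta_carotene = 15.8 * 1.82 / 2.82,
          echinenone = 15.8 / 2.82)
spec <- chromatogram_spec(stoichiometry = meas, noise_frac = 0.01,
                          seed = 7521)
sim <- simulate_chromatogram(spec)
for (wl in names(sim$chromatograms))
  write_chromatogram_csv(sim$chromatograms[[wl]],
                         sprintf("results/chromatograms/channel_%s.csv",
                                 wl))

chroms <- lapply(list.files("results/chromatograms", full.names = TRUE),
                 read_chromatogram_csv)
amounts <- quantify_channels(chroms)
report <- normalize_to_internal_standard(amounts)
print(report)
exp90 <- renormalize_total(report, assumed_total = 90)
cat(sprintf("expected copies at 90 total: Chl a %.1f, Chl f %.2f\n",
            exp90[["chl_a"]], exp90[["chl_f"]]))

jsonlite::write_json(
  list(amounts_umol = as.list(amounts),
       copies_per_monomer = as.list(report$copies),
       ratios = report$ratios,
       expected_at_90_total = as.list(exp90)),
  "results/stoichiometry.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/stoichiometry.json\n")
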