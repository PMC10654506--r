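#!/usr/bin/env Rscript

# Step 3: tiling-pattern statistics on the simulated data from step 1 -- the
# Delaunay match with its bootstrap chance level and the affine-optimal
# retinotopy deviation in both directions (RF -> tissue and tissue -> RF).
# Writes results/tiling/tiling_stats.json.

suppressPackageStartupMessages(library(retinotile))

seed <- 20260929L
out_dir <- "results/tiling"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

rgc_rf <- read_pattern_csv("results/simulation/rgc_rf.csv")
axon <- read_pattern_csv("results/simulation/axon.csv")
sc_soma <- read_pattern_csv("results/simulation/sc_soma.csv")
sc_rf <- read_pattern_csv("results/simulation/sc_rf.csv")

m_axon <- tiling_match(rgc_rf, axon)
m_soma <- tiling_match(sc_soma, sc_rf)
chance <- bootstrap_chance(rgc_rf, axon, repetitions = 10000,
                           seed = derive_seed(seed, "chance"))

# affine-optimal deviations: tissue-space (um) and visual-space (deg)
af_um <- affine_fit(rgc_rf, axon)
af_deg <- affine_fit(axon, rgc_rf)

cat(sprintf("axon-vs-RF match: %.1f%% (chance at p=0.05: %.1f%%)\n",
            m_axon$fraction, chance$threshold))
cat(sprintf("soma-vs-RF match: %.1f%%\n", m_soma$fraction))
cat(sprintf("affine deviation, axons:  %.1f +/- %.1f um (median +/- MAD)\n",
            af_um$summary["median"], af_um$summary["mad"]))
cat(sprintf("affine deviation, RFs:    %.2f +/- %.2f deg\n",
            af_deg$summary["median"], af_deg$summary["mad"]))

jsonlite::write_json(list(
  axon_match = m_axon$fraction,
  soma_match = m_soma$fraction,
  chance_threshold = chance$threshold,
  affine_dev_um = list(median = unname(af_um$summary["median"]),
                       mad = unname(af_um$summary["mad"])),
  affine_dev_deg = list(median = unname(af_deg$summary["median"]),
                        mad = unname(af_deg$summary["mad"])),
  seed = seed
), file.path(out_dir, "tiling_stats.json"), auto_unbox = TRUE, digits = NA)
cat(sprintf("outputs in %s\n", out_dir))
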