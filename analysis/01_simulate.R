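#!/usr/bin/env Rscript

# Stage 1: simulate a synthetic multi-state claims extract.
#
# Writes results/claims/{hospitals.csv, encounters.csv, ground_truth.json}.
# All downstream scripts read these files, so the whole workflow is
# reproducible from this single seeded step.

suppressPackageStartupMessages(library(egsnet))

out_dir <- file.path("results", "claims")
cfg <- sim_config(seed = 20160101)

sim <- simulate_claims(cfg, out_dir)
enc <- sim$simulation$encounters
cat(sprintf("simulated %d encounters for %d patients at %d hospitals\n",
            nrow(enc), length(unique(enc$patient_id)), cfg$n_hospitals))
cat("files:", paste(sort(list.files(out_dir)), collapse = ", "), "\n")
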