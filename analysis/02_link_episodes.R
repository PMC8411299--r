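#!/usr/bin/env Rscript

# Stage 2: link encounters into episodes of care and extract interhospital
# transfers, then restrict to the transfer cohort (adult emergency general
# surgery episodes with at least one transfer).
#
# Reads  results/claims/encounters.csv
# Writes results/episodes/{episodes.csv, transfers.csv, anomalies.csv,
#                          exclusions.csv}

suppressPackageStartupMessages(library(egsnet))

enc <- utils::read.csv(file.path("results", "claims", "encounters.csv"),
                       stringsAsFactors = FALSE)
codes <- read_code_set(egsnet_example("synthetic_code_set.json"))

episodes <- build_episodes(enc, codes)
cohort <- filter_transfer_cohort(episodes)
excl <- attr(cohort, "exclusions")

out_dir <- file.path("results", "episodes")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
utils::write.csv(as.data.frame(cohort$episodes)[
  , setdiff(names(cohort$episodes), "dx_codes")],
  file.path(out_dir, "episodes.csv"), row.names = FALSE)
utils::write.csv(as.data.frame(cohort$transfers),
                 file.path(out_dir, "transfers.csv"), row.names = FALSE)
utils::write.csv(as.data.frame(episodes$anomalies),
                 file.path(out_dir, "anomalies.csv"), row.names = FALSE)
utils::write.csv(data.frame(reason = names(excl), n = as.integer(excl)),
                 file.path(out_dir, "exclusions.csv"), row.names = FALSE)

cat(sprintf("%d episodes -> %d cohort episodes (%d transfers); excluded: %s\n",
            nrow(episodes$episodes), nrow(cohort$episodes),
            nrow(cohort$transfers),
            paste(names(excl), excl, sep = "=", collapse = ", ")))
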