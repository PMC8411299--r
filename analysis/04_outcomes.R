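#!/usr/bin/env Rscript

# Stage 4: episode-level risk models and hospital-level outcome measures:
# emergency-general-surgery volume, risk-adjusted mortality, and
# risk-adjusted failure to rescue, each cut into quartiles.
#
# Reads  results/claims/{encounters.csv, hospitals.csv}
# Writes results/outcomes/hospital_outcomes.csv and risk_models.json

suppressPackageStartupMessages(library(egsnet))

enc <- utils::read.csv(file.path("results", "claims", "encounters.csv"),
                       stringsAsFactors = FALSE)
hospitals <- utils::read.csv(file.path("results", "claims", "hospitals.csv"),
                             stringsAsFactors = FALSE)
codes <- read_code_set(egsnet_example("synthetic_code_set.json"))
comorbidity <- read_comorbidity_table(
  egsnet_example("synthetic_comorbidity_weights.json"))

episodes <- build_episodes(enc, codes)
frame <- episode_outcomes(episodes, codes, comorbidity)
frame <- frame[frame$age >= 18, ]
ho <- hospital_outcomes(frame, hospital_ids = hospitals$hospital_id)

out_dir <- file.path("results", "outcomes")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
utils::write.csv(as.data.frame(ho), file.path(out_dir, "hospital_outcomes.csv"),
                 row.names = FALSE)

summarize_model <- function(m) {
  if (is.null(m)) return(NULL)
  list(outcome = m$outcome, n = nrow(m$eligible), overall_rate = m$overall_rate,
       coefficients = as.list(stats::coef(m$fit)))
}
jsonlite::write_json(
  list(death = summarize_model(attr(ho, "death_model")),
       ftr = summarize_model(attr(ho, "ftr_model"))),
  file.path(out_dir, "risk_models.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

dm <- attr(ho, "death_model")
cat(sprintf("%d adult EGS episodes; crude mortality %.4f; FTR rate %.4f\n",
            nrow(frame), dm$overall_rate,
            attr(ho, "ftr_model")$overall_rate))
cat(sprintf("hospital EGS volume: median %d (IQR %d-%d)\n",
            stats::median(ho$egs_volume),
            stats::quantile(ho$egs_volume, 0.25, type = 7),
            stats::quantile(ho$egs_volume, 0.75, type = 7)))
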