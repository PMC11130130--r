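#!/usr/bin/env Rscript
# Stage 2: apply the cleaning rules (Bonferroni yield outliers, 4-SD /
# hard-cap density and fertilizer rules, missing geolocation or nutrient
# data, atypical sowing dates) with first-match-wins attribution.

suppressPackageStartupMessages(library(maizegap))

survey <- read_survey("results/synthetic_survey.csv")
out <- apply_qc(survey, qc_rules())
write_fixture(out$records, "results/clean_survey.csv")
jsonlite::write_json(
  list(n_in = out$report$n_in, n_out = out$report$n_out,
       removed = as.list(out$report$removed),
       thresholds = out$report$thresholds),
  "results/qc_report.json", auto_unbox = TRUE, digits = NA)

print(out$report)
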