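#!/usr/bin/env Rscript
# Stage 1: draw the synthetic smallholder survey used by the whole analysis.
# The generator encodes the study conditions: four technology levels with
# expected yields 1.8 / 2.9 / 3.6 / 4.3 t/ha, climate-zone and year random
# intercepts (SD 0.15 / 0.10 on the sqrt scale), and N-P rates correlated at
# r = 0.72. The survey is drawn at the deposited database's scale: 25 zones
# x 590 fields = 14,750 fields.

suppressPackageStartupMessages(library(maizegap))
dir.create("results", showWarnings = FALSE)

truth <- truth_spec(fields_per_zone = 590, seed = 42)
survey <- generate_survey(truth)
write_fixture(survey, "results/synthetic_survey.csv")
write.csv(truth_summary(truth), "results/truth_level_means.csv",
          row.names = FALSE)

cc <- complete.cases(survey$n_rate, survey$p_rate)
cat(sprintf("simulated %d fields in %d zones across %d regions\n",
            nrow(survey), length(unique(survey$zone_code)),
            length(unique(survey$region))))
cat(sprintf("realized N-P correlation: %.3f (target 0.72)\n",
            cor(survey$n_rate[cc], survey$p_rate[cc])))
cat("true level means (t/ha):",
    paste(round(truth_summary(truth)$mean_yield, 2), collapse = " / "), "\n")
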