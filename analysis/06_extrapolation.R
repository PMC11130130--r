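#!/usr/bin/env Rscript
# Stage 6: extrapolation safeguards. A gradient-boosted model over
# management and environment feeds per-field SHAP attributions (checked for
# additivity); spatially matched folds support honest cross-validation; and
# the environmental dissimilarity index bounds where predictions apply
# (index below 40%).

suppressPackageStartupMessages(library(maizegap))

zoned <- read_survey("results/zoned_survey.csv")
feats <- c("n_rate", "p_rate", "plant_density", "sowing_dev", "cultivar",
           "placement", "weedings", "elevation", "season_precip", "clay",
           "ph", "soil_oc")
gbm <- fit_yield_gbm(zoned, "yield_t_ha", feats, seed = 42)
chk <- shap_additivity_check(gbm, tolerance = 1e-6)
cat(sprintf("SHAP additivity: %s (max |residual| = %.2g)\n",
            if (chk$pass) "holds" else "VIOLATED", chk$max_abs_residual))
sv <- shap_values(gbm)
write.csv(shap_trend(sv, "n_rate", zoned$yield_t_ha * 0 + zoned$n_rate,
                     bins = 5),
          "results/shap_n_rate_trend.csv", row.names = FALSE)

sub <- zoned[!is.na(zoned$lon) & !is.na(zoned$lat), ][1:1000, ]
folds <- nndm_folds(sub[, c("lon", "lat")], k = 5, seed = 42)
cat(sprintf("NNDM folds: %s selected, sizes %s\n",
            attr(folds, "candidate"),
            paste(table(folds), collapse = "/")))

env_cols <- c("elevation", "season_precip", "clay", "ph", "soil_oc", "ecec")
env <- zoned[complete.cases(zoned[, env_cols]), env_cols]
set.seed(42)
ref_idx <- sample(nrow(env), 2000)
# pairwise normalization: the applicability convention for map predictions
cfg <- di_config(env[ref_idx, ], threshold = 0.40, norm = "pairwise")
di <- dissimilarity_index(env[-ref_idx, ], cfg)
cat(sprintf("dissimilarity of held-out fields: median %.2f, %.0f%% inside the area of applicability\n",
            median(di), 100 * mean(applicability_mask(di, cfg))))
write.csv(data.frame(di = di, applicable = applicability_mask(di, cfg)),
          "results/dissimilarity.csv", row.names = FALSE)
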