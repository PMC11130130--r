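#!/usr/bin/env Rscript
# Stage 4: one conditional inference tree per eligible stratum (management
# practices plus environmental covariates as candidates), summarized as the
# proportion of zones in which each practice splits a tree - the
# relative-importance statistic - and as practice-type shares per region.

suppressPackageStartupMessages(library(maizegap))

zoned <- read_survey("results/zoned_survey.csv")
cand <- default_candidates()
strata <- unique(zoned$stratum[zoned$eligible])

trees <- lapply(strata, function(s) {
  d <- zoned[zoned$stratum == s, ]
  grow_tree(d, "yield_t_ha", c(cand$practices, cand$covariates),
            cit_params(nrow(d)))
})
names(trees) <- strata

imp <- relative_importance(trees, cand$practices, cand$covariates)
write.csv(imp, "results/importance.csv", row.names = FALSE)

region_of <- vapply(strata, function(s)
  zoned$region[zoned$stratum == s][1], character(1))
by_region <- lapply(split(names(trees), region_of), function(zs)
  relative_importance(trees[zs], cand$practices))
shares <- importance_by_type(by_region, practice_types())
write.csv(shares, "results/importance_by_type.csv", row.names = FALSE)

imp_p <- imp[imp$role == "practice", ]
imp_p <- imp_p[order(-imp_p$importance), ]
cat("top practices by relative importance:\n")
print(head(imp_p[, c("variable", "n_split", "n_evaluable", "importance")], 6),
      row.names = FALSE)
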