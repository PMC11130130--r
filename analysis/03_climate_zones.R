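#!/usr/bin/env Rscript
# Stage 3: drop spatially isolated sites within each climate zone and flag
# the zone x season strata with enough fields (> 200) for a per-zone
# analysis. Ineligible fields are kept but excluded from the stratified
# models.

suppressPackageStartupMessages(library(maizegap))

clean <- read_survey("results/clean_survey.csv")
kept <- filter_isolated(clean)
cat(sprintf("isolation filter: %d of %d fields retained\n",
            nrow(kept), nrow(clean)))

strata <- select_strata(kept, min_n = 200)
kept$stratum <- strata$stratum
kept$eligible <- strata$eligible
write_fixture(kept, "results/zoned_survey.csv")

tab <- as.data.frame(table(stratum = strata$stratum,
                           eligible = strata$eligible))
tab <- tab[tab$Freq > 0, ]
write.csv(tab, "results/strata.csv", row.names = FALSE)
cat(sprintf("%d of %d strata eligible (more than 200 fields)\n",
            length(unique(strata$stratum[strata$eligible])),
            length(unique(strata$stratum))))
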