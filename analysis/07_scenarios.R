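#!/usr/bin/env Rscript
# Stage 7: 2050 self-sufficiency assessment on a fixed 40 Mha maize area.
# Scenario yields come from the shipped config: 2.7 t/ha if the historical
# gain rate (27 kg/ha/yr) persists, 4.2 t/ha if yield-gap closure reaches
# the level achieved by the high-technology farmers.

suppressPackageStartupMessages(library(maizegap))

inputs <- scenario_inputs_yaml(system.file("extdata", "ssa2050.yaml",
                                           package = "maizegap"))
tab <- scenario_table(inputs)
rounded <- round_scenario_table(tab)
write.csv(rounded, "results/scenario_table.csv", row.names = FALSE)

print(rounded, row.names = FALSE)
cat(sprintf("\nyield gap: %.1f t/ha; accelerated closure equivalent to %.0f%% of it\n",
            yield_gap(inputs$yield_potential, 1.7),
            100 * (4.2 - 1.7) / yield_gap(inputs$yield_potential, 1.7)))
cat(sprintf("demand is projected to grow %.1f-fold by 2050\n",
            inputs$demand_2050 / inputs$current_demand))
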