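# a technology-leveled dataset whose zone x year cells are identical copies
# of one block: between-zone and between-year variance are exactly zero, so
# the REML variance components land on the boundary and the mixed model
# must reduce to ordinary least squares
degenerate_leveled <- function(level_yields = c(1.8, 2.9, 3.6, 4.3)) {
  levels <- c("baseline", "HN", "HNP", "HNPS")
  m <- sqrt(level_yields)
  grid <- expand.grid(zone = paste0("Z", 1:3), year = 2016:2018,
                      level = levels, e = c(-0.1, 0, 0.1),
                      stringsAsFactors = FALSE)
  data.frame(yield_t_ha = (m[match(grid$level, levels)] + grid$e)^2,
             tech_level = grid$level, zone_code = grid$zone,
             year = grid$year, stringsAsFactors = FALSE)
}
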