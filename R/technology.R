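#' Tercile cutpoints
#'
#' Empirical 1/3 and 2/3 quantiles (type-7 by default, the documented
#' convention for all tercile splits in this package).
#' @param values numeric vector with at least 3 non-missing values.
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return numeric `c(lower, upper)`.
#' @export
tercile_cutpoints <- function(values, type = 7) {
  v <- values[!is.na(values)]
  if (length(v) < 3L) stop_named("need at least 3 non-missing values")
  stats::quantile(v, c(1 / 3, 2 / 3), type = type, names = FALSE)
}

#' Technology levels
#' @return the level labels, in increasing technology order plus
#'   "unclassified".
#' @export
tech_levels <- function() c("baseline", "HN", "HNP", "HNPS", "unclassified")

#' Assign technology levels to fields
#'
#' The four compared groups combine cultivar, N fertilizer, plant density
#' and sowing date:
#' * `baseline` - OPV, low N, low density, sown on the zone average date or
#'   later;
#' * `HN` - hybrid, high N, low density, average-or-late sowing;
#' * `HNP` - hybrid, high N, high density, average-or-late sowing;
#' * `HNPS` - hybrid, high N, high density, early sowing.
#'
#' With the default `rule = "fig5"` the category boundaries are the fixed
#' published ones: low N below 14 and high N above 42 kg/ha, low density
#' below 3 and high density above 4 plants/m2, late sowing a deviation of 0
#' days or more and early sowing more than 9 days before the zone-season
#' average. `rule = "tercile"` replaces the N, density and early-sowing
#' boundaries with the pooled tercile cutpoints of the data (late remains
#' "deviation >= 0"). Fields in the middle category of any defining
#' variable, or missing one, are `unclassified`.
#'
#' @param records data.frame with `cultivar`, `n_rate`, `plant_density`,
#'   `sowing_dev`.
#' @param rule `"fig5"` (fixed boundaries) or `"tercile"`.
#' @param cutpoints optional list with elements `n_rate`, `plant_density`,
#'   `sowing_dev`, each `c(lower, upper)` tercile cutpoints; computed from
#'   `records` when NULL and `rule = "tercile"`.
#' @return factor with levels [tech_levels()].
#' @export
assign_level <- function(records, rule = c("fig5", "tercile"),
                         cutpoints = NULL) {
  rule <- match.arg(rule)
  need <- c("cultivar", "n_rate", "plant_density", "sowing_dev")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop_named("records lack column(s): %s",
               paste(missing_cols, collapse = ", "))

  if (rule == "fig5") {
    bounds <- list(n_rate = c(14, 42), plant_density = c(3, 4),
                   sowing_dev = c(-9, NA))
  } else {
    if (is.null(cutpoints))
      cutpoints <- list(n_rate = tercile_cutpoints(records$n_rate),
                        plant_density = tercile_cutpoints(records$plant_density),
                        sowing_dev = tercile_cutpoints(records$sowing_dev))
    bounds <- list(n_rate = cutpoints$n_rate,
                   plant_density = cutpoints$plant_density,
                   sowing_dev = c(cutpoints$sowing_dev[1], NA))
  }

  hyb <- records$cultivar == "hybrid"
  low_n <- records$n_rate < bounds$n_rate[1]
  high_n <- records$n_rate > bounds$n_rate[2]
  low_d <- records$plant_density < bounds$plant_density[1]
  high_d <- records$plant_density > bounds$plant_density[2]
  late <- records$sowing_dev >= 0
  early <- records$sowing_dev < bounds$sowing_dev[1]

  lev <- rep("unclassified", nrow(records))
  miss <- is.na(hyb) | is.na(records$n_rate) |
    is.na(records$plant_density) | is.na(records$sowing_dev)
  set <- function(cond) !miss & !is.na(cond) & cond
  lev[set(!hyb & low_n & low_d & late)] <- "baseline"
  lev[set(hyb & high_n & low_d & late)] <- "HN"
  lev[set(hyb & high_n & high_d & late)] <- "HNP"
  lev[set(hyb & high_n & high_d & early)] <- "HNPS"
  factor(lev, levels = tech_levels())
}
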