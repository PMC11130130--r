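#' Linear yield projection
#'
#' @param y0 starting yield (t/ha).
#' @param rate yield gain (t/ha per year); the historical regional rate is
#'   0.027.
#' @param years projection horizon.
#' @return `y0 + rate * years`.
#' @export
project_yield_linear <- function(y0, rate, years) {
  stopifnot(y0 >= 0, rate >= 0, years >= 0)
  y0 + rate * years
}

#' Yield implied by a level of yield-gap closure
#'
#' @param ya actual yield (t/ha).
#' @param yp yield potential (t/ha), `yp >= ya`.
#' @param closure fraction of the gap closed, in \[0, 1\].
#' @return `ya + closure * (yp - ya)`.
#' @export
yield_from_gap_closure <- function(ya, yp, closure) {
  if (any(yp < ya)) stop_named("'yp' must be >= 'ya'")
  stopifnot(closure >= 0, closure <= 1)
  ya + closure * (yp - ya)
}

#' Yield gap
#' @param yp yield potential (t/ha).
#' @param ya actual yield (t/ha), `ya <= yp`.
#' @return `yp - ya` (t/ha).
#' @export
yield_gap <- function(yp, ya) {
  if (any(yp < ya)) stop_named("'yp' must be >= 'ya'")
  yp - ya
}

#' Projected demand in 2050
#'
#' @param percap_now current per-capita demand (kg/person/year).
#' @param rel_change relative change in per-capita demand to 2050 (fraction;
#'   e.g. 0.1 for +10%).
#' @param pop_2050 projected population (persons).
#' @return demand in million tonnes.
#' @export
demand_2050 <- function(percap_now, rel_change, pop_2050) {
  stopifnot(percap_now > 0, pop_2050 > 0)
  percap_now * (1 + rel_change) * pop_2050 / 1e9
}

#' Scenario inputs
#'
#' Quantities behind the self-sufficiency assessment: a fixed maize area,
#' current yield/production/demand (external statistics taken as inputs),
#' projected 2050 demand, the historical yield-gain rate, and either
#' explicit 2050 scenario yields or a gap-closure fraction with the yield
#' potential.
#'
#' @param area_mha maize area, million ha (held fixed; default 40).
#' @param current_yield t/ha (default 2).
#' @param current_production,current_demand Mt (defaults 80 and 79).
#' @param demand_2050 Mt (default 184).
#' @param gain_rate t/ha/yr (default 0.027).
#' @param horizon_years projection horizon (default 30).
#' @param yield_potential t/ha (default 10.6).
#' @param gap_closure fraction used for the acceleration scenario when its
#'   yield is not given explicitly.
#' @param scenario_yields_2050 optional named overrides
#'   `c(same_rate = , acceleration = )` for the 2050 yields (t/ha).
#' @export
scenario_inputs <- function(area_mha = 40, current_yield = 2,
                            current_production = 80, current_demand = 79,
                            demand_2050 = 184, gain_rate = 0.027,
                            horizon_years = 30, yield_potential = 10.6,
                            gap_closure = NULL,
                            scenario_yields_2050 = c(same_rate = 2.7,
                                                     acceleration = 4.2)) {
  vals <- c(area_mha, current_yield, current_production, current_demand,
            demand_2050, gain_rate, horizon_years, yield_potential)
  if (any(vals < 0)) stop_named("all scenario inputs must be >= 0")
  if (!is.null(gap_closure) && (gap_closure < 0 || gap_closure > 1))
    stop_named("'gap_closure' must be in [0, 1]")
  structure(list(area_mha = area_mha, current_yield = current_yield,
                 current_production = current_production,
                 current_demand = current_demand,
                 demand_2050 = demand_2050, gain_rate = gain_rate,
                 horizon_years = horizon_years,
                 yield_potential = yield_potential,
                 gap_closure = gap_closure,
                 scenario_yields_2050 = scenario_yields_2050),
            class = "scenario_inputs")
}

#' Read scenario inputs from a YAML config
#' @param path YAML file with the [scenario_inputs()] fields.
#' @export
scenario_inputs_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  sy <- cfg$scenario_yields_2050
  do.call(scenario_inputs, c(
    cfg[setdiff(names(cfg), "scenario_yields_2050")],
    if (!is.null(sy)) list(scenario_yields_2050 = unlist(sy))))
}

#' Self-sufficiency scenario table
#'
#' One row per scenario (current situation, same rate of yield gain to 2050,
#' acceleration of yield gain), with the identities holding exactly at full
#' precision: production = yield x area, SSR = production / demand, balance
#' = production - demand, and the extra land needed to cover a deficit at
#' the scenario's own yield, `max(0, -balance) / yield`. Rounding is applied
#' only by [round_scenario_table()].
#'
#' @param inputs a [scenario_inputs()].
#' @return data.frame: `scenario`, `yield_t_ha`, `production_mt`,
#'   `demand_mt`, `ssr`, `balance_mt`, `extra_land_mha`.
#' @export
scenario_table <- function(inputs) {
  stopifnot(inherits(inputs, "scenario_inputs"))
  sy <- inputs$scenario_yields_2050 %||% c(same_rate = NA_real_,
                                           acceleration = NA_real_)
  same_rate <- unname(sy["same_rate"])
  if (is.na(same_rate))
    same_rate <- project_yield_linear(inputs$current_yield, inputs$gain_rate,
                                      inputs$horizon_years)
  accel <- unname(sy["acceleration"])
  if (is.na(accel)) {
    if (is.null(inputs$gap_closure))
      stop_named("need either an acceleration yield or 'gap_closure'")
    accel <- yield_from_gap_closure(inputs$current_yield,
                                    inputs$yield_potential,
                                    inputs$gap_closure)
  }
  yields <- c(current = inputs$current_yield,
              same_rate = unname(same_rate), acceleration = unname(accel))
  demand <- c(inputs$current_demand, inputs$demand_2050, inputs$demand_2050)
  if (any(demand <= 0)) stop_named("demand must be > 0")
  production <- yields * inputs$area_mha
  balance <- production - demand
  data.frame(scenario = names(yields), yield_t_ha = unname(yields),
             production_mt = unname(production), demand_mt = demand,
             ssr = unname(production / demand), balance_mt = unname(balance),
             extra_land_mha = unname(pmax(0, -balance) / yields),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Presentation rounding for a scenario table
#'
#' Yields and SSR to one decimal; production, demand, balance and extra land
#' to whole million tonnes / hectares.
#' @param tab a [scenario_table()] result.
#' @export
round_scenario_table <- function(tab) {
  tab$yield_t_ha <- round(tab$yield_t_ha, 1)
  tab$ssr <- round(tab$ssr, 1)
  for (col in c("production_mt", "demand_mt", "balance_mt",
                "extra_land_mha"))
    tab[[col]] <- round(tab[[col]])
  tab
}
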