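#' Specification of the synthetic survey truth
#'
#' Defines the data-generating process for a synthetic smallholder maize
#' survey with the statistical structure the downstream analysis assumes:
#' known management effects on the square-root yield scale, climate-zone and
#' year random intercepts, correlated N and P fertilizer rates, and per-column
#' missingness. Because the truth is known, every downstream stage (quality
#' control, zonation, trees, mixed model) can be tested for parameter
#' recovery.
#'
#' The four key practices (cultivar, N rate, plant density, sowing date) act
#' on sqrt(yield) through step responses at the adoption-category thresholds
#' (hybrid vs OPV; N above 42 kg/ha; density above 4 plants/m2; sowing more
#' than 9 days before the zone average). With step responses, the expected
#' yield of each technology level is exactly specifiable through
#' `level_means`. Optional linear slope terms (default 0) are available for
#' tests that need smooth dose-response structure.
#'
#' Management practice distributions follow a latent adoption-class mixture
#' (traditional, improved nutrition, + density, + early sowing, mixed),
#' reflecting that technology adoption is bundled in these systems; this also
#' gives each technology level a realistic share of fields. N and P rates are
#' generated from a latent log-scale regression calibrated so their Pearson
#' correlation is close to `np_correlation` (default 0.72).
#'
#' @param level_means target expected yield (t/ha, back-transform convention
#'   `(E sqrt yield)^2`) for the four technology levels baseline, HN, HNP,
#'   HNPS. Default `c(1.8, 2.9, 3.6, 4.3)`.
#' @param hybrid_effect_share fraction of the baseline-to-HN sqrt-scale step
#'   attributed to the hybrid cultivar main effect.
#' @param interaction_share fraction of that step attributed to the hybrid x
#'   high-N synergy (the benefit of a hybrid is largest when N supply is
#'   high); the remainder is the high-N main effect. Because every
#'   technology level above baseline combines hybrid with high N, the
#'   decomposition leaves the level means untouched.
#' @param slope_n,slope_p,slope_density,slope_sowing optional linear effects
#'   per unit of the raw variable on the sqrt-yield scale (default 0).
#' @param effect_placement_hole,effect_weeding,effect_pesticide sqrt-scale
#'   effects of in-hole fertilizer placement, each weeding operation, and
#'   pesticide use (defaults 0: these act as null practices).
#' @param sd_zone,sd_year,sd_resid standard deviations (sqrt-yield scale) of
#'   the zone random intercept, year random intercept, and residual.
#' @param np_correlation target Pearson correlation of N and P rates.
#' @param n_zones,fields_per_zone number of climate zones and fields per zone.
#' @param years calendar years sampled uniformly.
#' @param missingness named list of per-column missing-completely-at-random
#'   rates.
#' @param outlier_site_rate fraction of fields whose coordinates are displaced
#'   far from their zone cluster (to exercise the isolation filter).
#' @param seed integer seed; `generate_survey()` is deterministic given it.
#' @return object of class `truth_spec`.
#' @seealso [generate_survey()], [truth_summary()]
#' @export
truth_spec <- function(level_means = c(1.8, 2.9, 3.6, 4.3),
                       hybrid_effect_share = 0.45,
                       interaction_share = 0.25,
                       slope_n = 0, slope_p = 0,
                       slope_density = 0, slope_sowing = 0,
                       effect_placement_hole = 0,
                       effect_weeding = 0,
                       effect_pesticide = 0,
                       sd_zone = 0.15, sd_year = 0.10, sd_resid = 0.15,
                       np_correlation = 0.72,
                       n_zones = 25, fields_per_zone = 200,
                       years = 2016:2022,
                       missingness = NULL,
                       outlier_site_rate = 0.004,
                       seed = 1L) {
  if (length(level_means) != 4L || any(level_means <= 0))
    stop_named("invalid truth_spec: 'level_means' must be 4 positive yields")
  if (any(diff(level_means) < 0))
    stop_named("invalid truth_spec: 'level_means' must be non-decreasing")
  for (nm in c("sd_zone", "sd_year", "sd_resid")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_named("invalid truth_spec: '%s' must be a single value >= 0", nm)
  }
  if (!is.numeric(np_correlation) || abs(np_correlation) > 1)
    stop_named("invalid truth_spec: 'np_correlation' must be in [-1, 1]")
  if (n_zones < 1 || fields_per_zone < 1)
    stop_named("invalid truth_spec: 'n_zones' and 'fields_per_zone' must be >= 1")
  if (hybrid_effect_share < 0 || interaction_share < 0 ||
      hybrid_effect_share + interaction_share > 1)
    stop_named(paste("invalid truth_spec: 'hybrid_effect_share' and",
                     "'interaction_share' must be >= 0 and sum to <= 1"))
  if (!is.null(missingness)) {
    rates <- unlist(missingness)
    if (!is.list(missingness) ||
        (length(missingness) > 0 && is.null(names(missingness))) ||
        any(rates < 0) || any(rates > 1))
      stop_named("invalid truth_spec: 'missingness' must be a named list of rates in [0, 1]")
  } else {
    missingness <- list(row_spacing = 0.10, pesticide_used = 0.08,
                        weedings = 0.05, compost_rate = 0.05,
                        twi = 0.05, pawhc = 0.05,
                        lon = 0.02, lat = 0.02,
                        n_rate = 0.02, p_rate = 0.02)
  }

  sq <- sqrt(level_means)
  spec <- list(
    level_means = level_means,
    base_sqrt = sq[1],
    effect_hybrid = hybrid_effect_share * (sq[2] - sq[1]),
    effect_interaction = interaction_share * (sq[2] - sq[1]),
    effect_high_n = (1 - hybrid_effect_share - interaction_share) *
      (sq[2] - sq[1]),
    effect_high_density = sq[3] - sq[2],
    effect_early_sowing = sq[4] - sq[3],
    slope_n = slope_n, slope_p = slope_p,
    slope_density = slope_density, slope_sowing = slope_sowing,
    effect_placement_hole = effect_placement_hole,
    effect_weeding = effect_weeding,
    effect_pesticide = effect_pesticide,
    sd_zone = sd_zone, sd_year = sd_year, sd_resid = sd_resid,
    np_correlation = np_correlation,
    n_zones = as.integer(n_zones),
    fields_per_zone = as.integer(fields_per_zone),
    years = as.integer(years),
    missingness = missingness,
    outlier_site_rate = outlier_site_rate,
    seed = as.integer(seed)
  )
  class(spec) <- "truth_spec"
  spec
}

# latent log-scale regression coefficient for a target Pearson correlation of
# the (lognormal-mixture) N and P rates; mapping calibrated once by simulation
np_latent_slope <- function(r_target) {
  b <- c(0.00, 0.20, 0.35, 0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80, 0.85)
  r <- c(0.00, 0.15, 0.27, 0.40, 0.45, 0.51, 0.57, 0.64, 0.72, 0.82, 0.94)
  s <- sign(r_target)
  s * stats::approx(r, b, xout = min(abs(r_target), max(r)), rule = 2)$y
}

# region layout: name, season regime, and a rough bounding box (degrees)
region_table <- function() {
  data.frame(
    region = c("NG", "RW-BI", "ZM", "TZ", "UG-KE"),
    seasons = c("single", "second", "single", "single", "two"),
    lon_min = c(6.0, 29.0, 27.0, 33.0, 33.5),
    lon_max = c(10.0, 30.8, 30.0, 36.0, 35.5),
    lat_min = c(8.0, -4.4, -15.5, -10.5, -0.5),
    lat_max = c(11.0, -1.2, -13.0, -7.5, 1.8),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic smallholder maize survey
#'
#' Draws a field-level survey table from the data-generating process defined
#' by a [truth_spec()]: management practices from an adoption-class mixture,
#' correlated N-P rates, zone/year random intercepts (centred so the
#' population intercept is identifiable), environmental covariates with
#' zone-level structure, clustered coordinates with a few planted remote
#' sites, and sqrt-scale yields truncated at zero. Missing values are
#' inserted completely at random per column at the spec's rates.
#'
#' @param truth a [truth_spec()].
#' @param n_fields optional total field count overriding
#'   `n_zones * fields_per_zone` (zones keep equal shares).
#' @return a `data.frame` with one row per field (see [survey_schema()]),
#'   including the zone assignment columns `zone_code`, `season`, `stratum`
#'   and the latent `adoption_class` (kept for diagnostics; not a survey
#'   variable).
#' @export
generate_survey <- function(truth, n_fields = NULL) {
  if (!inherits(truth, "truth_spec")) stop_named("'truth' must be a truth_spec")
  set.seed(truth$seed)

  n_zones <- truth$n_zones
  per_zone <- if (is.null(n_fields)) truth$fields_per_zone else
    as.integer(ceiling(n_fields / n_zones))
  n <- n_zones * per_zone

  regions <- region_table()
  zone_region <- regions$region[((seq_len(n_zones) - 1L) %% nrow(regions)) + 1L]
  zone_code <- sprintf("Z%02d", seq_len(n_zones))

  # zone spatial clusters inside the region bounding boxes
  ridx <- match(zone_region, regions$region)
  zc_lon <- stats::runif(n_zones, regions$lon_min[ridx], regions$lon_max[ridx])
  zc_lat <- stats::runif(n_zones, regions$lat_min[ridx], regions$lat_max[ridx])

  u_zone <- stats::rnorm(n_zones, 0, truth$sd_zone)
  u_zone <- u_zone - mean(u_zone)                # centred: intercept identifiable
  u_year <- stats::rnorm(length(truth$years), 0, truth$sd_year)
  u_year <- u_year - mean(u_year)

  zone <- rep(seq_len(n_zones), each = per_zone)
  region <- zone_region[zone]
  year <- sample(truth$years, n, replace = TRUE)

  season <- rep("single", n)
  season[region == "RW-BI"] <- "second"
  two <- region == "UG-KE"
  season[two] <- sample(c("first", "second"), sum(two), replace = TRUE)

  # latent adoption classes drive bundles of practices
  classes <- c("traditional", "hn", "hnp", "hnps", "mixed")
  cls <- sample(classes, n, replace = TRUE, prob = c(.22, .22, .20, .16, .20))

  mu_n <- c(traditional = log(7), hn = log(65), hnp = log(65),
            hnps = log(65), mixed = log(25))
  sg_n <- c(traditional = 0.7, hn = 0.5, hnp = 0.5, hnps = 0.5, mixed = 0.8)
  log_n <- stats::rnorm(n, mu_n[cls], sg_n[cls])
  n_rate <- exp(log_n)

  b <- np_latent_slope(truth$np_correlation)
  se_p <- sqrt(max(0.95^2 - b^2 * 1.19, 0.01))
  p_rate <- exp(log(8) + b * (log_n - 3.49) + stats::rnorm(n, 0, se_p))

  p_hyb <- c(traditional = .10, hn = .90, hnp = .90, hnps = .90, mixed = .50)
  cultivar <- ifelse(stats::runif(n) < p_hyb[cls], "hybrid", "OPV")

  mu_d <- c(traditional = log(2.4), hn = log(2.4), hnp = log(5),
            hnps = log(5), mixed = log(3.4))
  sg_d <- c(traditional = .30, hn = .30, hnp = .25, hnps = .25, mixed = .35)
  plant_density <- pmin(exp(stats::rnorm(n, mu_d[cls], sg_d[cls])), 12)

  mu_s <- c(traditional = 4, hn = 4, hnp = 4, hnps = -14, mixed = 0)
  sg_s <- c(traditional = 10, hn = 10, hnp = 10, hnps = 8, mixed = 12)
  sowing_dev <- stats::rnorm(n, mu_s[cls], sg_s[cls])

  improved <- cls %in% c("hn", "hnp", "hnps")
  placement <- character(n)
  placement[improved] <- sample(c("hole", "broadcast", "none"),
                                sum(improved), TRUE, prob = c(.60, .35, .05))
  placement[cls == "traditional"] <- sample(c("hole", "broadcast", "none"),
                                            sum(cls == "traditional"), TRUE,
                                            prob = c(.20, .40, .40))
  placement[cls == "mixed"] <- sample(c("hole", "broadcast", "none"),
                                      sum(cls == "mixed"), TRUE,
                                      prob = c(.40, .40, .20))

  weedings <- sample(c("0", "1", "2+"), n, TRUE, prob = c(.15, .45, .40))
  pesticide_used <- stats::runif(n) < ifelse(improved, .50, .20)
  compost_used <- stats::runif(n) < .40
  compost_has_manure <- compost_used & stats::runif(n) < .60
  compost_rate <- ifelse(compost_used, exp(stats::rnorm(n, log(1.5), .6)), 0)
  row_spacing <- stats::rnorm(n, 75, 8)
  field_size <- exp(stats::rnorm(n, log(.3), .6))
  pest_affected <- stats::runif(n) < .25
  disease_affected <- stats::runif(n) < .15
  striga <- stats::runif(n) < .08

  # coordinates: per-zone Gaussian cluster + planted remote outliers
  lon <- zc_lon[zone] + stats::rnorm(n, 0, 0.25)
  lat <- zc_lat[zone] + stats::rnorm(n, 0, 0.25)
  is_out <- stats::runif(n) < truth$outlier_site_rate
  lon[is_out] <- lon[is_out] + sample(c(-1, 1), sum(is_out), TRUE) *
    stats::runif(sum(is_out), 8, 15)

  # environmental covariates with zone-level structure
  z_elev <- stats::runif(n_zones, 500, 2000)
  z_clay <- stats::runif(n_zones, 15, 45)
  z_ph <- stats::runif(n_zones, 5, 7)
  z_oc <- stats::runif(n_zones, 0.5, 2.5)
  z_ecec <- stats::runif(n_zones, 5, 25)
  z_pawhc <- stats::runif(n_zones, 60, 120)
  zy_precip <- matrix(stats::runif(n_zones * length(truth$years), 500, 1100),
                      n_zones)
  yr_idx <- match(year, truth$years)
  elevation <- z_elev[zone] + stats::rnorm(n, 0, 50)
  season_precip <- zy_precip[cbind(zone, yr_idx)] + stats::rnorm(n, 0, 60)
  f_early <- pmin(pmax(stats::rnorm(n, .30, .04), .1), .5)
  f_flower <- pmin(pmax(stats::rnorm(n, .30, .04), .1), .5)
  precip_early <- season_precip * f_early
  precip_flower <- season_precip * f_flower
  precip_grainfill <- season_precip * pmax(1 - f_early - f_flower - .15, .05)
  clay <- pmin(pmax(z_clay[zone] + stats::rnorm(n, 0, 4), 2), 80)
  ph <- pmin(pmax(z_ph[zone] + stats::rnorm(n, 0, .25), 3.5), 9)
  soil_oc <- pmax(z_oc[zone] + stats::rnorm(n, 0, .3), .1)
  ecec <- pmax(z_ecec[zone] + stats::rnorm(n, 0, 2.5), 1)
  pawhc <- pmax(z_pawhc[zone] + stats::rnorm(n, 0, 8), 20)
  twi <- pmax(stats::rnorm(n, 9, 1.8), 2)

  weed_score <- c("0" = 0, "1" = 1, "2+" = 2)[weedings]
  lp <- truth$base_sqrt +
    truth$effect_hybrid * (cultivar == "hybrid") +
    truth$effect_high_n * (n_rate > 42) +
    truth$effect_interaction * (cultivar == "hybrid" & n_rate > 42) +
    truth$effect_high_density * (plant_density > 4) +
    truth$effect_early_sowing * (sowing_dev < -9) +
    truth$slope_n * n_rate + truth$slope_p * p_rate +
    truth$slope_density * plant_density + truth$slope_sowing * sowing_dev +
    truth$effect_placement_hole * (placement == "hole") +
    truth$effect_weeding * weed_score +
    truth$effect_pesticide * pesticide_used
  sqrt_y <- lp + u_zone[zone] + u_year[yr_idx] +
    stats::rnorm(n, 0, truth$sd_resid)
  yield_t_ha <- pmax(sqrt_y, 0)^2              # physical truncation at zero

  out <- data.frame(
    field_id = sprintf("F%06d", seq_len(n)),
    region = region, lon = lon, lat = lat, year = year, season = season,
    zone_code = zone_code[zone],
    stratum = paste(zone_code[zone], season, sep = ":"),
    sowing_dev = sowing_dev, cultivar = cultivar,
    n_rate = n_rate, p_rate = p_rate, placement = placement,
    compost_used = compost_used, compost_has_manure = compost_has_manure,
    compost_rate = compost_rate, plant_density = plant_density,
    row_spacing = row_spacing, weedings = weedings,
    pesticide_used = pesticide_used, pest_affected = pest_affected,
    disease_affected = disease_affected, striga = striga,
    field_size = field_size, yield_t_ha = yield_t_ha,
    elevation = elevation, season_precip = season_precip,
    precip_early = precip_early, precip_flower = precip_flower,
    precip_grainfill = precip_grainfill, clay = clay, ph = ph,
    soil_oc = soil_oc, ecec = ecec, pawhc = pawhc, twi = twi,
    adoption_class = cls,
    stringsAsFactors = FALSE
  )

  for (col in names(truth$missingness)) {
    rate <- truth$missingness[[col]]
    if (rate > 0 && col %in% names(out))
      out[[col]][stats::runif(n) < rate] <- NA
  }
  if (!is.null(n_fields) && n < nrow(out)) out <- out[seq_len(n_fields), ]
  out
}

#' True expected yield per technology level under a truth spec
#'
#' Computes the generator's expected yield for the four technology-level
#' definitions (baseline; hybrid + high N; + high density; + early sowing).
#' The default back-transform convention matches the mixed-model reporting:
#' `(E[sqrt yield | level])^2` at zero random effects; `bias_correct = TRUE`
#' adds the total random variance before squaring.
#'
#' `method = "closed"` uses the exact step-response decomposition and is only
#' available when all slope terms and non-defining practice effects are zero
#' (the default truth); `method = "mc"` evaluates the linear predictor on a
#' large simulated management draw and works for any truth.
#'
#' @param truth a [truth_spec()].
#' @param method `"closed"` or `"mc"`.
#' @param n_mc Monte-Carlo sample size for `method = "mc"`.
#' @param bias_correct add the zone + year + residual variance to the squared
#'   mean (lognormal-style retransformation correction).
#' @return data.frame with columns `level`, `mean_sqrt`, `mean_yield`.
#' @export
truth_summary <- function(truth, method = c("closed", "mc"), n_mc = 1e5,
                          bias_correct = FALSE) {
  if (!inherits(truth, "truth_spec")) stop_named("'truth' must be a truth_spec")
  method <- match.arg(method)
  levels <- c("baseline", "HN", "HNP", "HNPS")

  if (method == "closed") {
    extras <- c(truth$slope_n, truth$slope_p, truth$slope_density,
                truth$slope_sowing, truth$effect_placement_hole,
                truth$effect_weeding, truth$effect_pesticide)
    if (any(extras != 0))
      stop_named(paste("closed form requires zero slopes and zero",
                       "non-defining practice effects; use method = 'mc'"))
    s1 <- truth$effect_hybrid + truth$effect_high_n +
      truth$effect_interaction
    m <- truth$base_sqrt + c(0, s1, s1 + truth$effect_high_density,
                             s1 + truth$effect_high_density +
                               truth$effect_early_sowing)
  } else {
    sim <- truth_mc_predictor(truth, n_mc)
    m <- vapply(levels, function(l) mean(sim$lp[sim$level == l]), numeric(1))
  }
  v <- if (bias_correct) truth$sd_zone^2 + truth$sd_year^2 + truth$sd_resid^2 else 0
  data.frame(level = levels, mean_sqrt = as.numeric(m),
             mean_yield = as.numeric(m)^2 + v,
             stringsAsFactors = FALSE)
}

# Monte-Carlo draw of the management linear predictor and level membership,
# reusing the generator (random effects and residual excluded)
truth_mc_predictor <- function(truth, n_mc) {
  big <- truth
  big$fields_per_zone <- as.integer(ceiling(n_mc / big$n_zones))
  big$sd_zone <- 0; big$sd_year <- 0; big$sd_resid <- 0
  big$missingness <- list()
  d <- generate_survey(big)
  lev <- assign_level(d)
  list(lp = sqrt(d$yield_t_ha), level = as.character(lev))
}

#' Survey column classes
#'
#' The delimited-text schema shared by [write_fixture()] and [read_survey()].
#' @return named character vector mapping column name to R storage class.
#' @export
survey_schema <- function() {
  c(field_id = "character", region = "character", lon = "numeric",
    lat = "numeric", year = "integer", season = "character",
    zone_code = "character", stratum = "character", sowing_dev = "numeric",
    cultivar = "character", n_rate = "numeric", p_rate = "numeric",
    placement = "character", compost_used = "logical",
    compost_has_manure = "logical", compost_rate = "numeric",
    plant_density = "numeric", row_spacing = "numeric",
    weedings = "character", pesticide_used = "logical",
    pest_affected = "logical", disease_affected = "logical",
    striga = "logical", field_size = "numeric", yield_t_ha = "numeric",
    elevation = "numeric", season_precip = "numeric",
    precip_early = "numeric", precip_flower = "numeric",
    precip_grainfill = "numeric", clay = "numeric", ph = "numeric",
    soil_oc = "numeric", ecec = "numeric", pawhc = "numeric",
    twi = "numeric", adoption_class = "character")
}

#' Write a survey table to delimited text
#'
#' Comma-delimited, UTF-8, "." decimal separator; missing values are written
#' as the empty string. Round-trips losslessly through [read_survey()].
#' @param records survey data.frame.
#' @param path output file path.
#' @export
write_fixture <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_named("'records' must be a non-empty data.frame")
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a survey table written by [write_fixture()]
#' @param path file path.
#' @return data.frame with the classes of [survey_schema()] (columns absent
#'   from the file are simply absent).
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop_named("survey file not found: %s", path)
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  schema <- survey_schema()
  cls <- ifelse(hdr %in% names(schema), schema[hdr], NA)
  utils::read.csv(path, na.strings = "", colClasses = cls,
                  check.names = FALSE, stringsAsFactors = FALSE)
}
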