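#' Annual growing-degree days
#'
#' Accumulated daily mean temperature above a base temperature.
#' @param tavg_daily numeric vector of daily mean temperatures (degrees C)
#'   covering the year.
#' @param base_temp base temperature, default 0 C.
#' @return degree-days (C-days).
#' @export
growing_degree_days <- function(tavg_daily, base_temp = 0) {
  if (length(tavg_daily) == 0L) stop_named("empty temperature series")
  sum(pmax(tavg_daily - base_temp, 0))
}

#' Aridity index
#'
#' Annual precipitation divided by potential evapotranspiration
#' (dimensionless).
#' @param precip_annual mm.
#' @param pet_annual mm, must be positive.
#' @export
aridity_index <- function(precip_annual, pet_annual) {
  if (any(pet_annual <= 0)) stop_named("'pet_annual' must be > 0")
  precip_annual / pet_annual
}

#' Temperature seasonality
#'
#' Standard deviation of the twelve monthly mean temperatures; the default
#' convention multiplies by 100 (the WorldClim bio4 convention), `"sd"`
#' returns the plain standard deviation.
#' @param tavg_monthly exactly 12 monthly means (degrees C).
#' @param convention `"bio4"` or `"sd"`.
#' @export
temperature_seasonality <- function(tavg_monthly,
                                    convention = c("bio4", "sd")) {
  convention <- match.arg(convention)
  if (length(tavg_monthly) != 12L)
    stop_named("'tavg_monthly' must have exactly 12 values")
  s <- stats::sd(tavg_monthly)
  if (convention == "bio4") 100 * s else s
}

#' Climate-zone scheme
#'
#' Ordered bin edges for growing-degree days, aridity index and temperature
#' seasonality. A zone code is the concatenation of the three class indices
#' ("gdd-ai-ts"). Bins are half-open `[lo, hi)`: a value exactly on an
#' interior edge belongs to the upper bin. The default edges (shipped as a
#' package config) approximate the global yield-gap zonation: GDD classes of
#' 1000 C-days, aridity classes densified below 1, and bio4-convention
#' seasonality classes.
#'
#' @param gdd_edges,ai_edges,ts_edges strictly increasing numeric edges; the
#'   outermost edges bound the admissible range.
#' @param two_season_zones character vector of zone codes treated as zone x
#'   season strata.
#' @export
zone_scheme <- function(gdd_edges, ai_edges, ts_edges,
                        two_season_zones = character()) {
  for (nm in c("gdd_edges", "ai_edges", "ts_edges")) {
    e <- get(nm)
    if (length(e) < 2L || any(diff(e) <= 0))
      stop_named("'%s' must be strictly increasing with >= 2 values", nm)
  }
  structure(list(gdd_edges = gdd_edges, ai_edges = ai_edges,
                 ts_edges = ts_edges,
                 two_season_zones = two_season_zones),
            class = "zone_scheme")
}

#' Default climate-zone scheme from the shipped config
#' @param path YAML file; default the config installed with the package.
#' @export
zone_scheme_default <- function(path = system.file("extdata",
                                                   "zone_scheme.yaml",
                                                   package = "maizegap")) {
  cfg <- yaml::read_yaml(path)
  zone_scheme(as.numeric(unlist(cfg$gdd_edges)),
              as.numeric(unlist(cfg$ai_edges)),
              as.numeric(unlist(cfg$ts_edges)),
              as.character(unlist(cfg$two_season_zones)) %||% character())
}

#' Classify climate summaries into zone codes
#'
#' @param gdd,ai,ts numeric vectors (recycled to common length) of annual
#'   growing-degree days, aridity index and temperature seasonality.
#' @param scheme a [zone_scheme()].
#' @return character vector of zone codes "g-a-t".
#' @export
classify_zone <- function(gdd, ai, ts, scheme) {
  stopifnot(inherits(scheme, "zone_scheme"))
  bin <- function(x, edges, what) {
    i <- findInterval(x, edges)          # edges[i] <= x < edges[i+1]
    bad <- is.na(i) | i < 1L | i >= length(edges)
    if (any(bad))
      stop_named("%s value outside the scheme's edges: %s", what,
                 paste(utils::head(x[bad], 3), collapse = ", "))
    i
  }
  n <- max(length(gdd), length(ai), length(ts))
  gdd <- rep_len(gdd, n); ai <- rep_len(ai, n); ts <- rep_len(ts, n)
  sprintf("%d-%d-%d", bin(gdd, scheme$gdd_edges, "gdd"),
          bin(ai, scheme$ai_edges, "ai"), bin(ts, scheme$ts_edges, "ts"))
}

#' Drop spatially isolated sites within each climate zone
#'
#' For every zone with at least `min_sites` geolocated rows, computes each
#' site's median great-circle distance (km) to the other sites and drops
#' sites whose median distance exceeds the zone median of that statistic by
#' more than three of its standard deviations. Zones with fewer sites, and
#' rows without coordinates, pass through. Row order does not affect which
#' sites are dropped.
#'
#' @param records data.frame with `lon`, `lat` and a zone column.
#' @param zone_col name of the zone column.
#' @param sd_cutoff number of standard deviations, default 3.
#' @param min_sites minimum geolocated sites needed to judge isolation.
#' @return the retained rows of `records`.
#' @export
filter_isolated <- function(records, zone_col = "zone_code", sd_cutoff = 3,
                            min_sites = 3L) {
  stopifnot(is.data.frame(records), zone_col %in% names(records))
  keep <- rep(TRUE, nrow(records))
  geo <- !is.na(records$lon) & !is.na(records$lat)
  for (z in unique(records[[zone_col]])) {
    idx <- which(records[[zone_col]] == z & geo)
    if (length(idx) < min_sites) next
    pts <- cbind(records$lon[idx], records$lat[idx])
    d <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
    # median distance of each site to the *other* sites
    med_i <- vapply(seq_along(idx),
                    function(i) stats::median(d[i, -i]), numeric(1))
    s <- stats::sd(med_i)
    if (is.na(s) || s == 0) next
    keep[idx[med_i > stats::median(med_i) + sd_cutoff * s]] <- FALSE
  }
  records[keep, , drop = FALSE]
}

#' Zone-season stratum eligibility
#'
#' Each record belongs to exactly one zone x season stratum (in two-season
#' zones each crop season is a separate stratum). A stratum is eligible for
#' the per-zone analysis only when it holds strictly more than `min_n`
#' fields; ineligible records are flagged, not deleted.
#'
#' @param records data.frame with zone and season columns.
#' @param min_n minimum field count (strict), default 200.
#' @param zone_col,season_col column names.
#' @return data.frame (one row per record): `zone_code`, `season`,
#'   `stratum`, `eligible`.
#' @export
select_strata <- function(records, min_n = 200, zone_col = "zone_code",
                          season_col = "season") {
  stopifnot(is.data.frame(records), zone_col %in% names(records),
            season_col %in% names(records))
  stratum <- paste(records[[zone_col]], records[[season_col]], sep = ":")
  counts <- table(stratum)
  eligible <- as.vector(counts[stratum] > min_n)
  if (nrow(records) > 0L && !any(eligible))
    warning("no stratum exceeds min_n = ", min_n,
            "; the analysis set is empty", call. = FALSE)
  data.frame(zone_code = records[[zone_col]],
             season = records[[season_col]],
             stratum = stratum, eligible = eligible,
             stringsAsFactors = FALSE)
}

#' Sowing-date deviation from the stratum mean
#'
#' Day-of-year difference between each record's sowing date and its
#' stratum's average sowing date. With `method = "arithmetic"` deviations
#' within a stratum sum to zero exactly; `"circular"` handles seasons that
#' wrap across the December/January boundary via the circular mean;
#' `"auto"` (default) picks circular only when a stratum's dates span more
#' than 300 days.
#'
#' @param sowing_doy day of year (1-366); NAs propagate.
#' @param stratum stratum id per record.
#' @param method `"auto"`, `"arithmetic"` or `"circular"`.
#' @param period days in the year, default 365.
#' @return numeric deviations in days (negative = earlier than average).
#' @export
sowing_deviation <- function(sowing_doy, stratum,
                             method = c("auto", "arithmetic", "circular"),
                             period = 365) {
  method <- match.arg(method)
  stopifnot(length(sowing_doy) == length(stratum))
  dev <- rep(NA_real_, length(sowing_doy))
  for (s in unique(stratum)) {
    idx <- which(stratum == s & !is.na(sowing_doy))
    if (!length(idx)) next
    doy <- sowing_doy[idx]
    use_circ <- switch(method,
                       arithmetic = FALSE,
                       circular = TRUE,
                       auto = diff(range(doy)) > 300)
    if (!use_circ) {
      dev[idx] <- doy - mean(doy)
    } else {
      th <- doy / period * 2 * pi
      mu <- atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * period
      dev[idx] <- ((doy - mu + period / 2) %% period) - period / 2
    }
  }
  dev
}
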