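#' Typical fertilizer nutrient compositions
#'
#' Elemental nutrient fractions of common fertilizer products in the study
#' regions. Phosphorus is elemental P (P2O5 content times 0.4364), not P2O5.
#' @return data.frame with columns `product`, `n_frac`, `p_frac`.
#' @export
fertilizer_compositions <- function() {
  data.frame(
    product = c("urea", "dap", "can", "npk_17_17_17", "npk_23_10_5",
                "tsp", "ssp", "mop"),
    n_frac = c(0.46, 0.18, 0.26, 0.17, 0.23, 0.00, 0.00, 0.00),
    p_frac = c(0.00, 0.201, 0.00, 0.0742, 0.0436, 0.201, 0.0786, 0.00),
    stringsAsFactors = FALSE
  )
}

#' Convert fertilizer product amounts to elemental nutrient rates
#'
#' @param product_amounts named numeric vector, kg of product per hectare,
#'   names matching `composition$product`. An empty vector yields (0, 0).
#' @param composition nutrient-fraction table; default
#'   [fertilizer_compositions()].
#' @return named numeric vector `c(n_rate, p_rate)` in kg/ha of elemental N
#'   and P.
#' @export
fertilizer_to_nutrients <- function(product_amounts,
                                    composition = fertilizer_compositions()) {
  if (length(product_amounts) == 0L) return(c(n_rate = 0, p_rate = 0))
  if (is.null(names(product_amounts)) || any(!nzchar(names(product_amounts))))
    stop_named("'product_amounts' must be a named vector of kg/ha")
  if (any(product_amounts < 0)) stop_named("product amounts must be >= 0")
  if (any(composition$n_frac < 0 | composition$n_frac > 1 |
          composition$p_frac < 0 | composition$p_frac > 1))
    stop_named("nutrient fractions must lie in [0, 1]")
  unknown <- setdiff(names(product_amounts), composition$product)
  if (length(unknown))
    stop_named("unknown fertilizer product(s): %s",
               paste(unknown, collapse = ", "))
  i <- match(names(product_amounts), composition$product)
  c(n_rate = sum(product_amounts * composition$n_frac[i]),
    p_rate = sum(product_amounts * composition$p_frac[i]))
}

#' Bonferroni outlier test for yields
#'
#' Flags observations whose externally studentized residual from a reference
#' linear model (default: intercept only, optionally per group) has a
#' Bonferroni-adjusted two-sided p-value below `alpha`.
#'
#' @param values numeric vector (NAs are never flagged).
#' @param alpha familywise significance level.
#' @param groups optional grouping factor for the reference model (one
#'   intercept per group, e.g. region).
#' @return integer vector of flagged indices (positions in `values`).
#' @export
bonferroni_outlier_test <- function(values, alpha = 0.05, groups = NULL) {
  ok <- which(!is.na(values))
  n <- length(ok)
  if (n < 3L) stop_named("bonferroni_outlier_test needs at least 3 values")
  if (alpha <= 0) return(integer(0))
  y <- values[ok]
  if (stats::sd(y) < 1e-10 * (abs(mean(y)) + 1)) return(integer(0))
  if (is.null(groups)) {
    fit <- stats::lm(y ~ 1)
  } else {
    g <- droplevels(factor(groups[ok]))
    fit <- if (nlevels(g) > 1L) stats::lm(y ~ g) else stats::lm(y ~ 1)
  }
  t_i <- stats::rstudent(fit)
  df <- stats::df.residual(fit) - 1L
  if (df < 1L) return(integer(0))
  t_i[!is.finite(t_i)] <- 0              # zero-residual (constant) cases
  p <- 2 * stats::pt(-abs(t_i), df)
  p_adj <- pmin(1, p * n)
  ok[p_adj < alpha]
}

#' Quality-control rules
#'
#' Cleaning thresholds: yield outliers (Bonferroni studentized-residual
#' test), plant density and fertilizer rates above `min(mean + sd_cutoff*SD,
#' cap)`, missing geolocation, missing N or P, and atypical sowing dates
#' (deviation beyond `sowing_window` days). The density cap is 12 plants/m2;
#' the fertilizer caps are the elemental-nutrient equivalents of a 400 kg/ha
#' product cap (184 kg N/ha via 46% N urea, 80 kg P/ha via a 20.1% P
#' product).
#'
#' @param sd_cutoff standard deviations above the mean.
#' @param density_cap plants/m2 hard cap.
#' @param n_cap,p_cap kg/ha elemental nutrient hard caps.
#' @param outlier_alpha familywise alpha of the yield outlier test.
#' @param outlier_groups column used as the outlier-test reference model
#'   grouping (`"region"` by default; `NULL` for a single intercept).
#' @param sowing_window days; |sowing_dev| beyond it is atypical.
#' @export
qc_rules <- function(sd_cutoff = 4, density_cap = 12, n_cap = 184,
                     p_cap = 80, outlier_alpha = 0.05,
                     outlier_groups = "region", sowing_window = 60) {
  stopifnot(sd_cutoff > 0, density_cap > 0, n_cap > 0, p_cap > 0,
            outlier_alpha > 0, outlier_alpha < 1, sowing_window > 0)
  structure(list(sd_cutoff = sd_cutoff, density_cap = density_cap,
                 n_cap = n_cap, p_cap = p_cap,
                 outlier_alpha = outlier_alpha,
                 outlier_groups = outlier_groups,
                 sowing_window = sowing_window),
            class = "qc_rules")
}

qc_threshold <- function(x, sd_cutoff, cap) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(cap)
  min(mean(x) + sd_cutoff * stats::sd(x), cap)
}

#' Apply quality control to a survey table
#'
#' Removal rules are applied with first-match-wins attribution, in the fixed
#' order: yield outliers, excessive plant density, excessive fertilizer rate,
#' missing geolocation, missing N or P, atypical sowing date. The 4-SD
#' thresholds are computed on the sample with complete geolocation and
#' nutrient data and then frozen (pass `thresholds` from a previous report to
#' reproduce them, which makes the operation idempotent).
#'
#' @param records survey data.frame.
#' @param rules a [qc_rules()] object.
#' @param thresholds optional named list `density`, `n_rate`, `p_rate` of
#'   frozen thresholds.
#' @return list with `records` (clean rows) and `report` (class
#'   `qc_report`): counts removed per rule in application order, `n_in`,
#'   `n_out`, and the thresholds used.
#' @export
apply_qc <- function(records, rules = qc_rules(), thresholds = NULL) {
  stopifnot(is.data.frame(records))
  n_in <- nrow(records)
  has <- function(col) col %in% names(records)

  miss_geo <- if (has("lon") && has("lat"))
    is.na(records$lon) | is.na(records$lat) else rep(FALSE, n_in)
  miss_np <- if (has("n_rate") && has("p_rate"))
    is.na(records$n_rate) | is.na(records$p_rate) else rep(FALSE, n_in)

  if (is.null(thresholds)) {
    base <- records[!(miss_geo | miss_np), , drop = FALSE]
    thresholds <- list(
      density = if (has("plant_density"))
        qc_threshold(base$plant_density, rules$sd_cutoff, rules$density_cap)
      else rules$density_cap,
      n_rate = if (has("n_rate"))
        qc_threshold(base$n_rate, rules$sd_cutoff, rules$n_cap)
      else rules$n_cap,
      p_rate = if (has("p_rate"))
        qc_threshold(base$p_rate, rules$sd_cutoff, rules$p_cap)
      else rules$p_cap
    )
  }

  outlier <- rep(FALSE, n_in)
  if (has("yield_t_ha") && sum(!is.na(records$yield_t_ha)) >= 3L) {
    grp <- if (!is.null(rules$outlier_groups) && has(rules$outlier_groups))
      records[[rules$outlier_groups]] else NULL
    outlier[bonferroni_outlier_test(records$yield_t_ha,
                                    rules$outlier_alpha, grp)] <- TRUE
  }
  density <- if (has("plant_density"))
    !is.na(records$plant_density) & records$plant_density > thresholds$density
  else rep(FALSE, n_in)
  fert <- rep(FALSE, n_in)
  if (has("n_rate")) fert <- fert |
      (!is.na(records$n_rate) & records$n_rate > thresholds$n_rate)
  if (has("p_rate")) fert <- fert |
      (!is.na(records$p_rate) & records$p_rate > thresholds$p_rate)
  sowing <- if (has("sowing_dev"))
    !is.na(records$sowing_dev) & abs(records$sowing_dev) > rules$sowing_window
  else rep(FALSE, n_in)

  rule_masks <- list(yield_outlier = outlier, density = density,
                     fertilizer = fert, missing_geolocation = miss_geo,
                     missing_np = miss_np, atypical_sowing = sowing)
  claimed <- rep(FALSE, n_in)
  removed <- integer(length(rule_masks))
  names(removed) <- names(rule_masks)
  for (r in names(rule_masks)) {
    hit <- rule_masks[[r]] & !claimed
    removed[r] <- sum(hit)
    claimed <- claimed | hit
  }

  report <- structure(list(n_in = n_in, n_out = n_in - sum(removed),
                           removed = removed, thresholds = thresholds,
                           rules = rules),
                      class = "qc_report")
  list(records = records[!claimed, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("quality control: %d in, %d out (%d removed)\n",
              x$n_in, x$n_out, x$n_in - x$n_out))
  for (r in names(x$removed))
    cat(sprintf("  %-20s %d\n", r, x$removed[r]))
  invisible(x)
}
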