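#' Default candidate sets for the per-zone tree analysis
#' @return list with `practices` (manageable) and `covariates`
#'   (non-manageable) column names.
#' @export
default_candidates <- function() {
  list(practices = c("cultivar", "n_rate", "p_rate", "placement",
                     "plant_density", "sowing_dev", "weedings",
                     "pesticide_used", "compost_used", "compost_rate",
                     "striga"),
       covariates = c("elevation", "season_precip", "precip_early",
                      "precip_flower", "precip_grainfill", "clay", "ph",
                      "soil_oc", "ecec", "pawhc", "twi"))
}

#' Run the survey analysis pipeline end to end
#'
#' simulate (or load) -> quality control -> strata/isolation -> per-stratum
#' conditional inference trees -> practice importance -> technology levels
#' -> mixed model and marginal means -> scenario table. Stages communicate
#' through files under `out_dir` so a run is auditable; a manifest (seed,
#' row counts per stage, package version) is written last and contains no
#' volatile fields, so a rerun with the same config reproduces identical
#' outputs.
#'
#' @param config list with components `seed` (integer), `truth` (arguments
#'   for [truth_spec()], or a ready `truth_spec`; alternatively
#'   `input_csv` with a survey file to load), and optionally `qc`
#'   ([qc_rules()] arguments), `min_n` (stratum eligibility), `cit`
#'   ([cit_params()] overrides), `level_rule`, and `scenario`
#'   ([scenario_inputs()] arguments).
#' @param out_dir output directory (created).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  for (key in c("seed"))
    if (is.null(config[[key]])) stop_named("missing config key: '%s'", key)
  if (is.null(config$truth) && is.null(config$input_csv))
    stop_named("missing config key: 'truth' (or 'input_csv')")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("maizegap")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_named("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  records <- stage("simulate", {
    if (!is.null(config$input_csv)) {
      read_survey(config$input_csv)
    } else {
      truth <- if (inherits(config$truth, "truth_spec")) config$truth
               else do.call(truth_spec,
                            c(config$truth, list(seed = config$seed)))
      d <- generate_survey(truth)
      write_fixture(d, file.path(out_dir, "fields.csv"))
      d
    }
  })
  manifest$n_fields <- nrow(records)

  qc <- stage("qc", {
    rules <- do.call(qc_rules, config$qc %||% list())
    out <- apply_qc(records, rules)
    write_fixture(out$records, file.path(out_dir, "clean.csv"))
    jsonlite::write_json(
      list(n_in = out$report$n_in, n_out = out$report$n_out,
           removed = as.list(out$report$removed),
           thresholds = out$report$thresholds),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
    out
  })
  clean <- qc$records
  manifest$n_clean <- nrow(clean)

  zoned <- stage("zones", {
    kept <- filter_isolated(clean)
    strata <- select_strata(kept, min_n = config$min_n %||% 200)
    kept$stratum <- strata$stratum
    kept$eligible <- strata$eligible
    write_fixture(kept, file.path(out_dir, "zoned.csv"))
    kept
  })
  manifest$n_zoned <- nrow(zoned)
  manifest$n_eligible_strata <- length(unique(zoned$stratum[zoned$eligible]))

  trees <- stage("trees", {
    cand <- default_candidates()
    strata <- unique(zoned$stratum[zoned$eligible])
    ts <- lapply(strata, function(s) {
      d <- zoned[zoned$stratum == s, , drop = FALSE]
      params <- do.call(cit_params,
                        c(list(n = nrow(d)), config$cit %||% list()))
      grow_tree(d, "yield_t_ha",
                c(cand$practices, cand$covariates), params)
    })
    names(ts) <- strata
    writeLines(jsonlite::toJSON(lapply(ts, function(t)
      jsonlite::fromJSON(tree_to_json(t), simplifyVector = FALSE)),
      auto_unbox = TRUE, digits = NA), file.path(out_dir, "trees.json"))
    ts
  })

  imp <- stage("importance", {
    cand <- default_candidates()
    tab <- relative_importance(trees, cand$practices, cand$covariates)
    utils::write.csv(tab, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
    tab
  })

  fit_out <- stage("fit", {
    zoned$tech_level <- assign_level(zoned,
                                     rule = config$level_rule %||% "fig5")
    fit <- fit_sqrt_lmm(zoned[zoned$eligible, , drop = FALSE])
    mm <- marginal_means(fit)
    utils::write.csv(mm, file.path(out_dir, "marginal_means.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(beta = as.list(fit$beta), var_zone = fit$var_zone,
           var_year = fit$var_year, var_resid = fit$var_resid,
           n = fit$n, logLik = fit$logLik),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    list(fit = fit, means = mm)
  })
  manifest$n_modeled <- fit_out$fit$n

  stage("scenarios", {
    inputs <- do.call(scenario_inputs, config$scenario %||% list())
    tab <- scenario_table(inputs)
    utils::write.csv(round_scenario_table(tab),
                     file.path(out_dir, "scenario_table.csv"),
                     row.names = FALSE)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load the deposited field database
#'
#' Maps a user-downloaded copy of the deposited survey (the archived
#' field-level yield and management database) onto the package's survey
#' schema through an explicit column map. The archive is not shipped with
#' the package and must be downloaded from its Zenodo record first.
#'
#' @param path CSV file extracted from the deposit.
#' @param column_map named character vector `deposited_name = package_name`;
#'   the default maps the documented deposit columns.
#' @return survey data.frame; the row count is reported with `message()` so
#'   it can be compared against the documented 14,773 fields.
#' @export
load_deposited <- function(path, column_map = NULL) {
  if (!file.exists(path))
    stop_named(paste("deposited database not found at '%s': download the",
                     "archive from its Zenodo record (10.5281/zenodo.11115815)",
                     "and pass the extracted CSV path"), path)
  column_map <- column_map %||% c(
    field = "field_id", country_group = "region", longitude = "lon",
    latitude = "lat", year = "year", season = "season",
    sowing_date_dev = "sowing_dev", variety_type = "cultivar",
    n_kg_ha = "n_rate", p_kg_ha = "p_rate",
    fertilization_method = "placement", compost = "compost_used",
    manure = "compost_has_manure", compost_t_ha = "compost_rate",
    plants_m2 = "plant_density", row_spacing_cm = "row_spacing",
    weedings = "weedings", pesticide = "pesticide_used",
    pests = "pest_affected", diseases = "disease_affected",
    striga = "striga", field_size_ha = "field_size",
    yield_t_ha = "yield_t_ha")
  raw <- utils::read.csv(path, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  unmapped <- setdiff(names(column_map), names(raw))
  if (length(unmapped))
    stop_named("deposited file lacks expected column(s): %s",
               paste(unmapped, collapse = ", "))
  out <- raw[, names(column_map), drop = FALSE]
  names(out) <- unname(column_map)
  message(sprintf("loaded %d deposited field records", nrow(out)))
  out
}
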