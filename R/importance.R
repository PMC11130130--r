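#' Relative importance of practices across climate zones
#'
#' A practice is counted as having a significant effect in a zone when it
#' appears as a split variable anywhere in that zone's conditional inference
#' tree. Relative importance is the proportion of zones where this happens;
#' by default the denominator counts only the zones where the practice was
#' evaluable (at least two distinct observed values at the root, recorded at
#' training), because a practice that never varies in a zone cannot show an
#' effect there. Non-manageable covariates can be tallied alongside with
#' `role = "covariate"`.
#'
#' @param trees named list of `cit_tree` objects, one per zone (or zone x
#'   season stratum).
#' @param practices character vector of manageable-practice column names.
#' @param covariates optional character vector of non-manageable covariates,
#'   tallied separately.
#' @param denominator `"evaluable"` (default) or `"all"` zones.
#' @return data.frame: `variable`, `role`, `n_split`, `n_evaluable`,
#'   `n_zones`, `importance` (NA when a practice is evaluable nowhere).
#' @export
relative_importance <- function(trees, practices, covariates = NULL,
                                denominator = c("evaluable", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(length(trees) >= 1L)
  lapply(trees, function(t) stopifnot(inherits(t, "cit_tree")))
  split_vars <- lapply(trees, tree_variables)
  evaluable <- lapply(trees, `[[`, "evaluable")
  tally <- function(vars, role) {
    if (!length(vars)) return(NULL)
    n_split <- vapply(vars, function(v)
      sum(vapply(split_vars, function(sv) v %in% sv, logical(1))), integer(1))
    n_eval <- vapply(vars, function(v)
      sum(vapply(evaluable, function(ev) v %in% ev, logical(1))), integer(1))
    den <- if (denominator == "evaluable") n_eval else length(trees)
    data.frame(variable = vars, role = role, n_split = n_split,
               n_evaluable = n_eval, n_zones = length(trees),
               importance = ifelse(den > 0, n_split / den, NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(tally(practices, "practice"), tally(covariates, "covariate"))
}

#' Practice-type importance shares per region
#'
#' Sums practice importances within each type (nutrients, cultivars,
#' establishment, pest management) and normalizes to shares within each
#' region. Regions where no practice was significant get NA shares.
#'
#' @param importance_by_region named list (region -> output of
#'   [relative_importance()]); a single table is treated as one region.
#' @param types named character vector mapping every practice to its type.
#' @return data.frame: `region`, `type`, `share`; shares sum to 1 within a
#'   region whenever any practice is significant there.
#' @export
importance_by_type <- function(importance_by_region, types) {
  if (is.data.frame(importance_by_region))
    importance_by_region <- list(all = importance_by_region)
  out <- lapply(names(importance_by_region), function(reg) {
    imp <- importance_by_region[[reg]]
    imp <- imp[imp$role == "practice", , drop = FALSE]
    untyped <- setdiff(imp$variable, names(types))
    if (length(untyped))
      stop_named("practice(s) without a type: %s",
                 paste(untyped, collapse = ", "))
    v <- ifelse(is.na(imp$importance), 0, imp$importance)
    by_type <- tapply(v, types[imp$variable], sum)
    tot <- sum(by_type)
    data.frame(region = reg, type = names(by_type),
               share = if (tot > 0) as.numeric(by_type) / tot
                       else rep(NA_real_, length(by_type)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Default practice -> type map
#' @export
practice_types <- function() {
  c(n_rate = "nutrients", p_rate = "nutrients", placement = "nutrients",
    compost_used = "nutrients", compost_rate = "nutrients",
    compost_has_manure = "nutrients",
    cultivar = "cultivars",
    sowing_dev = "establishment", plant_density = "establishment",
    row_spacing = "establishment",
    weedings = "pest management", pesticide_used = "pest management",
    striga = "pest management")
}
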