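#' Fit the square-root-scale technology-level mixed model
#'
#' Fits, by restricted maximum likelihood,
#' `sqrt(yield) ~ tech_level + (1 | zone) + (1 | year)`
#' on the fields assigned to the four technology levels: the fixed part is
#' the baseline sqrt-yield intercept plus one contrast per higher level, and
#' climate zone and year enter as crossed random intercepts absorbing the
#' environmental background.
#'
#' @param records data.frame with the response, technology level, zone and
#'   year columns.
#' @param response,level,zone,year column names.
#' @param reml use REML (default) rather than ML.
#' @return object of class `sqrt_lmm`: fixed effects (`beta`, treatment
#'   coding with baseline reference), their covariance, variance components
#'   (`var_zone`, `var_year`, `var_resid`), per-level counts, the underlying
#'   `lmerMod` fit and its log-likelihood.
#' @export
fit_sqrt_lmm <- function(records, response = "yield_t_ha",
                         level = "tech_level", zone = "zone_code",
                         year = "year", reml = TRUE) {
  for (col in c(response, level, zone, year))
    if (!col %in% names(records)) stop_named("missing column '%s'", col)
  lv <- factor(as.character(records[[level]]),
               levels = c("baseline", "HN", "HNP", "HNPS"))
  keep <- !is.na(lv) & !is.na(records[[response]])
  d <- data.frame(.y = sqrt(records[[response]][keep]),
                  .lv = droplevels(lv[keep]),
                  .zone = factor(records[[zone]][keep]),
                  .year = factor(records[[year]][keep]))
  absent <- setdiff(c("baseline", "HN", "HNP", "HNPS"), levels(d$.lv))
  if (length(absent))
    stop_named("technology level(s) absent from the data: %s",
               paste(absent, collapse = ", "))
  if (nlevels(d$.zone) < 2L || nlevels(d$.year) < 2L)
    stop_named("need at least 2 zones and 2 years")
  d$.lv <- factor(d$.lv, levels = c("baseline", "HN", "HNP", "HNPS"))

  fit <- lme4::lmer(.y ~ .lv + (1 | .zone) + (1 | .year), data = d,
                    REML = reml,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (any(grepl("failed to converge", msgs, ignore.case = TRUE)))
    stop_named("mixed model failed to converge: %s",
               paste(msgs, collapse = "; "))

  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v else 0 }
  beta <- lme4::fixef(fit)
  names(beta) <- c("baseline", "HN", "HNP", "HNPS")
  structure(list(beta = beta, vcov = as.matrix(stats::vcov(fit)),
                 var_zone = getv(".zone"), var_year = getv(".year"),
                 var_resid = getv("Residual"),
                 n_by_level = table(d$.lv), n = nrow(d),
                 logLik = as.numeric(stats::logLik(fit)),
                 reml = reml, model = fit),
            class = "sqrt_lmm")
}

#' Back-transformed marginal means per technology level
#'
#' Evaluates each level's mean on the sqrt scale at zero random effects
#' (baseline intercept plus the level contrast) and back-transforms by
#' squaring; standard errors follow by the delta method
#' (`se = 2 |mean_sqrt| se_sqrt`). `bias_correct = TRUE` adds the summed
#' random-effect and residual variances before reporting the yield, the
#' lognormal-style retransformation correction (off by default, matching
#' the group-mean reporting convention).
#'
#' @param fit a [fit_sqrt_lmm()] result.
#' @param bias_correct logical.
#' @return data.frame of class `marginal_means`: `level`, `mean_sqrt`,
#'   `se_sqrt`, `mean_yield`, `se_yield`, `n`.
#' @export
marginal_means <- function(fit, bias_correct = FALSE) {
  stopifnot(inherits(fit, "sqrt_lmm"))
  L <- rbind(baseline = c(1, 0, 0, 0), HN = c(1, 1, 0, 0),
             HNP = c(1, 0, 1, 0), HNPS = c(1, 0, 0, 1))
  m <- as.numeric(L %*% fit$beta)
  se <- sqrt(diag(L %*% fit$vcov %*% t(L)))
  corr <- if (bias_correct) fit$var_zone + fit$var_year + fit$var_resid else 0
  out <- data.frame(level = rownames(L), mean_sqrt = m, se_sqrt = se,
                    mean_yield = m^2 + corr, se_yield = 2 * abs(m) * se,
                    n = as.integer(fit$n_by_level[rownames(L)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("marginal_means", "data.frame")
  out
}

#' Yield contrasts versus the baseline level
#'
#' @param means a [marginal_means()] table.
#' @return data.frame with, per level, the yield ratio to baseline, the
#'   percent increase and the absolute difference (t/ha).
#' @export
level_contrasts <- function(means) {
  stopifnot(inherits(means, "marginal_means"),
            "baseline" %in% means$level)
  base <- means$mean_yield[means$level == "baseline"]
  data.frame(level = means$level,
             ratio = means$mean_yield / base,
             pct_increase = 100 * (means$mean_yield / base - 1),
             difference = means$mean_yield - base,
             stringsAsFactors = FALSE, row.names = NULL)
}
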