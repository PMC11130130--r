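make_leveled <- function(seed = 1, ...) {
  tr <- truth_spec(seed = seed, ...)
  d <- generate_survey(tr)
  d$tech_level <- assign_level(d)
  d
}

test_that("zero random-effect variance reduces to ordinary least squares", {
  d <- degenerate_leveled()
  fit <- fit_sqrt_lmm(d)
  expect_equal(fit$var_zone, 0, tolerance = 1e-10)
  expect_equal(fit$var_year, 0, tolerance = 1e-10)
  sub <- d
  sub$tech_level <- factor(sub$tech_level,
                           levels = c("baseline", "HN", "HNP", "HNPS"))
  ols <- coef(lm(sqrt(yield_t_ha) ~ tech_level, data = sub))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-6)

  # and near-zero true variance in generated data keeps the estimates close
  g <- make_leveled(seed = 2, sd_zone = 0, sd_year = 0,
                    missingness = list())
  gfit <- fit_sqrt_lmm(g)
  gsub <- g[g$tech_level != "unclassified", ]
  gsub$tech_level <- droplevels(gsub$tech_level)
  gols <- coef(lm(sqrt(yield_t_ha) ~ tech_level, data = gsub))
  expect_equal(unname(gfit$beta), unname(gols), tolerance = 1e-3)
})

test_that("doubling yields scales sqrt-scale coefficients by sqrt(2)", {
  d <- make_leveled(seed = 3, n_zones = 6, fields_per_zone = 150)
  f1 <- fit_sqrt_lmm(d)
  d2 <- d; d2$yield_t_ha <- 2 * d2$yield_t_ha
  f2 <- fit_sqrt_lmm(d2)
  expect_equal(unname(f2$beta), sqrt(2) * unname(f1$beta), tolerance = 1e-6)
})

test_that("marginal means back-transform correctly and match emmeans", {
  d <- make_leveled(seed = 4)
  fit <- fit_sqrt_lmm(d)
  mm <- marginal_means(fit)
  # algebra: baseline mean is the squared intercept
  expect_equal(mm$mean_yield[1], unname(fit$beta["baseline"])^2,
               tolerance = 1e-12)
  expect_equal(mm$mean_yield[2],
               unname(fit$beta["baseline"] + fit$beta["HN"])^2,
               tolerance = 1e-12)
  # bias correction adds exactly the summed variance components
  mmc <- marginal_means(fit, bias_correct = TRUE)
  expect_equal(mmc$mean_yield - mm$mean_yield,
               rep(fit$var_zone + fit$var_year + fit$var_resid, 4),
               tolerance = 1e-12)

  skip_if_not_installed("emmeans")
  em <- as.data.frame(emmeans::emmeans(fit$model, ".lv"))
  expect_equal(mm$mean_sqrt, em$emmean, tolerance = 1e-6)
  expect_equal(mm$se_sqrt, em$SE, tolerance = 1e-6)
})

test_that("standard errors shrink with the sample", {
  # tiny random-effect variances so the residual term dominates the SE
  small <- make_leveled(seed = 5, n_zones = 10, fields_per_zone = 50,
                        sd_zone = 0.02, sd_year = 0.02, sd_resid = 0.3)
  large <- make_leveled(seed = 5, n_zones = 10, fields_per_zone = 500,
                        sd_zone = 0.02, sd_year = 0.02, sd_resid = 0.3)
  se_s <- marginal_means(fit_sqrt_lmm(small))$se_yield
  se_l <- marginal_means(fit_sqrt_lmm(large))$se_yield
  expect_true(all(se_l < se_s))
})

test_that("level contrasts report ratios, percent gains and differences", {
  mm <- structure(data.frame(level = c("baseline", "HN", "HNP", "HNPS"),
                             mean_sqrt = sqrt(c(1.8, 2.9, 3.6, 4.3)),
                             se_sqrt = 0.01,
                             mean_yield = c(1.8, 2.9, 3.6, 4.3),
                             se_yield = 0.03, n = 100L),
                  class = c("marginal_means", "data.frame"))
  lc <- level_contrasts(mm)
  expect_equal(lc$ratio[1], 1)
  expect_equal(lc$ratio[4], 4.3 / 1.8, tolerance = 1e-12)
  expect_equal(round(lc$ratio[4], 1), 2.4)
  expect_equal(lc$difference[4], 2.5)
  expect_equal(round(lc$pct_increase[2]), 61)
})

test_that("missing levels and too few grouping levels raise clear errors", {
  d <- make_leveled(seed = 6, n_zones = 4, fields_per_zone = 120)
  no_hnps <- d[d$tech_level != "HNPS", ]
  expect_error(fit_sqrt_lmm(no_hnps), "HNPS")
  one_zone <- d[d$zone_code == d$zone_code[1], ]
  expect_error(fit_sqrt_lmm(one_zone), "2 zones")
  expect_error(fit_sqrt_lmm(d[, setdiff(names(d), "year")]), "year")
})

test_that("the likelihood prefers the truth to perturbed parameters", {
  # consistency smoke test: deviance at the fitted (near-true) parameters is
  # lower than with the level structure shuffled
  d <- make_leveled(seed = 7)
  fit <- fit_sqrt_lmm(d)
  shuf <- d
  keep <- shuf$tech_level %in% c("baseline", "HN", "HNP", "HNPS")
  set.seed(1)
  shuf$tech_level[keep] <- sample(shuf$tech_level[keep])
  fit_shuf <- fit_sqrt_lmm(shuf)
  expect_gt(fit$logLik, fit_shuf$logLik)
})
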