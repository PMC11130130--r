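env_ref <- function(n = 120, seed = 1) {
  set.seed(seed)
  data.frame(elevation = rnorm(n, 1200, 300),
             season_precip = rnorm(n, 800, 150),
             clay = rnorm(n, 30, 6),
             ph = rnorm(n, 6, 0.4))
}

test_that("dissimilarity index is zero at references and unit-mean leave-one-out", {
  ref <- env_ref()
  cfg <- di_config(ref)
  expect_equal(dissimilarity_index(ref[1:10, ], cfg), rep(0, 10))

  # leave-one-out normalization: the reference cloud's own nearest-neighbour
  # distances average exactly 1 after scaling
  z <- cfg$zref
  dd <- as.matrix(dist(z)); diag(dd) <- Inf
  expect_equal(mean(apply(dd, 1, min)) / cfg$norm, 1, tolerance = 1e-12)
})

test_that("dissimilarity grows monotonically along any weighted axis", {
  ref <- env_ref()
  cfg <- di_config(ref, weights = c(elevation = .4, season_precip = .3,
                                    clay = .2, ph = .1))
  # scan outward from the edge of the cloud along the elevation axis: once
  # beyond every reference the index must increase monotonically
  base <- colMeans(ref)
  base["elevation"] <- max(ref$elevation)
  line <- do.call(rbind, lapply(seq(0, 5, by = 0.25), function(s) {
    p <- base; p["elevation"] <- p["elevation"] + s * 300; as.data.frame(t(p))
  }))
  di <- dissimilarity_index(line, cfg)
  expect_true(all(diff(di) >= -1e-9))
  expect_gt(di[length(di)], 1)
})

test_that("dissimilarity index is invariant to affine rescaling of a variable", {
  ref <- env_ref()
  pts <- env_ref(n = 30, seed = 2)
  cfg <- di_config(ref)
  d1 <- dissimilarity_index(pts, cfg)
  ref2 <- ref; pts2 <- pts
  ref2$clay <- 1000 * ref2$clay - 7      # affine map absorbed by scaling
  pts2$clay <- 1000 * pts2$clay - 7
  d2 <- dissimilarity_index(pts2, di_config(ref2))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("applicability is strictly below the 40% threshold", {
  ref <- env_ref()
  cfg <- di_config(ref, threshold = 0.40)
  expect_true(all(applicability_mask(ref, cfg)))        # DI 0 everywhere
  expect_identical(applicability_mask(c(0.39, 0.40, 0.41), cfg),
                   c(TRUE, FALSE, FALSE))
  expect_error(dissimilarity_index(data.frame(elevation = 1), cfg),
               "season_precip")
})

test_that("NNDM folds separate planted spatial clusters and handle edge cases", {
  set.seed(3)
  cl1 <- cbind(runif(40, 30, 30.5), runif(40, -2, -1.5))
  cl2 <- cbind(runif(40, 31, 31.5), runif(40, -2, -1.5))
  coords <- rbind(cl1, cl2)
  # prediction area much larger than the sampled clusters: typical
  # prediction-to-training distances are of the between-cluster order or
  # beyond, so matching them requires spatially blocked folds
  grid <- as.matrix(expand.grid(lon = seq(25, 37, by = 0.5),
                                lat = seq(-5, 1, by = 0.5)))
  folds <- nndm_folds(coords, k = 2, seed = 1, pred_coords = grid)
  expect_equal(length(unique(folds)), 2)
  expect_equal(length(unique(folds[1:40])), 1)     # one cluster, one fold
  expect_equal(length(unique(folds[41:80])), 1)
  expect_false(folds[1] == folds[41])

  coords_u <- cbind(runif(30, 30, 35), runif(30, -3, 0))
  expect_equal(nndm_folds(coords_u, k = nrow(coords_u)),
               1:30, ignore_attr = TRUE)           # k = n: leave-one-out
  expect_error(nndm_folds(coords_u, k = 1), ">= 2")
  expect_error(nndm_folds(coords_u[c(1, 1, 1), ], k = 3), "distinct")

  # determinism and disjoint-exhaustive folds
  f1 <- nndm_folds(coords_u, k = 5, seed = 7)
  f2 <- nndm_folds(coords_u, k = 5, seed = 7)
  expect_identical(as.integer(f1), as.integer(f2))
  expect_setequal(unique(f1), 1:5)
})

test_that("without spatial structure NNDM folds look like random folds", {
  set.seed(4)
  coords <- cbind(runif(150, 28, 40), runif(150, -12, 0))
  folds <- nndm_folds(coords, k = 5, seed = 2)
  set.seed(5)
  rnd <- sample(rep_len(1:5, 150))
  dmat <- geosphere::distm(coords) / 1000
  nn_out <- function(f) vapply(seq_len(150), function(i)
    min(dmat[i, f != f[i]]), numeric(1))
  ks <- suppressWarnings(ks.test(nn_out(folds), nn_out(rnd)))
  expect_gt(ks$p.value, 0.05)
})

test_that("SHAP attributions satisfy additivity and recover the N trend", {
  tr <- truth_spec(n_zones = 5, fields_per_zone = 120,
                   missingness = list(), seed = 13)
  d <- generate_survey(tr)
  feats <- c("n_rate", "plant_density", "sowing_dev", "cultivar",
             "elevation", "season_precip")
  gbm <- fit_yield_gbm(d, "yield_t_ha", feats, seed = 1)
  chk <- shap_additivity_check(gbm, tolerance = 1e-6)
  expect_true(chk$pass)
  expect_lt(chk$max_abs_residual, 1e-6)

  sv <- shap_values(gbm)
  expect_equal(rowSums(sv), predict_gbm(gbm) - gbm$offset,
               tolerance = 1e-5)
  # positive planted N effect: attribution rises across N-rate bins
  trend <- shap_trend(sv, "n_rate", d$n_rate, bins = 4)
  expect_gt(trend$mean_shap[4], trend$mean_shap[1])
  # direction summary agrees
  tn <- chk$trend[chk$trend$feature == "n_rate", ]
  expect_gt(tn$mean_shap_high, tn$mean_shap_low)
})

test_that("a constant response yields (near-)zero attributions", {
  set.seed(6)
  d <- data.frame(a = rnorm(150), b = rnorm(150), y = 2)
  gbm <- fit_yield_gbm(d, "y", c("a", "b"), nrounds = 20, seed = 1)
  sv <- shap_values(gbm)
  expect_lt(max(abs(sv[, c("a", "b")])), 1e-6)
  expect_equal(predict_gbm(gbm), rep(2, 150), tolerance = 1e-6)
})

test_that("pairwise normalization gives smaller indices than leave-one-out", {
  ref <- env_ref()
  pts <- env_ref(n = 20, seed = 9)
  d_nn <- dissimilarity_index(pts, di_config(ref, norm = "nn"))
  d_pw <- dissimilarity_index(pts, di_config(ref, norm = "pairwise"))
  expect_true(all(d_pw < d_nn))
  # both are the same distance in different units
  cfg_nn <- di_config(ref, norm = "nn")
  cfg_pw <- di_config(ref, norm = "pairwise")
  expect_equal(d_pw * cfg_pw$norm, d_nn * cfg_nn$norm, tolerance = 1e-10)
})
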