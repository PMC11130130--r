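#' Dissimilarity-index configuration
#'
#' Stores the reference set of environmental vectors (the training fields),
#' their standardization parameters, non-negative variable weights
#' (normalized to sum to one; typically relative importances from the
#' predictive model) and the applicability threshold. The index of a new
#' point is its weighted Euclidean distance, on standardized variables, to
#' the nearest reference field, scaled by a reference statistic. The default
#' scaling (`norm = "nn"`) is the mean leave-one-out nearest-neighbour
#' distance within the reference set, a self-calibrating unit: reference
#' points score 0 and the reference cloud itself averages 1, so the index
#' reads as "how many typical nearest-neighbour spacings away".
#' `norm = "pairwise"` scales by the mean of all pairwise reference
#' distances instead (the convention of the area-of-applicability
#' literature), under which in-distribution points score well below 1 and a
#' 40% threshold is permissive rather than strict.
#'
#' @param ref data.frame or matrix of reference environmental vectors
#'   (numeric columns only; complete cases used).
#' @param weights optional named (or positionally matched) non-negative
#'   weights; default equal.
#' @param threshold applicability threshold on the index, default 0.40.
#' @param norm `"nn"` (default) or `"pairwise"`.
#' @return object of class `di_config`.
#' @export
di_config <- function(ref, weights = NULL, threshold = 0.40,
                      norm = c("nn", "pairwise")) {
  norm <- match.arg(norm)
  ref <- as.matrix(as.data.frame(ref))
  storage.mode(ref) <- "double"
  ref <- ref[stats::complete.cases(ref), , drop = FALSE]
  if (nrow(ref) < 2L) stop_named("need at least 2 complete reference rows")
  if (threshold <= 0 || threshold > 1)
    stop_named("'threshold' must be in (0, 1]")
  p <- ncol(ref)
  w <- weights %||% rep(1 / p, p)
  if (!is.null(names(w)) && !is.null(colnames(ref)))
    w <- w[colnames(ref)]
  if (length(w) != p || any(is.na(w)) || any(w < 0) || sum(w) == 0)
    stop_named("'weights' must be %d non-negative values (not all zero)", p)
  w <- w / sum(w)
  ctr <- colMeans(ref)
  scl <- apply(ref, 2, stats::sd)
  if (any(scl == 0))
    stop_named("constant reference variable(s): %s",
               paste(colnames(ref)[scl == 0], collapse = ", "))
  # weighted Euclidean = plain Euclidean after scaling each standardized
  # axis by sqrt(weight)
  zref <- sweep(sweep(ref, 2, ctr), 2, scl, "/")
  zref <- sweep(zref, 2, sqrt(w), "*")
  dd <- as.matrix(stats::dist(zref))
  diag(dd) <- Inf
  norm_const <- if (norm == "nn") mean(apply(dd, 1, min))
                else mean(dd[is.finite(dd)])
  if (norm_const == 0)
    stop_named("degenerate reference set: all points coincide")
  structure(list(zref = zref, center = ctr, scale = scl, weights = w,
                 norm = norm_const, norm_type = norm,
                 threshold = threshold, variables = colnames(ref)),
            class = "di_config")
}

#' Environmental dissimilarity index
#'
#' @param points data.frame or matrix of environmental vectors containing
#'   every weighted variable of the configuration.
#' @param config a [di_config()].
#' @return numeric vector: 0 at a reference point; ~1 on average at the
#'   reference cloud's own leave-one-out distances.
#' @export
dissimilarity_index <- function(points, config) {
  stopifnot(inherits(config, "di_config"))
  points <- as.data.frame(points)
  absent <- setdiff(config$variables, names(points))
  if (length(absent))
    stop_named("points lack weighted variable(s): %s",
               paste(absent, collapse = ", "))
  x <- as.matrix(points[, config$variables, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(is.na(x))) stop_named("missing values in weighted variables")
  z <- sweep(sweep(x, 2, config$center), 2, config$scale, "/")
  z <- sweep(z, 2, sqrt(config$weights), "*")
  # min squared distance to the reference via the expansion
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  rn <- rowSums(config$zref^2)
  d2 <- outer(rowSums(z^2), rn, "+") - 2 * z %*% t(config$zref)
  d2min <- apply(d2, 1, min)
  d2min[d2min < 1e-12] <- 0        # cancellation noise at reference points
  unname(sqrt(d2min) / config$norm)
}

#' Applicability mask
#'
#' TRUE where the dissimilarity index is strictly below the configured
#' threshold (a point exactly at the threshold is outside the area of
#' applicability).
#'
#' @param points data.frame of environmental vectors, or a precomputed
#'   numeric dissimilarity-index vector.
#' @param config a [di_config()].
#' @export
applicability_mask <- function(points, config) {
  di <- if (is.numeric(points) && is.null(dim(points))) points
        else dissimilarity_index(points, config)
  di < config$threshold
}

#' Spatially matched cross-validation folds (k-fold NNDM)
#'
#' Builds k disjoint, exhaustive folds whose test-to-training
#' nearest-neighbour great-circle distance distribution approximates the
#' prediction-to-training one. Candidate groupings are k-means clusterings
#' of the coordinates with q = k..Q clusters greedily merged into k folds
#' (q = k gives pure spatial blocks; large q approaches a random split),
#' plus a plain random split; the grouping minimizing the Wasserstein-1
#' distance between its test-to-training nearest-neighbour distances and
#' the target distribution wins. The target is the nearest-neighbour
#' distance from each prediction point to the sample; when no prediction
#' locations are supplied the sample itself is used (leave-one-out
#' distances).
#'
#' @param coords two-column matrix/data.frame of lon, lat (degrees).
#' @param k number of folds, `2 <= k <= n`; `k = n` returns leave-one-out
#'   folds directly.
#' @param seed integer seed (clustering and the random candidate).
#' @param pred_coords optional lon/lat of the prediction area.
#' @param max_q largest candidate cluster count; default
#'   `min(n - 1, max(5 * k, 30))`.
#' @return integer fold id per row, with attributes `candidate` (chosen
#'   grouping) and `w1` (its Wasserstein-1 match).
#' @export
nndm_folds <- function(coords, k, seed = 1L, pred_coords = NULL,
                       max_q = NULL) {
  coords <- as.matrix(as.data.frame(coords))
  n <- nrow(coords)
  if (k < 2L) stop_named("'k' must be >= 2")
  if (n < k) stop_named("'k' cannot exceed the number of records")
  n_loc <- nrow(unique(coords))
  if (k > n_loc) stop_named("'k' exceeds the number of distinct locations")
  if (k == n) {
    out <- seq_len(n)
    attr(out, "candidate") <- "leave-one-out"
    return(out)
  }
  set.seed(seed)

  dmat <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  if (is.null(pred_coords)) {
    dd <- dmat; diag(dd) <- Inf
    target <- apply(dd, 1, min)
  } else {
    pred_coords <- as.matrix(as.data.frame(pred_coords))
    target <- apply(geosphere::distm(pred_coords, coords,
                                     fun = geosphere::distHaversine) / 1000,
                    1, min)
  }

  test_train_nn <- function(folds) {
    vapply(seq_len(n), function(i)
      min(dmat[i, folds != folds[i]]), numeric(1))
  }
  probs <- seq(0.01, 0.99, by = 0.01)
  w1 <- function(a, b)
    mean(abs(stats::quantile(a, probs, names = FALSE) -
             stats::quantile(b, probs, names = FALSE)))

  merge_to_k <- function(cluster) {
    sizes <- sort(table(cluster), decreasing = TRUE)
    fold_of <- integer(length(sizes))
    names(fold_of) <- names(sizes)
    load <- numeric(k)
    for (cl in names(sizes)) {
      f <- which.min(load)
      fold_of[cl] <- f
      load[f] <- load[f] + sizes[cl]
    }
    unname(fold_of[as.character(cluster)])
  }

  candidates <- list(random = sample(rep_len(seq_len(k), n)))
  max_q <- max_q %||% min(n_loc - 1L, max(5L * k, 30L))
  for (q in k:max_q) {
    km <- tryCatch(stats::kmeans(coords, centers = q, nstart = 3,
                                 iter.max = 50),
                   error = function(e) NULL)
    if (is.null(km)) next
    folds <- if (q == k) km$cluster else merge_to_k(km$cluster)
    if (length(unique(folds)) == k)
      candidates[[paste0("kmeans_q", q)]] <- folds
  }

  scores <- vapply(candidates,
                   function(f) w1(test_train_nn(f), target), numeric(1))
  best <- names(candidates)[which.min(scores)]
  out <- candidates[[best]]
  attr(out, "candidate") <- best
  attr(out, "w1") <- unname(min(scores))
  out
}

#' Fit a gradient-boosted yield model
#'
#' Thin wrapper around xgboost (squared-error objective) producing a model
#' suitable for the SHAP attribution contract; missing predictor values are
#' handled natively by the learner. The response is centred and scaled to
#' half-unit standard deviation before training (offset and scale are stored
#' and inverted by [predict_gbm()] and [shap_values()]): boosted-tree leaf
#' values accumulate in single precision, so the additivity identity holds
#' only to an absolute error proportional to the prediction magnitude, and
#' the reduced internal scale together with a modest default ensemble
#' (60 rounds, depth 4, learning rate 0.2) keeps that error well below the
#' 1e-6 contract tolerance on the model scale.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param features predictor column names (numeric or coercible; factors and
#'   characters are converted to their level codes).
#' @param nrounds,max_depth,learning_rate learner settings.
#' @param seed integer seed.
#' @return list of class `yield_gbm`: `model` (xgb.Booster), `features`,
#'   `offset`, and the training design matrix.
#' @export
fit_yield_gbm <- function(data, response, features, nrounds = 60,
                          max_depth = 4, learning_rate = 0.2, seed = 1L) {
  X <- gbm_design(data, features)
  y <- data[[response]]
  ok <- !is.na(y)
  offset <- mean(y[ok])
  scale <- 2 * stats::sd(y[ok])
  if (!is.finite(scale) || scale == 0) scale <- 1
  set.seed(seed)
  model <- xgboost::xgboost(X[ok, , drop = FALSE], (y[ok] - offset) / scale,
                            nrounds = nrounds, max_depth = max_depth,
                            learning_rate = learning_rate,
                            nthreads = 1, verbosity = 0)
  structure(list(model = model, features = features, offset = offset,
                 scale = scale, X = X[ok, , drop = FALSE]),
            class = "yield_gbm")
}

#' Predict yields from a boosted model
#' @param gbm a [fit_yield_gbm()] result.
#' @param data data.frame with the feature columns (default training data).
#' @return numeric predictions on the response scale.
#' @export
predict_gbm <- function(gbm, data = NULL) {
  stopifnot(inherits(gbm, "yield_gbm"))
  X <- if (is.null(data)) gbm$X else gbm_design(data, gbm$features)
  stats::predict(gbm$model, X) * gbm$scale + gbm$offset
}

gbm_design <- function(data, features) {
  cols <- lapply(data[features], function(x) {
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) as.numeric(x) else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- features
  X
}

#' Per-field SHAP attributions of a boosted model
#'
#' @param gbm a [fit_yield_gbm()] result.
#' @param data data.frame with the feature columns (default: training data).
#' @return matrix of per-feature attributions in response units (t/ha) with
#'   a trailing intercept column (the base value); rows sum to
#'   `predict_gbm(gbm, data) - gbm$offset` up to single-precision rounding.
#' @export
shap_values <- function(gbm, data = NULL) {
  stopifnot(inherits(gbm, "yield_gbm"))
  X <- if (is.null(data)) gbm$X else gbm_design(data, gbm$features)
  stats::predict(gbm$model, X, type = "contrib") * gbm$scale
}

#' SHAP additivity contract
#'
#' Asserts, per record and on the boosted model's own (standardized)
#' prediction scale, that the base value plus the summed per-feature
#' attributions reproduces the model prediction within `tolerance`, and
#' summarizes the attribution direction of each feature (mean attribution in
#' the lower vs upper half of the feature's values) for qualitative
#' comparison with the per-practice response trends.
#'
#' @param gbm a [fit_yield_gbm()] result.
#' @param data data.frame (default training data).
#' @param tolerance maximum |prediction - (bias + sum of attributions)|.
#' @return list: `pass`, `max_abs_residual`, `offenders` (row indices beyond
#'   tolerance), `trend` (data.frame of low/high mean attributions per
#'   feature).
#' @export
shap_additivity_check <- function(gbm, data = NULL, tolerance = 1e-6) {
  stopifnot(inherits(gbm, "yield_gbm"))
  X <- if (is.null(data)) gbm$X else gbm_design(data, gbm$features)
  contrib <- stats::predict(gbm$model, X, type = "contrib")
  pred <- stats::predict(gbm$model, X)
  resid <- abs(rowSums(contrib) - pred)
  offenders <- which(resid > tolerance)
  trend <- do.call(rbind, lapply(gbm$features, function(f) {
    x <- X[, f]
    ok <- !is.na(x)
    med <- stats::median(x[ok])
    data.frame(feature = f,
               mean_shap_low = mean(contrib[ok & x <= med, f]),
               mean_shap_high = mean(contrib[ok & x > med, f]),
               stringsAsFactors = FALSE)
  }))
  out <- list(pass = length(offenders) == 0L,
              max_abs_residual = max(resid), offenders = offenders,
              trend = trend)
  if (!out$pass)
    warning(sprintf("SHAP additivity violated for %d record(s); max |resid| = %g",
                    length(offenders), out$max_abs_residual), call. = FALSE)
  out
}

#' Mean SHAP attribution across bins of a feature
#'
#' @param shap attribution matrix from [shap_values()].
#' @param feature feature name.
#' @param values the feature's raw values (same rows).
#' @param bins number of quantile bins.
#' @return data.frame `bin`, `mid`, `mean_shap`.
#' @export
shap_trend <- function(shap, feature, values, bins = 5) {
  ok <- !is.na(values)
  br <- unique(stats::quantile(values[ok], seq(0, 1, length.out = bins + 1)))
  b <- cut(values[ok], br, include.lowest = TRUE)
  data.frame(bin = levels(b),
             mid = as.numeric(tapply(values[ok], b, stats::median)),
             mean_shap = as.numeric(tapply(shap[ok, feature], b, mean)),
             stringsAsFactors = FALSE, row.names = NULL)
}
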