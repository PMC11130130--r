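#' Conditional-inference-tree tuning parameters
#'
#' Stopping rules for [grow_tree()]: splits are attempted only when the
#' Bonferroni-adjusted association p-value falls below `alpha`, trees never
#' exceed `max_depth` levels, intermediate nodes must hold at least
#' `min_split` observations and terminal nodes at least `min_bucket`.
#' Defaults follow the survey-analysis tuning: `alpha = 0.01`, depth 10,
#' intermediate nodes above 20% of the observations (or 200 when the initial
#' n exceeds 1000) and terminal nodes above 5% (or 50). The low-n variant
#' (`low_n = TRUE`) relaxes to `alpha = 0.1`, `min_split = 10`,
#' `min_bucket = 8`.
#'
#' @param n initial number of observations (used to resolve the relative
#'   node-size rules); required unless both `min_split` and `min_bucket` are
#'   given.
#' @param low_n use the relaxed low-sample tuning.
#' @param alpha significance level; default 0.01 (0.1 when `low_n`).
#' @param max_depth maximum number of node levels on any path.
#' @param min_split minimum node size to attempt a split.
#' @param min_bucket minimum terminal-node size.
#' @param n_perm Monte-Carlo permutations for the association p-value; 0
#'   (default) uses the asymptotic reference distribution.
#' @param seed seed for the Monte-Carlo permutations.
#' @export
cit_params <- function(n = NULL, low_n = FALSE, alpha = NULL, max_depth = 10,
                       min_split = NULL, min_bucket = NULL, n_perm = 0,
                       seed = NULL) {
  if (is.null(alpha)) alpha <- if (low_n) 0.1 else 0.01
  if (low_n) {
    min_split <- min_split %||% 10L
    min_bucket <- min_bucket %||% 8L
  } else if (is.null(min_split) || is.null(min_bucket)) {
    if (is.null(n))
      stop_named("cit_params needs 'n' to resolve the node-size rules")
    min_split <- min_split %||% if (n > 1000) 200L else ceiling(0.20 * n)
    min_bucket <- min_bucket %||% if (n > 1000) 50L else ceiling(0.05 * n)
  }
  if (alpha <= 0 || alpha >= 1) stop_named("'alpha' must be in (0, 1)")
  if (max_depth < 1) stop_named("'max_depth' must be >= 1")
  if (min_bucket > min_split)
    stop_named("'min_bucket' must not exceed 'min_split'")
  structure(list(alpha = alpha, max_depth = as.integer(max_depth),
                 min_split = as.integer(min_split),
                 min_bucket = as.integer(min_bucket),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "cit_params")
}

# numeric scores for a predictor column: ordered factors and logicals become
# integer scores, characters become factors (handled separately)
cit_scores <- function(x) {
  if (is.ordered(x)) as.numeric(x)
  else if (is.logical(x)) as.numeric(x)
  else x
}

# standardized linear association statistic under the permutation null.
# numeric x: z^2 with z = (sum g*h - n*gbar*hbar) / sqrt(SSg*SSh/(n-1)),
# the square of the standardized correlation statistic. factor x (k levels):
# quadratic form (n-1)*SSB/SST, asymptotically chi-square with k-1 df.
# returns list(stat, df); df = 1 for numeric.
cit_stat <- function(x, y) {
  if (is.factor(x) && !is.ordered(x)) {
    f <- droplevels(x)
    k <- nlevels(f)
    n <- length(y)
    sst <- sum((y - mean(y))^2)
    if (k < 2L || sst == 0) return(list(stat = 0, df = max(k - 1L, 1L)))
    m <- tapply(y, f, mean)
    nj <- tabulate(f)
    ssb <- sum(nj * (m - mean(y))^2)
    list(stat = (n - 1) * ssb / sst, df = k - 1L)
  } else {
    g <- cit_scores(x)
    n <- length(y)
    ssg <- sum((g - mean(g))^2)
    ssh <- sum((y - mean(y))^2)
    if (ssg == 0 || ssh == 0) return(list(stat = 0, df = 1L))
    z <- (sum(g * y) - n * mean(g) * mean(y)) / sqrt(ssg * ssh / (n - 1))
    list(stat = z^2, df = 1L)
  }
}

#' Permutation-test association p-value
#'
#' Tests independence of a predictor and a numeric response with a
#' standardized linear statistic (rank/score form for numeric, ordered and
#' logical predictors; indicator form for factors), computed case-wise on
#' the non-missing pairs. The default reference distribution is asymptotic
#' (normal / chi-square); with `n_perm > 0` the p-value is Monte-Carlo
#' estimated from random permutations of the response.
#'
#' A predictor with fewer than two distinct non-missing values gives p = 1
#' by convention.
#'
#' @param x predictor column (numeric, logical, factor or ordered).
#' @param y numeric response.
#' @param n_perm number of Monte-Carlo permutations (0 = asymptotic).
#' @param seed optional seed for the permutations.
#' @return p-value in (0, 1].
#' @export
association_pvalue <- function(x, y, n_perm = 0, seed = NULL) {
  if (!is.numeric(y)) stop_named("'y' must be numeric")
  if (is.character(x)) x <- factor(x)
  cc <- !is.na(x) & !is.na(y)
  x <- if (is.factor(x)) droplevels(x[cc]) else x[cc]
  y <- y[cc]
  n <- length(y)
  if (n < 3L || length(unique(x)) < 2L) return(1)
  obs <- cit_stat(x, y)
  if (obs$stat == 0) return(1)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      s <- cit_stat(x, y[sample.int(n)])$stat
      if (s >= obs$stat - 1e-12) hits <- hits + 1L
    }
    return((1 + hits) / (1 + n_perm))
  }
  if (obs$df == 1L) 2 * stats::pnorm(-sqrt(obs$stat))
  else stats::pchisq(obs$stat, df = obs$df, lower.tail = FALSE)
}

#' Select the split variable at a node
#'
#' Computes the association p-value of each candidate against the response,
#' Bonferroni-adjusts across the candidates actually testable (two or more
#' distinct non-missing values), and returns the variable with the smallest
#' p-value when its adjusted value falls below `alpha`. Ties are broken by
#' candidate order.
#'
#' @param data data.frame holding the node's observations.
#' @param response response column name.
#' @param candidates character vector of candidate column names.
#' @param params a [cit_params()].
#' @return `NULL` (no significant association) or a list with `variable`,
#'   `p_value`, `p_adjusted`.
#' @export
select_split_variable <- function(data, response, candidates, params) {
  if (!length(candidates)) return(NULL)
  y <- data[[response]]
  testable <- vapply(candidates, function(v) {
    x <- data[[v]]
    sum(!duplicated(x[!is.na(x) & !is.na(y)])) >= 2L
  }, logical(1))
  if (!any(testable)) return(NULL)
  vars <- candidates[testable]
  p <- vapply(vars, function(v)
    association_pvalue(data[[v]], y, n_perm = params$n_perm,
                       seed = params$seed), numeric(1))
  best <- which.min(p)                        # stable: first minimum wins
  p_adj <- min(1, p[best] * length(vars))
  if (p_adj >= params$alpha) return(NULL)
  list(variable = vars[best], p_value = unname(p[best]), p_adjusted = p_adj)
}

#' Best binary split point for a selected variable
#'
#' Numeric (and ordered/logical) predictors: the threshold maximizing the
#' standardized two-sample statistic over all cut points that leave at least
#' `min_bucket` non-missing observations on each side; the returned cut is
#' the midpoint of the adjacent distinct values. Factors: the best binary
#' partition of the observed levels, found exactly by the sorted-group-means
#' reduction. Computed case-wise on non-missing pairs.
#'
#' @param x selected predictor column.
#' @param y numeric response.
#' @param min_bucket minimum child size.
#' @return `NULL` when no feasible cut exists, otherwise a list with
#'   `type` ("numeric" or "categorical"), `cut` (numeric threshold; go left
#'   when `x <= cut`) or `left_levels` (levels routed left), and `stat`.
#' @export
best_split_point <- function(x, y, min_bucket = 1L) {
  if (is.character(x)) x <- factor(x)
  cc <- !is.na(x) & !is.na(y)
  y <- y[cc]
  n <- length(y)
  if (n < 2L * min_bucket) return(NULL)

  if (is.factor(x) && !is.ordered(x)) {
    f <- droplevels(x[cc])
    k <- nlevels(f)
    if (k < 2L) return(NULL)
    ord <- order(tapply(y, f, mean))        # exact for binary SS partitions
    lv <- levels(f)[ord]
    nj <- tabulate(f)[ord]
    sj <- as.numeric(tapply(y, f, sum))[ord]
    cn <- cumsum(nj)[-k]
    cs <- cumsum(sj)[-k]
    feas <- cn >= min_bucket & (n - cn) >= min_bucket
    if (!any(feas)) return(NULL)
    stat <- split_stat(cs, cn, n, sum(y), sum((y - mean(y))^2))
    stat[!feas] <- -Inf
    j <- which.max(stat)
    return(list(type = "categorical", left_levels = lv[seq_len(j)],
                stat = stat[j]))
  }

  g <- cit_scores(x[cc])
  o <- order(g)
  gs <- g[o]; ys <- y[o]
  cuts <- which(gs[-n] < gs[-1])            # boundaries of distinct values
  cuts <- cuts[cuts >= min_bucket & (n - cuts) >= min_bucket]
  if (!length(cuts)) return(NULL)
  cy <- cumsum(ys)
  stat <- split_stat(cy[cuts], cuts, n, sum(ys), sum((ys - mean(ys))^2))
  j <- which.max(stat)                      # ties: smallest cut wins
  i <- cuts[j]
  list(type = "numeric", cut = (gs[i] + gs[i + 1]) / 2, stat = stat[j])
}

# squared standardized two-sample statistic for a left group of size nl with
# response sum sl, out of n observations with total sum st and total sum of
# squares ssy: z^2 = (n-1) * (sl - nl*st/n)^2 / (ssy * nl * (n - nl) / n)
split_stat <- function(sl, nl, n, st, ssy) {
  if (ssy <= 0) return(rep(0, length(sl)))
  num <- (sl - nl * st / n)^2
  den <- ssy * nl * (n - nl) / n / (n - 1)
  num / den
}

#' Grow a conditional inference tree
#'
#' Binary recursive partitioning in which a node is split only when the
#' Bonferroni-adjusted permutation-test association between the response and
#' the best candidate is significant ([select_split_variable()]), using the
#' best feasible cut of that variable ([best_split_point()]). Character
#' candidates are treated as factors, `weedings`-style ordered encodings as
#' numeric scores, logicals as 0/1. Observations with a missing value of a
#' node's split variable are routed to the child holding the majority of the
#' non-missing observations. Deterministic for fixed data and parameters
#' (the asymptotic test uses no randomness).
#'
#' @param data data.frame.
#' @param response response column name (numeric).
#' @param candidates candidate predictor column names.
#' @param params a [cit_params()]; default `cit_params(nrow(data))`.
#' @return object of class `cit_tree`.
#' @export
grow_tree <- function(data, response, candidates, params = NULL) {
  stopifnot(is.data.frame(data), nrow(data) > 0L,
            response %in% names(data))
  missing_cand <- setdiff(candidates, names(data))
  if (length(missing_cand))
    stop_named("candidates not in data: %s",
               paste(missing_cand, collapse = ", "))
  params <- params %||% cit_params(nrow(data))
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  for (v in candidates) if (is.character(data[[v]]))
    data[[v]] <- factor(data[[v]])
  y <- data[[response]]

  evaluable <- candidates[vapply(candidates, function(v)
    sum(!duplicated(data[[v]][!is.na(data[[v]])])) >= 2L, logical(1))]

  next_id <- local({ i <- 0L; function() { i <<- i + 1L; i } })

  build <- function(idx, depth) {
    node <- list(id = next_id(), n = length(idx),
                 mean = mean(y[idx]), is_leaf = TRUE)
    if (depth >= params$max_depth || length(idx) < params$min_split)
      return(node)
    sel <- select_split_variable(data[idx, , drop = FALSE], response,
                                 candidates, params)
    if (is.null(sel)) return(node)
    x <- data[[sel$variable]][idx]
    sp <- best_split_point(x, y[idx], params$min_bucket)
    if (is.null(sp)) return(node)
    go_left <- if (sp$type == "numeric") cit_scores(x) <= sp$cut
               else as.character(x) %in% sp$left_levels
    miss <- is.na(go_left)
    nl <- sum(go_left, na.rm = TRUE)
    nr <- sum(!go_left, na.rm = TRUE)
    if (nl < params$min_bucket || nr < params$min_bucket) return(node)
    missing_dir <- if (nl >= nr) "left" else "right"
    go_left[miss] <- missing_dir == "left"
    node$is_leaf <- FALSE
    node$split_variable <- sel$variable
    node$split_type <- sp$type
    node$split_point <- if (sp$type == "numeric") sp$cut else sp$left_levels
    node$p_value <- sel$p_adjusted
    node$missing_dir <- missing_dir
    node$left <- build(idx[go_left], depth + 1L)
    node$right <- build(idx[!go_left], depth + 1L)
    node
  }

  structure(list(root = build(seq_along(y), 1L), params = params,
                 response = response, candidates = candidates,
                 evaluable = evaluable, n = length(y)),
            class = "cit_tree")
}

#' Split variables used anywhere in a tree
#' @param tree a `cit_tree`.
#' @return character vector (empty for a single-leaf tree).
#' @export
tree_variables <- function(tree) {
  stopifnot(inherits(tree, "cit_tree"))
  walk <- function(node) {
    if (node$is_leaf) return(character())
    c(node$split_variable, walk(node$left), walk(node$right))
  }
  unique(walk(tree$root))
}

# all root-to-leaf paths as lists of split variables
tree_paths <- function(tree) {
  walk <- function(node, path) {
    if (node$is_leaf) return(list(path))
    p <- c(path, node$split_variable)
    c(walk(node$left, p), walk(node$right, p))
  }
  walk(tree$root, character())
}

#' Predict yields from a conditional inference tree
#'
#' Routes each record to a leaf (missing split values follow the majority
#' direction recorded at training) and returns the leaf mean response.
#' @param tree a `cit_tree`.
#' @param newdata data.frame with the candidate columns (missing allowed).
#' @return numeric vector of leaf means.
#' @export
predict_tree <- function(tree, newdata) {
  stopifnot(inherits(tree, "cit_tree"))
  out <- numeric(nrow(newdata))
  route <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$is_leaf) { out[idx] <<- node$mean; return(invisible()) }
    x <- newdata[[node$split_variable]][idx]
    go_left <- if (node$split_type == "numeric") cit_scores(x) <= node$split_point
               else as.character(x) %in% node$split_point
    go_left[is.na(go_left)] <- node$missing_dir == "left"
    route(node$left, idx[go_left])
    route(node$right, idx[!go_left])
  }
  route(tree$root, seq_len(nrow(newdata)))
  out
}

#' Serialize a tree to JSON
#' @param tree a `cit_tree`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    if (node$is_leaf)
      return(list(id = node$id, n = node$n, mean = node$mean, leaf = TRUE))
    list(id = node$id, n = node$n, mean = node$mean, leaf = FALSE,
         split_variable = node$split_variable, split_type = node$split_type,
         split_point = node$split_point, p_value = node$p_value,
         missing_dir = node$missing_dir,
         left = strip(node$left), right = strip(node$right))
  }
  js <- jsonlite::toJSON(strip(tree$root), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @export
print.cit_tree <- function(x, ...) {
  cat(sprintf("conditional inference tree: n = %d, response = %s\n",
              x$n, x$response))
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$is_leaf) {
      cat(sprintf("%s* leaf: n = %d, mean = %.3f\n", pad, node$n, node$mean))
    } else {
      rule <- if (node$split_type == "numeric")
        sprintf("%s <= %.4g", node$split_variable, node$split_point)
      else sprintf("%s in {%s}", node$split_variable,
                   paste(node$split_point, collapse = ","))
      cat(sprintf("%s%s (p_adj = %.2g, n = %d)\n", pad, rule,
                  node$p_value, node$n))
      walk(node$left, indent + 1L)
      walk(node$right, indent + 1L)
    }
  }
  walk(x$root, 0L)
  invisible(x)
}
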