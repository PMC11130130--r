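test_that("association test detects strong signal and respects conventions", {
  set.seed(1)
  x <- rnorm(100)
  y <- x + rnorm(100, 0, 0.01)
  expect_lt(association_pvalue(x, y), 1e-6)
  expect_equal(association_pvalue(rep(1, 50), rnorm(50)), 1)  # constant x
  expect_equal(association_pvalue(rnorm(50), rep(2, 50)), 1)  # constant y
  expect_error(association_pvalue(rnorm(10), letters[1:10]), "numeric")

  # factor predictors use the chi-square quadratic form; for two groups it
  # agrees with the numeric two-sample form
  set.seed(2)
  g <- factor(sample(c("a", "b"), 80, TRUE))
  y2 <- rnorm(80) + (g == "b")
  expect_equal(association_pvalue(g, y2),
               association_pvalue(as.numeric(g == "b"), y2),
               tolerance = 1e-10)
})

test_that("asymptotic test holds its size at alpha = 0.05", {
  set.seed(3)
  p <- replicate(1000, association_pvalue(rnorm(100), rnorm(100)))
  rate <- mean(p < 0.05)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
})

test_that("Monte-Carlo p-value matches full permutation enumeration at n = 7", {
  set.seed(4)
  x <- rnorm(7)
  y <- c(0.2, 1.5, -0.7, 0.9, 2.2, -1.1, 0.4)
  # enumeration oracle over all 7! permutations of the response
  obs <- oracle_stat(x, y)
  P <- all_perms(7)
  exact <- mean(apply(P, 1, function(idx) oracle_stat(x, y[idx])) >=
                  obs - 1e-12)
  p_mc <- association_pvalue(x, y, n_perm = 10000, seed = 9)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(p_mc - exact), 3 * se + 2e-4)
})

test_that("split-variable selection: planted signal, Bonferroni, tie order", {
  set.seed(5)
  n <- 300
  d <- as.data.frame(matrix(rnorm(n * 10), n))
  names(d) <- paste0("x", 1:10)
  d$y <- d$x3 * 0.8 + rnorm(n)
  params <- cit_params(n)
  sel <- select_split_variable(d, "y", paste0("x", 1:10), params)
  expect_equal(sel$variable, "x3")
  expect_lt(sel$p_adjusted, params$alpha)

  # byte-identical candidate columns: first in declared order wins
  d$dup1 <- d$x3; d$dup2 <- d$x3
  sel2 <- select_split_variable(d, "y", c("dup1", "dup2"), params)
  expect_equal(sel2$variable, "dup1")

  expect_null(select_split_variable(d, "y", character(0), params))
})

test_that("all-null candidates are selected in about alpha of datasets", {
  set.seed(6)
  hits <- replicate(400, {
    d <- as.data.frame(matrix(rnorm(200 * 8), 200))
    names(d) <- paste0("x", 1:8)
    d$y <- rnorm(200)
    !is.null(select_split_variable(d, "y", paste0("x", 1:8),
                                   cit_params(200, alpha = 0.05)))
  })
  # Bonferroni keeps the familywise rate at or below alpha
  expect_lt(mean(hits), 0.05 + qnorm(0.995) * sqrt(0.05 * 0.95 / 400))
})

test_that("split points equal exhaustive search on tiny data", {
  # step response: the cut must fall between the step's neighbours
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1) + c(.01, -.02, .015, 0, .01, -.01, 0, .02)
  sp <- best_split_point(x, y, min_bucket = 1)
  expect_equal(sp$cut, 4.5)

  # exhaustive oracle: every midpoint, statistic computed independently
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    x <- sample(seq_len(n))            # distinct values
    y <- rnorm(n)
    sp <- best_split_point(x, y, min_bucket = 1)
    xs <- sort(x)
    cand <- (xs[-n] + xs[-1]) / 2
    stats_or <- vapply(cand, function(c0)
      oracle_stat(as.numeric(x <= c0), y), numeric(1))
    expect_equal(sp$cut, cand[which.max(stats_or)])
  }

  # min_bucket = n/2 leaves only the median cut
  x <- 1:8; y <- c(5, 1, 4, 2, 8, 3, 9, 7)
  sp <- best_split_point(x, y, min_bucket = 4)
  expect_equal(sp$cut, 4.5)

  # binary categorical: the single possible partition
  f <- factor(rep(c("u", "v"), each = 5))
  yy <- c(rnorm(5), rnorm(5, 3))
  sp <- best_split_point(f, yy, min_bucket = 1)
  expect_setequal(sp$left_levels, "u")
  expect_null(best_split_point(1:4, rnorm(4), min_bucket = 3))
})

test_that("categorical splits match exhaustive subset search", {
  set.seed(8)
  for (rep in 1:10) {
    f <- factor(sample(letters[1:4], 40, TRUE))
    y <- rnorm(40) + c(a = 0, b = 1.5, c = 0.2, d = 1.4)[as.character(f)]
    sp <- best_split_point(f, y, min_bucket = 2)
    lv <- levels(droplevels(f))
    k <- length(lv)
    best <- -Inf; best_set <- NULL
    for (m in 1:(2^(k - 1) - 1)) {      # enumerate binary level partitions
      left <- lv[as.logical(bitwAnd(m, 2^(seq_len(k) - 1)))]
      g <- as.numeric(f %in% left)
      if (sum(g) < 2 || sum(1 - g) < 2) next
      s <- oracle_stat(g, y)
      if (s > best) { best <- s; best_set <- left }
    }
    expect_true(setequal(sp$left_levels, best_set) ||
                  setequal(sp$left_levels, setdiff(lv, best_set)))
  }
})

test_that("grown trees honor the stopping rules and conservation identity", {
  tr <- small_truth(seed = 31)
  d <- generate_survey(tr)
  cand <- default_candidates()
  params <- cit_params(nrow(d))
  tree <- grow_tree(d, "yield_t_ha", c(cand$practices, cand$covariates),
                    params)

  depth_and_leaves <- function(node, depth = 1) {
    if (node$is_leaf)
      return(data.frame(depth = depth, n = node$n))
    rbind(depth_and_leaves(node$left, depth + 1),
          depth_and_leaves(node$right, depth + 1))
  }
  leaves <- depth_and_leaves(tree$root)
  expect_lte(max(leaves$depth), params$max_depth)
  expect_true(all(leaves$n >= params$min_bucket))

  # sum over leaves of n * mean equals the total training response
  tot <- sum(d$yield_t_ha[!is.na(d$yield_t_ha)])
  pred <- predict_tree(tree, d)
  expect_equal(sum(predict_tree(tree, d[!is.na(d$yield_t_ha), ])),
               tot, tolerance = 1e-8)

  # constant response: single leaf, prediction is the grand mean
  dc <- d; dc$yield_t_ha <- 2.5
  tc <- grow_tree(dc, "yield_t_ha", cand$practices, params)
  expect_true(tc$root$is_leaf)
  expect_equal(unique(predict_tree(tc, dc)), 2.5)
  expect_length(tree_variables(tc), 0)
})

test_that("tree_variables matches a manual traversal and missing routing works", {
  set.seed(9)
  n <- 400
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 1.5 * (d$a > 0) + 0.8 * (d$b > 0.5) + rnorm(n, 0, 0.4)
  tree <- grow_tree(d, "y", c("a", "b", "c"),
                    cit_params(n, min_split = 40, min_bucket = 20))
  vars <- tree_variables(tree)
  manual <- character()
  walk <- function(nd) if (!nd$is_leaf) {
    manual <<- c(manual, nd$split_variable); walk(nd$left); walk(nd$right)
  }
  walk(tree$root)
  expect_setequal(vars, unique(manual))
  expect_true(all(c("a", "b") %in% vars))

  # records with a missing split value still get a prediction
  d2 <- d[1:10, ]; d2$a <- NA
  expect_true(all(is.finite(predict_tree(tree, d2))))
})

test_that("lowering alpha never grows the tree", {
  tr <- small_truth(seed = 17)
  d <- generate_survey(tr)
  cand <- default_candidates()$practices
  n_nodes <- function(tree) {
    cnt <- function(nd) if (nd$is_leaf) 1 else 1 + cnt(nd$left) + cnt(nd$right)
    cnt(tree$root)
  }
  sizes <- vapply(c(0.2, 0.05, 0.01, 0.001), function(a)
    n_nodes(grow_tree(d, "yield_t_ha", cand, cit_params(nrow(d), alpha = a))),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("tree JSON serialization round-trips the structure", {
  set.seed(10)
  d <- data.frame(x = rnorm(200))
  d$y <- (d$x > 0) + rnorm(200, 0, 0.1)
  tree <- grow_tree(d, "y", "x", cit_params(200, min_split = 40,
                                            min_bucket = 20))
  js <- jsonlite::fromJSON(tree_to_json(tree))
  expect_equal(js$split_variable, tree$root$split_variable)
  expect_equal(js$n, tree$root$n)
  expect_equal(js$left$n + js$right$n, js$n)
})
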