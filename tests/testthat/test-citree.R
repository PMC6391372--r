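test_that("permutation p-values detect strong association and obey conventions", {
  set.seed(1)
  x <- rnorm(40)
  y <- 2 * x + rnorm(40, 0, 0.01)
  expect_lte(association_pvalue(x, y, n_perm = 4999, seed = 1), 0.001)
  expect_equal(association_pvalue(x, rep(5, 40), n_perm = 99, seed = 1), 1)
  expect_equal(association_pvalue(rep(2, 40), y, n_perm = 99, seed = 1), 1)
  p1 <- association_pvalue(x, y + rnorm(40), n_perm = 199, seed = 7)
  p2 <- association_pvalue(x, y + rnorm(40), n_perm = 199, seed = 7)
  expect_identical(p1, p2)  # reproducible given seed
  expect_gt(p1, 0)
  expect_lte(p1, 1)
})

test_that("categorical association uses the between-group statistic", {
  set.seed(2)
  g <- factor(rep(c("a", "b", "c"), each = 15))
  y <- c(rnorm(15, 0), rnorm(15, 3), rnorm(15, 6))
  expect_lte(association_pvalue(g, y, n_perm = 999, seed = 1), 0.01)
  expect_gt(association_pvalue(g, rnorm(45), n_perm = 199, seed = 1), 0.05)
})

test_that("type-I error of the permutation test is near nominal", {
  set.seed(11)
  rej <- vapply(1:300, function(i) {
    association_pvalue(rnorm(30), rnorm(30), n_perm = 199) <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.09)
})

test_that("variable selection finds a planted signal and stops under the null", {
  set.seed(3)
  make_X <- function(n) {
    X <- as.data.frame(matrix(rnorm(n * 30), n))
    names(X) <- paste0("v", 1:30)
    X$state <- factor(sample(c("IA", "IL", "MN"), n, replace = TRUE))
    X
  }
  hits <- 0
  for (i in 1:5) {
    X <- make_X(60)
    y <- 3 * X$v7 + rnorm(60, 0, 0.5)
    sel <- select_split_variable(X, y, citree_controls(n_perm = 1999, seed = i))
    if (!is.null(sel) && sel$variable == "v7") hits <- hits + 1
  }
  expect_gte(hits, 4)
  stops <- 0
  for (i in 1:5) {
    X <- make_X(60)
    sel <- select_split_variable(X, rnorm(60), citree_controls(n_perm = 999, seed = i))
    if (is.null(sel)) stops <- stops + 1
  }
  expect_gte(stops, 4)
})

test_that("identical columns tie-break by column order", {
  set.seed(4)
  x <- rnorm(50)
  X <- data.frame(a = x, b = x)
  y <- 2 * x + rnorm(50, 0, 0.1)
  sel <- select_split_variable(X, y, citree_controls(n_perm = 999, seed = 1))
  expect_equal(sel$variable, "a")
})

test_that("binary splits sit at the midpoint of a planted step", {
  x <- rep(1:10, each = 4)
  y <- ifelse(x <= 5, 0, 10)
  sp <- best_binary_split(x, y, min_terminal = 4)
  expect_equal(sp$threshold, 5.5)
})

test_that("the split equals an exhaustive-search oracle on random data", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(40); y <- rnorm(40) + ifelse(x > 0, s %% 3, 0)
    sp <- best_binary_split(x, y, min_terminal = 5L)
    expect_equal(sp$threshold, split_oracle(x, y, 5L))
  }
})

test_that("categorical splits order levels by mean and return a level set", {
  set.seed(5)
  g <- factor(rep(c("a", "b", "c", "d"), each = 10))
  y <- c(rnorm(10, 0), rnorm(10, 10), rnorm(10, 0.2), rnorm(10, 9.8))
  sp <- best_binary_split(g, y, min_terminal = 5L)
  expect_equal(sp$type, "factor")
  expect_setequal(sp$left_levels, c("a", "c"))
})

test_that("fitted trees honor size and depth controls and conserve the mean", {
  g <- gen_citree_dataset(n = 186, seed = 2)
  ctl <- citree_controls(n_perm = 1999, seed = 1)
  tree <- fit_citree(g$data[, tree_predictor_names()], g$data$yield, ctl)
  nd <- tree$nodes
  leaves <- nd[is.na(nd$split_var), ]
  internal <- nd[!is.na(nd$split_var), ]
  expect_true(all(leaves$n >= ctl$min_terminal))
  expect_true(all(internal$n >= ctl$min_internal))
  expect_true(max(nd$depth) <= ctl$max_depth)
  # leaf means weighted by counts reproduce the grand mean exactly
  expect_equal(sum(leaves$mean * leaves$n) / sum(leaves$n), mean(g$data$yield))
  # every observation is routed to exactly one leaf
  expect_true(all(tree$where %in% leaves$id))
  # depth cap produces at most a root split
  shallow <- fit_citree(g$data[, tree_predictor_names()], g$data$yield,
                        citree_controls(n_perm = 999, seed = 1, max_depth = 2))
  expect_lte(max(shallow$nodes$depth), 2)
})

test_that("pure-noise yields give a single leaf at the grand mean", {
  g <- gen_citree_dataset(n = 120, seed = 3)
  set.seed(6)
  y <- rnorm(120, 3500, 200)
  tree <- fit_citree(g$data[, tree_predictor_names()], y,
                     citree_controls(n_perm = 999, seed = 1))
  expect_equal(nrow(tree$nodes), 1)
  expect_equal(tree$nodes$mean[1], mean(y))
})

test_that("predictions equal the routed leaf mean", {
  g <- gen_citree_dataset(n = 186, seed = 4)
  X <- g$data[, tree_predictor_names()]
  tree <- fit_citree(X, g$data$yield, citree_controls(n_perm = 1999, seed = 1))
  pred <- predict_citree(tree, X)
  leaves <- tree$nodes[is.na(tree$nodes$split_var), ]
  expect_equal(pred, leaves$mean[match(tree$where, leaves$id)])
})

test_that("relaxing the terminal size keeps the first two split variables", {
  g <- gen_citree_dataset(n = 186, seed = 5)
  X <- g$data[, tree_predictor_names()]
  strict <- fit_citree(X, g$data$yield, citree_controls(n_perm = 1999, seed = 1))
  loose <- fit_citree(X, g$data$yield,
                      citree_controls(n_perm = 1999, seed = 1,
                                      min_terminal = 10, min_internal = 20))
  top2 <- function(tr) {
    nd <- tr$nodes[!is.na(tr$nodes$split_var), ]
    nd$split_var[order(nd$depth, nd$id)][1:2]
  }
  expect_equal(top2(strict), top2(loose))
})

test_that("tree serialization and printing expose the fitted structure", {
  g <- gen_citree_dataset(n = 186, seed = 6)
  tree <- fit_citree(g$data[, tree_predictor_names()], g$data$yield,
                     citree_controls(n_perm = 1999, seed = 1))
  js <- jsonlite::fromJSON(citree_to_json(tree))
  expect_equal(nrow(js$nodes), nrow(tree$nodes))
  expect_output(print(tree), "vpd_mean_W3")
})

test_that("the within-stratum Vpd slope recovers a planted effect", {
  set.seed(7)
  n <- 100
  d <- data.frame(state = sample(c("IA", "IL", "MO"), n, replace = TRUE),
                  vpd_mean_W3 = runif(n, 1.5, 3))
  d$yield <- 4000 - 1135 * d$vpd_mean_W3 + rnorm(n, 0, 150)
  sl <- node_vpd_slope(d, "vpd_mean_W3")
  expect_gt(-1135, sl$ci[1])
  expect_lt(-1135, sl$ci[2])
  expect_gt(sl$p_homogeneity, 0.01)  # no planted state-by-Vpd interaction
  # independence: CI covers zero
  d$yield <- rnorm(n, 3500, 200)
  sl0 <- node_vpd_slope(d, "vpd_mean_W3")
  expect_true(sl0$ci[1] < 0 && sl0$ci[2] > 0)
  # exact fit through collinear points (single state)
  d3 <- data.frame(state = "IA", vpd_mean_W3 = c(1, 2, 3),
                   yield = c(4000, 3000, 2000))
  # perfect fit: suppress the stats "essentially perfect fit" warning
  expect_equal(suppressWarnings(node_vpd_slope(d3, "vpd_mean_W3")$slope), -1000)
  d3$vpd_mean_W3 <- 2
  expect_error(node_vpd_slope(d3, "vpd_mean_W3"), "constant")
})
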