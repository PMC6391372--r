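test_that("stratified split matches the rounding rule and is reproducible", {
  d <- data.frame(state = rep("IA", 20), year = rep(2010, 20))
  sp <- stratified_split(d, 0.85, seed = 1)
  expect_length(sp$train, 17)
  expect_length(sp$test, 3)
  sp2 <- stratified_split(d, 0.85, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(d, 0.85, seed = 2)
  expect_false(identical(sp$train, sp3$train))
  expect_setequal(c(sp$train, sp$test), 1:20)
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("singleton strata go to training with a message", {
  d <- data.frame(state = c("IA", "IA", "IA", "IL"), year = 2010)
  expect_message(sp <- stratified_split(d, 0.5, seed = 1), "singleton")
  expect_true(4 %in% sp$train)
})

test_that("componentwise-linear boosting converges to the least-squares line", {
  set.seed(1)
  x <- rnorm(80)
  y <- 3 + 2 * x + rnorm(80, 0, 0.5)
  X <- data.frame(x = x)
  m <- fit_boost(X, y, boost_controls(n_iter = 600, step = 0.2,
                                      base_learner = "componentwise_linear"))
  ols <- lm(y ~ x)
  expect_lt(max(abs(predict_boost(m, X) - fitted(ols)) / abs(fitted(ols))), 0.01)
  expect_true(all(diff(m$train_mse) <= 1e-12))
})

test_that("training MSE is monotone non-increasing for stumps too", {
  set.seed(2)
  X <- data.frame(a = rnorm(60), b = rnorm(60))
  y <- ifelse(X$a > 0, 5, 0) + rnorm(60, 0, 0.5)
  m <- fit_boost(X, y, boost_controls(n_iter = 200, base_learner = "stump"))
  expect_true(all(diff(m$train_mse) <= 1e-12))
  expect_lt(tail(m$train_mse, 1), var(y))
})

test_that("zero iterations give a constant-offset model whose RMSE is sd(y)", {
  set.seed(3)
  X <- data.frame(a = rnorm(50))
  y <- rnorm(50, 100, 10)
  m <- fit_boost(X, y, boost_controls(n_iter = 0))
  expect_equal(unique(predict_boost(m, X)), mean(y))
  ev <- evaluate_boost(m, X, y)
  expect_equal(ev$rmse, sqrt(mean((y - mean(y))^2)))
  expect_equal(ev$r2, 0)
})

test_that("independent features give near-zero held-out R-squared", {
  set.seed(4)
  X <- as.data.frame(matrix(rnorm(150 * 5), 150))
  y <- rnorm(150)
  m <- fit_boost(X[1:100, ], y[1:100],
                 boost_controls(n_iter = 100, base_learner = "componentwise_linear"))
  ev <- evaluate_boost(m, X[101:150, ], y[101:150])
  expect_lt(ev$r2, 0.25)
})

test_that("halving the step with doubled iterations changes predictions < 1%", {
  set.seed(5)
  X <- as.data.frame(matrix(rnorm(120 * 4), 120))
  y <- 2 * X$V1 - X$V3 + rnorm(120, 0, 0.3)
  m1 <- fit_boost(X, y, boost_controls(n_iter = 600, step = 0.2,
                                       base_learner = "componentwise_linear"))
  m2 <- fit_boost(X, y, boost_controls(n_iter = 1200, step = 0.1,
                                       base_learner = "componentwise_linear"))
  p1 <- predict_boost(m1, X); p2 <- predict_boost(m2, X)
  expect_lt(max(abs(p1 - p2)) / sd(y), 0.01)
})

test_that("the year feature absorbs a technology trend that would bias contrasts", {
  set.seed(6)
  n <- 300
  year <- sample(2007:2016, n, replace = TRUE)
  # weather feature drifts with year (warming), and yield has both a true
  # weather effect and an independent technology trend
  x <- rnorm(n) + 0.4 * (year - 2011)
  trend <- 60
  y <- -500 * x + trend * (year - 2007) + rnorm(n, 0, 50)
  Xfull <- data.frame(x = x, year = year)
  m_with <- fit_boost(Xfull, y, boost_controls(base_learner = "componentwise_linear"))
  m_without <- fit_boost(Xfull["x"], y, boost_controls(base_learner = "componentwise_linear"))
  # counterfactual contrast: change x by +1 at fixed year
  probe0 <- data.frame(x = 0, year = 2011)
  probe1 <- data.frame(x = 1, year = 2011)
  c_with <- predict_boost(m_with, probe1) - predict_boost(m_with, probe0)
  c_without <- predict_boost(m_without, probe1) - predict_boost(m_without, probe0)
  # omitted-variable algebra: dropping year shifts the slope by
  # trend * cov(year, x) / var(x)
  bias <- trend * cov(year, x) / var(x)
  expect_lt(abs(c_with - (-500)), 25)
  expect_lt(abs(c_without - (-500 + bias)), 25)
  expect_gt(abs(bias), 60)  # the planted confounding is material
})

test_that("prediction demands the full feature schema", {
  set.seed(7)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  m <- fit_boost(X, rnorm(30), boost_controls(n_iter = 20))
  expect_error(predict_boost(m, data.frame(a = 1)), "missing feature")
})

test_that("boosting models serialize to JSON", {
  set.seed(8)
  X <- data.frame(a = rnorm(40))
  m <- fit_boost(X, 2 * X$a, boost_controls(n_iter = 10))
  js <- jsonlite::fromJSON(boost_to_json(m))
  expect_equal(js$step, 0.2)
  expect_equal(nrow(js$learners), 10)
})
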