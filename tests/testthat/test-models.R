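test_that("the baseline predicts the training mean, ignoring the inputs", {
  d <- tibble::tibble(pH = c(1, 5, 9), target = c(2, 4, 6))
  m <- fit_soft_sensor(d, family = "baseline")
  expect_equal(predict(m, d), rep(4, 3))
  wild <- tibble::tibble(pH = c(-100, 0, 3000))
  expect_equal(predict(m, wild), rep(4, 3))
})

test_that("a depth-1 tree finds the exhaustive-search split", {
  # hand oracle: squared error is minimized splitting between x = 1 and 2
  d <- tibble::tibble(x = c(0, 1, 2, 3), target = c(0, 0, 10, 10))
  m <- fit_soft_sensor(d, family = "cart", config = list(max_depth = 1))
  expect_equal(predict(m, d), c(0, 0, 10, 10))
  expect_equal(sort(unique(predict(m, d))), c(0, 10))
})

test_that("tree training error is non-increasing in depth", {
  set.seed(31)
  d <- tibble::tibble(x1 = runif(400), x2 = runif(400))
  d$target <- sin(6 * d$x1) + (d$x2 > 0.5) * 2 + rnorm(400, 0, 0.1)
  maes <- vapply(c(1, 2, 3, 5, 8, 12), function(dep) {
    m <- fit_soft_sensor(d, family = "cart", config = list(max_depth = dep))
    mean(abs(d$target - predict(m, d)))
  }, numeric(1))
  expect_true(all(diff(maes) <= 1e-12))
})

test_that("ridge regression with a vanishing penalty recovers an exact linear law", {
  set.seed(17)
  d <- tibble::tibble(a = rnorm(200, 3, 2), b = runif(200, -5, 5))
  d$target <- 2.5 * d$a - 4 * d$b + 7
  nz <- fit_normalizer(d, c("a", "b"), power_transform = FALSE)
  m <- fit_soft_sensor(d, family = "lr", config = list(l2 = 1e-10),
                       normalizer = nz)
  expect_equal(predict(m, d), d$target, tolerance = 1e-6)
  # slope in original units: coefficient divided by the feature scale
  expect_equal(unname(m$fit$coef["a"] / nz$scale[["a"]]), 2.5,
               tolerance = 1e-6)
  expect_equal(unname(m$fit$coef["b"] / nz$scale[["b"]]), -4,
               tolerance = 1e-6)
})

test_that("ridge solution matches glmnet at a matched penalty", {
  skip_if_not_installed("glmnet")
  set.seed(41)
  n <- 500
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$target <- 1.5 * d$a - 2 * d$b + 0.5 * d$c + rnorm(n, 0, 0.3)
  l2 <- 0.37
  nz <- fit_normalizer(d, c("a", "b", "c"), power_transform = FALSE)
  m <- fit_soft_sensor(d, family = "lr", config = list(l2 = l2),
                       normalizer = nz)
  xn <- as.matrix(apply_normalizer(nz, d)[, c("a", "b", "c")])
  # glmnet minimizes RSS/(2n) + lambda/2 * ||b||^2 for alpha = 0,
  # i.e. RSS + n*lambda*||b||^2: lambda = l2/n matches this ridge
  g <- glmnet::glmnet(xn, d$target, alpha = 0, lambda = l2 / n,
                      standardize = FALSE, intercept = TRUE,
                      thresh = 1e-14)
  # glmnet solves iteratively; agreement to ~0.1% is solver tolerance
  expect_equal(unname(m$fit$coef), as.numeric(g$beta), tolerance = 1e-3)
})

test_that("a forest of identical trees predicts like its single tree", {
  set.seed(53)
  d <- tibble::tibble(x1 = runif(200), x2 = runif(200))
  d$target <- 3 * d$x1 + rnorm(200, 0, 0.05)
  m <- fit_soft_sensor(d, family = "rf",
                       config = list(max_depth = 4, n_estimators = 20),
                       mtry_fraction = 1, seed = 9)
  # disable the two sources of tree diversity via ranger's own controls
  m$fit <- ranger::ranger(x = as.data.frame(
    apply_normalizer(m$normalizer, d[, c("x1", "x2")])), y = d$target,
    num.trees = 20, max.depth = 4, mtry = 2, min.node.size = 5,
    replace = FALSE, sample.fraction = 1, seed = 9, num.threads = 1)
  per_tree <- predict(m$fit, data = as.data.frame(
    apply_normalizer(m$normalizer, d[, c("x1", "x2")])),
    predict.all = TRUE, num.threads = 1)$predictions
  expect_equal(apply(per_tree, 1, stats::var), rep(0, 200), tolerance = 1e-20)
  expect_equal(predict(m, d), per_tree[, 1])
})

test_that("predictions are row-pure: permuting rows permutes predictions", {
  set.seed(61)
  d <- tibble::tibble(x1 = runif(100), x2 = runif(100))
  d$target <- d$x1 * 5 + d$x2^2 + rnorm(100, 0, 0.1)
  perm <- sample(100)
  for (fam in c("lr", "cart", "rf")) {
    m <- fit_soft_sensor(d, family = fam,
                         config = list(l2 = 0.1, max_depth = 6,
                                       n_estimators = 15))
    expect_equal(predict(m, d[perm, ]), predict(m, d)[perm], info = fam)
  }
})

test_that("prediction fails loudly when feature columns are missing", {
  d <- tibble::tibble(x1 = runif(50), x2 = runif(50), target = runif(50))
  m <- fit_soft_sensor(d, family = "lr", config = list(l2 = 0.1))
  expect_error(predict(m, d[, "x1", drop = FALSE]), "x2")
})

test_that("forest importance identifies the causal variable and sums to one", {
  set.seed(71)
  n <- 10000
  d <- tibble::tibble(
    pH = rnorm(n, 8, 0.5),
    Temperature = rnorm(n, 18, 4),
    noise = rnorm(n)
  )
  # nonlinear single-variable coupling: only pH drives the target
  d$target <- exp(d$pH - 7) + rnorm(n, 0, 0.1)
  m <- fit_soft_sensor(d, family = "rf",
                       config = list(max_depth = 20, n_estimators = 50),
                       seed = 5)
  imp <- feature_importance(m, d)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_true(all(abs(imp$correlation) <= 1))
  expect_equal(imp$feature[1], "pH")
  expect_lt(imp$importance[imp$feature == "noise"],
            min(imp$importance[imp$feature == "pH"]))

  lr <- fit_soft_sensor(d, family = "lr", config = list(l2 = 0.1))
  expect_error(feature_importance(lr, d), "random-forest")
})

test_that("named feature subsets restrict matrices canonically and idempotently", {
  rec <- clean_records(spiky_sim()$records)$records
  f <- build_dataset(rec, "input_day", "output_day_median")
  three <- restrict_features(f, feature_subset("3-AGG"))
  expect_equal(feature_names(three),
               c("pH_day_max", "Temperature_day_min", "SystemBattery_day_min"))
  five <- restrict_features(f, feature_subset("5-AGG"))
  expect_equal(length(feature_names(five)), 5)
  expect_equal(sum(grepl("^pH_", feature_names(five))), 2)
  expect_identical(restrict_features(three, feature_subset("3-AGG")), three)
  expect_error(restrict_features(f, feature_subset("custom", "pH_week_max")),
               "pH_week_max")
  expect_error(feature_subset("custom"), "features")
})
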