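test_that("chunks partition the rows contiguously with near-equal sizes", {
  for (case in list(c(100, 10), c(101, 10), c(97, 7), c(10, 2))) {
    plan <- make_chunks(case[1], k = case[2])
    expect_equal(length(plan$chunk), case[1])
    expect_equal(sort(unique(plan$chunk)), seq_len(case[2]))
    expect_lte(diff(range(plan$sizes)), 1)
    # contiguity: chunk index is non-decreasing along the rows
    expect_true(all(diff(plan$chunk) >= 0))
    # partition: disjoint cover with the declared sizes
    expect_equal(as.integer(table(plan$chunk)), plan$sizes)
  }
  expect_error(make_chunks(5, k = 6), "cannot split")
  expect_error(make_chunks(5, k = 1), "at least 2")
})

test_that("sampled configurations are reproducible and in range", {
  cfgs <- sample_configs(c("lr", "cart", "rf"), n = 25, seed = 123)
  expect_equal(nrow(cfgs), 75)
  expect_identical(cfgs, sample_configs(c("lr", "cart", "rf"), n = 25,
                                        seed = 123))
  expect_false(identical(cfgs, sample_configs(c("lr", "cart", "rf"), n = 25,
                                              seed = 124)))
  lr <- cfgs[cfgs$family == "lr", ]
  expect_true(all(lr$l2 >= 1e-4 & lr$l2 <= 1))
  cart <- cfgs[cfgs$family == "cart", ]
  expect_true(all(cart$max_depth >= 1 & cart$max_depth <= 500))
  rf <- cfgs[cfgs$family == "rf", ]
  expect_true(all(rf$n_estimators >= 2 & rf$n_estimators <= 200))
  expect_equal(nrow(sample_configs("baseline", n = 25)), 1)
  expect_error(sample_configs("gbm"), "unknown family")
})

test_that("the search trains configs x folds models and ranks by mean MAE", {
  set.seed(3)
  d <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (0:199) * 900,
    buoy_id = "beach", x = rnorm(200)
  )
  d$target <- 2 * d$x + rnorm(200, 0, 0.2)
  s <- run_search(d, family = "cart", k = 5, n_configs = 4, seed = 2)
  expect_equal(s$n_models, 4 * 5)
  lb <- s$leaderboard
  expect_equal(nrow(lb), 4)
  expect_true(all(diff(lb$mean_mae) >= 0))
  expect_equal(lb$mean_mae,
               vapply(lb$fold_mae, mean, numeric(1)))
  expect_equal(length(lb$fold_mae[[1]]), 5)
  expect_identical(s$best_config$config_id, lb$config_id[1])
})

test_that("baseline fold models predict their training chunks' target mean", {
  d <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (0:99) * 900,
    buoy_id = "beach", x = rnorm(100), target = rnorm(100, 10, 3)
  )
  s <- run_search(d, family = "baseline", k = 5, seed = 1)
  oof <- assemble_oof(d, s)
  plan <- s$plan
  for (ch in 1:5) {
    train_mean <- mean(d$target[plan$chunk != ch])
    expect_equal(unique(oof$y_pred[oof$fold == ch]), train_mean)
    # closed-form MAE check for the baseline on its validation chunk
    expect_equal(mean(abs(oof$y_true[oof$fold == ch] - train_mean)),
                 mean(abs(d$target[plan$chunk == ch] - train_mean)))
  }
})

test_that("out-of-fold assembly covers every row exactly once, leakage-free", {
  sim <- three_year_sim()
  rec <- clean_records(sim$records)$records
  d <- build_dataset(rec, "input_orig", "output_orig")
  s <- run_search(d, family = "lr", k = 10, n_configs = 3, seed = 4)
  oof <- assemble_oof(d, s)
  expect_equal(nrow(oof), nrow(d))
  key <- paste(oof$timestamp, oof$buoy_id)
  expect_false(any(duplicated(key)))
  expect_setequal(key, paste(d$timestamp, d$buoy_id))
  # each row's fold is the chunk that contains it
  expect_equal(oof$fold, s$plan$chunk)
  # with 3 calendar years, every (buoy, month) pools 3 year-occurrences
  pooling <- oof |>
    dplyr::mutate(year = lubridate::year(timestamp)) |>
    dplyr::group_by(buoy_id, month) |>
    dplyr::summarise(n_years = dplyr::n_distinct(year), .groups = "drop")
  expect_true(all(pooling$n_years == 3))
  expect_equal(nrow(pooling), 24)
})

test_that("no shuffling: training rows keep their temporal order within folds", {
  d <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (0:59) * 900,
    buoy_id = "beach", x = rnorm(60), target = rnorm(60)
  )
  plan <- make_chunks(d, k = 6)
  for (ch in c(1, 3, 6)) {
    idx <- which(plan$chunk != ch)
    expect_true(all(diff(idx) > 0))
    expect_true(all(diff(as.numeric(d$timestamp[idx])) > 0))
    # validation rows never appear in training
    expect_length(intersect(idx, which(plan$chunk == ch)), 0)
  }
})

test_that("normalizers are fold-local: they differ from a global fit under drift", {
  set.seed(13)
  # strong distribution drift across time
  d <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (0:499) * 900,
    buoy_id = "beach",
    x = c(rnorm(250, 0, 1), rnorm(250, 30, 5))
  )
  d$target <- d$x + rnorm(500, 0, 0.1)
  plan <- make_chunks(d, k = 5)
  global <- fit_normalizer(d, "x")
  fold1 <- fit_normalizer(d[plan$chunk != 5, ], "x")
  expect_gt(abs(global$center[["x"]] - fold1$center[["x"]]), 1)
  expect_false(isTRUE(all.equal(global$lambda[["x"]], fold1$lambda[["x"]])))
})

test_that("a linear target is recovered to numerical precision by the fold models", {
  set.seed(19)
  d <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (0:499) * 900,
    buoy_id = "beach", a = rnorm(500, 2, 3), b = runif(500, -1, 1)
  )
  d$target <- 3 * d$a - 2 * d$b + 1
  cfg <- tibble::tibble(family = "lr", config_id = 1L, l2 = 1e-12,
                        max_depth = NA_integer_, n_estimators = NA_integer_)
  s <- run_search(d, family = "lr", k = 5, configs = cfg, seed = 1,
                  power_transform = FALSE)
  expect_lt(s$best_config$mean_mae, 1e-8)
})

test_that("a reserved holdout chunk is predicted by a model that never saw it", {
  d <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (0:199) * 900,
    buoy_id = "beach", x = rnorm(200)
  )
  d$target <- d$x * 2 + rnorm(200, 0, 0.1)
  s <- run_search(d, family = "lr", k = 5, n_configs = 2, seed = 6,
                  holdout_chunk = 5)
  expect_equal(s$n_models, 2 * 4) # search runs on the 4 remaining chunks
  oof <- assemble_oof(d, s)
  expect_equal(nrow(oof), sum(s$plan$chunk == 5))
  expect_setequal(oof$timestamp, d$timestamp[s$plan$chunk == 5])
})
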