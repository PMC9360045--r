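test_that("rolling statistics match the brute-force oracle on gappy random series", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    # irregular spacing emulates cleaning gaps
    t0 <- as.POSIXct("2021-03-01", tz = "UTC") +
      cumsum(sample(c(900, 1800, 3600, 7200), n, replace = TRUE))
    x <- rnorm(n, 10, 4)
    d <- tibble::tibble(timestamp = t0, v = x)
    for (w in c("hour", "day")) {
      got <- rolling_stats(d, v, window = w)
      wsec <- if (w == "hour") 3600 else 86400
      for (s in c("mean", "std", "median", "min", "max")) {
        expect_equal(got[[paste("v", w, s, sep = "_")]],
                     oracle_roll(t0, x, wsec, s),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("rolling windows are trailing, ordered, and well-defined at the start", {
  d <- tibble::tibble(
    timestamp = as.POSIXct("2020-07-01", tz = "UTC") + (0:3) * 900,
    v = c(1, 2, 3, 4)
  )
  got <- rolling_stats(d, v, window = "hour")
  expect_equal(got$v_hour_mean[4], 2.5)
  expect_equal(got$v_hour_min[4], 1)
  expect_equal(got$v_hour_max[4], 4)
  expect_equal(got$v_hour_median[4], 2.5)
  expect_equal(got$v_hour_std[4], 1.29099444873581, tolerance = 1e-12)
  # single-sample window at the series start
  expect_equal(got$v_hour_mean[1], 1)
  expect_equal(got$v_hour_std[1], 0)
  expect_equal(got$v_hour_n, 1:4)

  # anti-leakage: changing a future value never changes earlier windows
  d2 <- d
  d2$v[4] <- 1000
  got2 <- rolling_stats(d2, v, window = "hour")
  expect_equal(got2$v_hour_mean[1:3], got$v_hour_mean[1:3])
  expect_equal(got2$v_hour_max[1:3], got$v_hour_max[1:3])

  # windowed order statistics are coherent
  sim <- spiky_sim()
  f <- build_input_variant(clean_records(sim$records)$records, "input_day")
  expect_true(all(f$pH_day_min <= f$pH_day_median &
                    f$pH_day_median <= f$pH_day_max))
  expect_true(all(f$pH_day_min <= f$pH_day_mean &
                    f$pH_day_mean <= f$pH_day_max))

  expect_error(rolling_stats(d, v, stats = "mode"), "unknown statistic")
})

test_that("input variants produce exactly the declared feature sets", {
  rec <- clean_records(spiky_sim()$records)$records
  counts <- c(input_orig = 4, input_hour = 24, input_day = 24, input_mix = 44)
  for (v in names(counts)) {
    f <- build_input_variant(rec, v)
    expect_equal(length(feature_names(f)), unname(counts[v]))
    expect_false(anyNA(f))
  }
  f <- build_input_variant(rec, "input_mix")
  expect_true(all(c("pH_day_max", "Temperature_day_min", "SystemBattery_day_min",
                    "Conductivity_day_max", "pH_day_min", "pH_hour_std") %in%
                    names(f)))
  # input_orig is the identity on the raw input channels
  fo <- build_input_variant(rec, "input_orig")
  expect_equal(fo$pH, rec$ph)
  expect_equal(fo$Temperature, rec$temperature)
  expect_error(build_input_variant(rec, "input_week"))
})

test_that("aggregations never mix buoys", {
  rec <- dplyr::bind_rows(
    make_records(8, buoy = "beach", ph = 7),
    make_records(8, buoy = "dam", ph = 9)
  )
  f <- build_input_variant(rec, "input_hour")
  expect_equal(unique(f$pH_hour_mean[f$buoy_id == "beach"]), 7)
  expect_equal(unique(f$pH_hour_mean[f$buoy_id == "dam"]), 9)
})

test_that("output variants aggregate chlorophyll as declared", {
  rec <- make_records(4, chlorophyll = 7)
  for (v in c("output_orig", "output_hour_mean", "output_hour_median",
              "output_day_mean", "output_day_median")) {
    y <- build_output_variant(rec, v)
    expect_equal(y$target, rep(7, 4), info = v)
  }
  rec2 <- make_records(4, chlorophyll = c(0, 100, 0, 0))
  expect_equal(build_output_variant(rec2, "output_hour_median")$target[4], 0)
  expect_equal(build_output_variant(rec2, "output_hour_mean")$target[4], 25)
  expect_error(build_output_variant(rec2, "output_week_mean"))
  expect_error(build_output_variant(dplyr::select(rec2, -"chlorophyll"),
                                    "output_orig"), "chlorophyll")
})

test_that("day-median output suppresses spike-driven alarm crossings", {
  rec <- clean_records(spiky_sim()$records)$records
  orig <- build_output_variant(rec, "output_orig")
  med <- build_output_variant(rec, "output_day_median")
  # independent crossing count: a crossing is an up-transition over 10 ug/L
  crossings <- function(x) sum(x[-1] > 10 & x[-length(x)] <= 10)
  expect_lt(crossings(med$target), crossings(orig$target))
  # aggregation never increases the target spread
  expect_lte(sd(med$target), sd(orig$target))
})

test_that("the experiment grid enumerates all 20 variant pairs once", {
  g <- experiment_grid()
  expect_equal(nrow(g), 20)
  expect_equal(nrow(dplyr::distinct(g[, 1:2])), 20)
  expect_true(any(g$input_variant == "input_orig" &
                    g$output_variant == "output_orig"))
  expect_equal(sort(unique(g$n_features)), c(4, 24, 44))
})

test_that("normalizer standardizes its own fit data and freezes its state", {
  set.seed(7)
  d <- tibble::tibble(a = rexp(300, 0.2), b = rnorm(300, 50, 9),
                      c = runif(300, -3, 3))
  nz <- fit_normalizer(d)
  z <- apply_normalizer(nz, d)
  expect_true(all(abs(colMeans(z)) < 1e-6))
  expect_true(all(abs(vapply(z, sd, numeric(1)) - 1) < 1e-6))

  # a near-normal column keeps a power parameter near the identity (1)
  expect_lt(abs(nz$lambda[["b"]] - 1), 0.3)

  # frozen application: state identical before and after, never refit
  d2 <- tibble::tibble(a = rexp(100, 5), b = rnorm(100, -4, 1),
                       c = runif(100, 10, 20))
  before <- serialize(nz, NULL)
  z2 <- apply_normalizer(nz, d2)
  expect_identical(serialize(nz, NULL), before)
  # disjoint data is transformed with the training parameters, so it is
  # generally not standardized
  expect_gt(abs(mean(z2$b)), 1)
})

test_that("zero-variance columns pass through with unit scale and a warning", {
  d <- tibble::tibble(a = rnorm(50), flat = rep(2, 50))
  expect_warning(nz <- fit_normalizer(d), "zero-variance")
  expect_equal(unname(nz$scale["flat"]), 1)
  z <- apply_normalizer(nz, d)
  expect_true(all(z$flat == 0)) # centred constant
})

test_that("normalizer transform agrees with an independent Yeo-Johnson oracle", {
  # hand-written Yeo-Johnson at the fitted lambda, applied to fresh data
  yj <- function(x, l) {
    ifelse(x >= 0,
           if (abs(l) < 1e-12) log1p(x) else ((1 + x)^l - 1) / l,
           if (abs(l - 2) < 1e-12) -log1p(-x) else
             -((1 - x)^(2 - l) - 1) / (2 - l))
  }
  set.seed(21)
  train <- tibble::tibble(a = rexp(500, 0.5))
  test <- tibble::tibble(a = rexp(40, 0.5))
  nz <- fit_normalizer(train)
  lam <- nz$lambda[["a"]]
  manual <- yj(test$a, lam)
  ref <- yj(train$a, lam)
  expect_equal(apply_normalizer(nz, test)$a,
               (manual - mean(ref)) / sd(ref), tolerance = 1e-8)
})
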