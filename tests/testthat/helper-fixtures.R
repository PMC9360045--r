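# Shared fixtures and independent oracles. Simulations are cached per test
# session; everything is generated in code under fixed seeds.

make_records <- function(n = 10, start = "2020-06-01", by = 900,
                         buoy = "beach", temperature = 15, conductivity = 60,
                         ph = 7.5, battery = 13, chlorophyll = 4) {
  tibble::tibble(
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * by,
    buoy_id = buoy,
    temperature = rep_len(temperature, n),
    conductivity = rep_len(conductivity, n),
    ph = rep_len(ph, n),
    battery = rep_len(battery, n),
    chlorophyll = rep_len(chlorophyll, n)
  )
}

# Brute-force trailing-window oracle: explicitly collects the in-window
# samples for every row and applies the plain R statistic. Independent of
# the package's two-pointer C++ path.
oracle_roll <- function(t, x, window, stat) {
  t <- as.numeric(t)
  fn <- switch(stat,
    mean = mean, median = median, min = min, max = max,
    std = function(v) if (length(v) > 1) sd(v) else 0
  )
  vapply(seq_along(t), function(i) {
    fn(x[t > t[i] - window & t <= t[i]])
  }, numeric(1))
}

# Brute-force confusion matrix by explicit pairwise comparison.
oracle_confusion <- function(truth, pred) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] && pred[i]) tp <- tp + 1L
    else if (!truth[i] && pred[i]) fp <- fp + 1L
    else if (truth[i] && !pred[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Three-year, two-buoy simulation at 4-hour cadence: small enough for model
# fits in tests, but multi-year, so every calendar month recurs in training
# whichever contiguous chunk is held out — the property the chunked K-fold
# design relies on. Spikes emulate fluorescence interference so output
# aggregation has something to filter.
spiky_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_buoys(
        synthetic_config(n_years = 3, cadence_min = 240, spike_rate = 0.01))
    }
    cache
  }
})

# Three calendar years at 6-hour cadence: cheap, but every month occurs in
# three different years, which the monthly pooling tests need.
three_year_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_buoys(synthetic_config(n_years = 3, cadence_min = 360))
    }
    cache
  }
})
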