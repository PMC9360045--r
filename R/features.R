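#' Trailing moving-window statistics of a time-indexed series
#'
#' For each observation at time `t`, computes descriptive statistics over
#' every sample in the trailing interval `(t - window, t]`. Windows are
#' duration-based, so gaps left by cleaning shrink the in-window sample
#' count instead of silently stretching the horizon, and the current sample
#' is always included — a window never sees the future. The standard
#' deviation is the sample (n-1) form, defined as 0 for a single-sample
#' window.
#'
#' @param data A data frame, time-sorted within the series.
#' @param value Column holding the numeric series (tidy-eval).
#' @param time Column holding the timestamps (tidy-eval, default
#'   `timestamp`).
#' @param window Window length: `"hour"`, `"day"`, or a duration in seconds.
#' @param stats Statistics to compute, a subset of
#'   `c("mean", "std", "median", "min", "max")`.
#' @param prefix Name prefix for the new columns
#'   (`<prefix>_<window>_<stat>`); defaults to the value column's name.
#'
#' @return `data` with one new column per requested statistic plus
#'   `<prefix>_<window>_n`, the in-window sample count (an audit column,
#'   not a model feature).
#' @examples
#' d <- tibble::tibble(
#'   timestamp = as.POSIXct("2020-07-01", tz = "UTC") + (0:3) * 900,
#'   ph = c(1, 2, 3, 4)
#' )
#' rolling_stats(d, ph, window = "hour")
#' @export
rolling_stats <- function(data, value, time = timestamp, window = "hour",
                          stats = c("mean", "std", "median", "min", "max"),
                          prefix = NULL) {
  col <- rlang::as_name(rlang::ensym(value))
  time_col <- rlang::as_name(rlang::ensym(time))
  .rolling_stats_chr(data, col, time_col, window, stats, prefix %||% col)
}

.rolling_stats_chr <- function(data, col, time_col = "timestamp",
                               window = "hour",
                               stats = c("mean", "std", "median", "min", "max"),
                               prefix = col) {
  bad <- setdiff(stats, .window_stats)
  if (length(bad)) {
    abort(paste0("unknown statistic(s): ", paste(bad, collapse = ", ")))
  }
  wname <- if (is.character(window)) window else paste0(window, "s")
  wsec <- if (is.character(window)) {
    if (!window %in% names(.window_secs)) {
      abort("`window` must be \"hour\", \"day\" or a number of seconds")
    }
    .window_secs[[window]]
  } else as.numeric(window)
  res <- .roll_stats_cpp(as.numeric(data[[time_col]]), data[[col]], wsec)
  for (s in stats) {
    data[[paste(prefix, wname, s, sep = "_")]] <- res[[s]]
  }
  data[[paste(prefix, wname, "n", sep = "_")]] <- res$n_in_window
  data
}

.variant_columns <- function(variant) {
  base <- unname(.display_names[.input_vars])
  windows <- switch(variant,
    input_orig = character(0),
    input_hour = "hour",
    input_day = "day",
    input_mix = c("hour", "day"),
    abort(paste0("unknown input variant: ", variant))
  )
  agg <- unlist(lapply(windows, function(w) {
    unlist(lapply(base, function(v) paste(v, w, .window_stats, sep = "_")))
  }))
  c(base, agg)
}

#' The four input feature variants
#'
#' Builds the feature matrix for one of the four input configurations:
#' `input_orig` (the 4 raw variables), `input_hour` / `input_day` (those 4
#' plus 5 trailing-window statistics per variable over 1 hour / 24 hours,
#' 24 columns) and `input_mix` (both windows, 44 columns). Aggregations are
#' computed per buoy so one buoy's history never leaks into another's
#' features. Feature columns use display names (`Temperature`,
#' `Conductivity`, `pH`, `SystemBattery`) with `_hour_`/`_day_` statistic
#' suffixes, e.g. `pH_day_max`.
#'
#' @param records A cleaned sensor records tibble.
#' @param variant One of `"input_orig"`, `"input_hour"`, `"input_day"`,
#'   `"input_mix"`.
#'
#' @return A tibble with `timestamp`, `buoy_id`, and the variant's feature
#'   columns in canonical order; the variant name is attached as attribute
#'   `"variant"`.
#' @export
build_input_variant <- function(records, variant = c("input_orig", "input_hour",
                                                     "input_day", "input_mix")) {
  variant <- rlang::arg_match(variant)
  cols <- .variant_columns(variant)
  windows <- intersect(c("hour", "day"),
                       unique(sub("^.*?_(hour|day)_.*$", "\\1",
                                  grep("_(hour|day)_", cols, value = TRUE))))
  out <- records |>
    dplyr::select(dplyr::all_of(c("timestamp", "buoy_id", .input_vars))) |>
    dplyr::rename(!!!setNames(.input_vars, .display_names[.input_vars])) |>
    dplyr::group_by(.data$buoy_id) |>
    dplyr::group_modify(function(d, key) {
      for (w in windows) {
        for (v in .display_names[.input_vars]) {
          d <- .rolling_stats_chr(d, v, window = w)
        }
      }
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("timestamp", "buoy_id", cols)))
  attr(out, "variant") <- variant
  out
}

#' The five output (target) variants
#'
#' Derives the regression target from chlorophyll-a: the instantaneous value
#' (`output_orig`) or its trailing-window mean/median over 1 hour or 24
#' hours. Aggregated targets filter ephemeral fluorescence spikes out of the
#' quantity the soft-sensor is asked to reproduce. Windows are trailing
#' (causal), matching the input aggregations, so the target at time `t`
#' never depends on samples after `t`.
#'
#' @param records A cleaned sensor records tibble with `chlorophyll`.
#' @param variant One of `"output_orig"`, `"output_hour_mean"`,
#'   `"output_hour_median"`, `"output_day_mean"`, `"output_day_median"`.
#'
#' @return A tibble `timestamp`, `buoy_id`, `target` (ug/L), with the
#'   variant name attached as attribute `"variant"`.
#' @export
build_output_variant <- function(records,
                                 variant = c("output_orig", "output_hour_mean",
                                             "output_hour_median",
                                             "output_day_mean",
                                             "output_day_median")) {
  variant <- rlang::arg_match(variant)
  if (!"chlorophyll" %in% names(records)) {
    abort("`records` has no chlorophyll column")
  }
  out <- records |>
    dplyr::select(dplyr::all_of(c("timestamp", "buoy_id", "chlorophyll")))
  if (variant == "output_orig") {
    out <- dplyr::rename(out, target = "chlorophyll")
  } else {
    parts <- strsplit(variant, "_")[[1]] # c("output", window, stat)
    out <- out |>
      dplyr::group_by(.data$buoy_id) |>
      dplyr::group_modify(function(d, key) {
        .rolling_stats_chr(d, "chlorophyll", window = parts[2],
                           stats = parts[3], prefix = "chl")
      }) |>
      dplyr::ungroup() |>
      dplyr::transmute(.data$timestamp, .data$buoy_id,
                       target = .data[[paste("chl", parts[2], parts[3],
                                             sep = "_")]])
  }
  attr(out, "variant") <- variant
  out
}

#' Assemble a modelling dataset from one input and one output variant
#'
#' Convenience wrapper joining [build_input_variant()] and
#' [build_output_variant()] on `(buoy_id, timestamp)`, time-sorted with the
#' buoys pooled — the layout expected by [make_chunks()] and [run_search()].
#'
#' @inheritParams build_input_variant
#' @param input_variant,output_variant Variant names.
#' @return A tibble `timestamp`, `buoy_id`, feature columns, `target`, with
#'   attributes `"variant"` (input) and `"output_variant"`.
#' @export
build_dataset <- function(records, input_variant = "input_orig",
                          output_variant = "output_orig") {
  x <- build_input_variant(records, input_variant)
  y <- build_output_variant(records, output_variant)
  out <- dplyr::inner_join(x, y, by = c("timestamp", "buoy_id")) |>
    dplyr::arrange(.data$timestamp, .data$buoy_id)
  attr(out, "variant") <- input_variant
  attr(out, "output_variant") <- output_variant
  out
}

#' Enumerate the input x output experiment grid
#'
#' All 4 input variants crossed with all 5 output variants: the 20 dataset
#' variations over which model families are tuned and compared.
#'
#' @return A 20-row tibble with columns `input_variant`, `output_variant`
#'   and `n_features`, in a fixed deterministic order.
#' @export
experiment_grid <- function() {
  inputs <- c("input_orig", "input_hour", "input_day", "input_mix")
  outputs <- c("output_orig", "output_hour_mean", "output_hour_median",
               "output_day_mean", "output_day_median")
  tidyr::expand_grid(input_variant = inputs, output_variant = outputs) |>
    dplyr::mutate(n_features = purrr::map_int(.data$input_variant,
                                              ~ length(.variant_columns(.x))))
}

#' Feature columns of a modelling dataset
#'
#' @param data A dataset built by [build_input_variant()] or
#'   [build_dataset()].
#' @return Character vector of feature column names (identifier, audit and
#'   target columns excluded).
#' @export
feature_names <- function(data) {
  setdiff(names(data), c("timestamp", "buoy_id", "target"))
}
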