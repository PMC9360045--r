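#' Physical validity ranges for buoy sensor variables
#'
#' One row per variable with its `[min, max]` physical limits and the
#' tolerance band used by [clean_records()]: a value up to
#' `tolerance * (max - min)` outside a limit is snapped to that limit; any
#' value further out (or missing) invalidates its whole row. The shipped
#' defaults are plausible freshwater sensor limits and are configuration,
#' not normative constants; adjust them to the deployment.
#'
#' @param temperature,conductivity,ph,battery,chlorophyll Length-2 numeric
#'   `(min, max)` limits, in deg C, uS/cm, pH units, V and ug/L respectively.
#' @param tolerance Snap-band width as a fraction of each variable's span;
#'   must lie in `[0, 1)`.
#'
#' @return A tibble with columns `variable`, `min`, `max`, `tolerance`.
#' @examples
#' valid_ranges(chlorophyll = c(0, 300))
#' @export
valid_ranges <- function(temperature = c(-5, 50),
                         conductivity = c(0, 2000),
                         ph = c(0, 14),
                         battery = c(0, 20),
                         chlorophyll = c(0, 500),
                         tolerance = 0.05) {
  lims <- list(temperature = temperature, conductivity = conductivity,
               ph = ph, battery = battery, chlorophyll = chlorophyll)
  for (v in names(lims)) {
    if (length(lims[[v]]) != 2 || lims[[v]][1] >= lims[[v]][2]) {
      abort(paste0("`", v, "` must be c(min, max) with min < max"))
    }
  }
  if (tolerance < 0 || tolerance >= 1) abort("`tolerance` must be in [0, 1)")
  tibble::tibble(
    variable = names(lims),
    min = purrr::map_dbl(lims, 1),
    max = purrr::map_dbl(lims, 2),
    tolerance = tolerance
  )
}

#' Read a raw buoy sensor table from CSV
#'
#' Reads a CSV export, optionally renaming columns to the canonical schema,
#' validates timestamps, and returns the table sorted by buoy and time.
#' Duplicate `(buoy_id, timestamp)` pairs are rejected: they indicate a
#' corrupted export.
#'
#' @param path Path to a CSV file with a header row and ISO-8601 timestamps.
#' @param schema Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(ph = "PH", battery = "batt_v")`.
#'   Unmapped canonical names are looked up directly.
#'
#' @return A tibble with columns `timestamp` (POSIXct, UTC), `buoy_id` and
#'   the five numeric sensor variables (chlorophyll may be absent).
#' @export
read_buoy_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  canonical <- c("timestamp", "buoy_id", .sensor_vars)
  lookup <- setNames(canonical, canonical)
  if (!is.null(schema)) lookup[names(schema)] <- unname(schema)
  required <- setdiff(canonical, "chlorophyll")
  missing <- required[!lookup[required] %in% names(raw)]
  if (length(missing)) {
    abort(paste0("missing required column(s): ",
                 paste0(missing, " (looked for '", lookup[missing], "')",
                        collapse = ", ")))
  }
  present <- canonical[lookup[canonical] %in% names(raw)]
  tab <- raw[, lookup[present]]
  names(tab) <- present

  if (!inherits(tab$timestamp, "POSIXct")) {
    parsed <- suppressWarnings(
      lubridate::as_datetime(as.character(tab$timestamp), tz = "UTC"))
    bad <- which(is.na(parsed) & !is.na(tab$timestamp))
    if (length(bad)) {
      abort(paste0("unparseable timestamp at row(s): ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    tab$timestamp <- parsed
  }
  tab <- dplyr::arrange(tab, .data$buoy_id, .data$timestamp)
  dup <- duplicated(tab[, c("buoy_id", "timestamp")])
  if (any(dup)) {
    first <- tab[which(dup)[1], ]
    abort(paste0("duplicate (buoy_id, timestamp): ", first$buoy_id, " @ ",
                 format(first$timestamp)))
  }
  tab
}

#' Clean buoy records by boundary snapping and row removal
#'
#' Applies the two-step range rule: a value outside its `[min, max]` limits
#' by at most `tolerance` (default 5%) of the span `max - min` is replaced
#' by its nearest boundary (a calibration-offset correction); a row in which
#' any variable lies beyond that band, or is missing, is removed whole (a
#' sensor fault). Row order and timestamps of kept rows are preserved, and
#' the operation is idempotent.
#'
#' @param records A sensor records tibble (see [read_buoy_table()]).
#' @param ranges A [valid_ranges()] table covering every numeric variable
#'   present.
#'
#' @return A list with elements `records` (the cleaned tibble) and `report`
#'   (class `"clean_report"`): `rows_in`, `rows_kept`, `rows_removed`,
#'   `removal_fraction`, and `snapped`, a named per-variable count of values
#'   snapped in kept rows.
#' @examples
#' tab <- tibble::tibble(
#'   timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (0:2) * 900,
#'   buoy_id = "beach", temperature = c(12, 13, 12.5),
#'   conductivity = 60, ph = c(7.2, 14.5, 15), battery = 13,
#'   chlorophyll = 4
#' )
#' clean_records(tab)$report
#' @export
clean_records <- function(records, ranges = valid_ranges()) {
  vars <- intersect(.sensor_vars, names(records))
  missing_ranges <- setdiff(vars, ranges$variable)
  if (length(missing_ranges)) {
    abort(paste0("no valid range configured for: ",
                 paste(missing_ranges, collapse = ", ")))
  }
  n_in <- nrow(records)
  snapped <- setNames(rep(0L, length(vars)), vars)
  if (n_in == 0) {
    report <- structure(list(rows_in = 0L, rows_kept = 0L, rows_removed = 0L,
                             removal_fraction = 0, snapped = snapped,
                             all_removed = FALSE),
                        class = "clean_report")
    return(list(records = records, report = report))
  }

  keep <- rep(TRUE, n_in)
  snap_flags <- matrix(FALSE, n_in, length(vars),
                       dimnames = list(NULL, vars))
  for (v in vars) {
    lim <- ranges[ranges$variable == v, ]
    band <- lim$tolerance * (lim$max - lim$min)
    x <- records[[v]]
    snap_lo <- !is.na(x) & x < lim$min & x >= lim$min - band
    snap_hi <- !is.na(x) & x > lim$max & x <= lim$max + band
    out <- is.na(x) | x < lim$min - band | x > lim$max + band
    x[snap_lo] <- lim$min
    x[snap_hi] <- lim$max
    records[[v]] <- x
    snap_flags[, v] <- snap_lo | snap_hi
    keep <- keep & !out
  }
  for (v in vars) snapped[v] <- sum(snap_flags[keep, v])

  out_tab <- records[keep, , drop = FALSE]
  report <- structure(list(
    rows_in = n_in,
    rows_kept = sum(keep),
    rows_removed = n_in - sum(keep),
    removal_fraction = (n_in - sum(keep)) / n_in,
    snapped = snapped,
    all_removed = !any(keep)
  ), class = "clean_report")
  if (report$all_removed) warn("cleaning removed every row")
  list(records = out_tab, report = report)
}

#' @export
print.clean_report <- function(x, ...) {
  cat("<clean_report>\n")
  cat(sprintf("  rows: %d in, %d kept, %d removed (%.2f%%)\n",
              x$rows_in, x$rows_kept, x$rows_removed,
              100 * x$removal_fraction))
  snaps <- x$snapped[x$snapped > 0]
  if (length(snaps)) {
    cat("  snapped:", paste0(names(snaps), "=", snaps, collapse = ", "), "\n")
  } else {
    cat("  snapped: none\n")
  }
  invisible(x)
}

#' @export
tidy.clean_report <- function(x, ...) {
  tibble::tibble(variable = names(x$snapped),
                 values_snapped = unname(as.integer(x$snapped)))
}

#' @export
glance.clean_report <- function(x, ...) {
  tibble::tibble(rows_in = x$rows_in, rows_kept = x$rows_kept,
                 rows_removed = x$rows_removed,
                 removal_fraction = x$removal_fraction)
}

#' Descriptive statistics of a sensor table
#'
#' Per-variable count, mean, sample standard deviation, extrema and
#' quartiles — the standard summary table reported for multi-year buoy
#' deployments.
#'
#' @param records A (cleaned) sensor records tibble.
#'
#' @return A tibble with one row per variable and columns `variable`,
#'   `count`, `mean`, `std`, `min`, `p25`, `p50`, `p75`, `max`.
#' @export
summarize_records <- function(records) {
  vars <- intersect(.sensor_vars, names(records))
  if (nrow(records) == 0) abort("cannot summarize an empty table")
  purrr::map(vars, function(v) {
    x <- records[[v]]
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    tibble::tibble(
      variable = v, count = sum(!is.na(x)), mean = mean(x, na.rm = TRUE),
      std = sd(x, na.rm = TRUE), min = min(x, na.rm = TRUE),
      p25 = q[1], p50 = q[2], p75 = q[3], max = max(x, na.rm = TRUE)
    )
  }) |> purrr::list_rbind()
}
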