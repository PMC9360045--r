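#' Configuration for the synthetic two-buoy generator
#'
#' Builds the parameter set for [simulate_buoys()]. The generator emulates a
#' eutrophic reservoir monitored by two solar-powered buoys ("beach": shallow,
#' noisier sensors; "dam": deeper, with a stronger diel chlorophyll migration)
#' logging temperature, conductivity, pH, system battery and chlorophyll-a
#' every 15 minutes. The structural couplings are the ones a chlorophyll
#' soft-sensor relies on: photosynthetic activity raises pH with algal
#' biomass, rainfall dilutes conductivity while drought concentrates it, the
#' battery traces daylight (and hence season), and blooms are ephemeral
#' pulses riding a late-summer seasonal envelope that peaks in September.
#'
#' @param start First timestamp (UTC date or datetime).
#' @param n_years Number of years to simulate.
#' @param cadence_min Sampling cadence in minutes; must divide one day.
#' @param buoys Character vector of buoy profile names to include
#'   (subset of `"beach"`, `"dam"`).
#' @param chl_base Baseline chlorophyll-a level, ug/L.
#' @param chl_peak Amplitude of the seasonal bloom envelope at its peak, ug/L.
#' @param peak_doy Day-of-year of the envelope peak (default Sep 5).
#' @param envelope_width_days Gaussian width of the seasonal envelope, days.
#' @param pulse_rate Expected bloom pulses per simulated year.
#' @param pulse_meanlog,pulse_sdlog Log-normal parameters of pulse amplitude
#'   (ug/L).
#' @param pulse_duration_days Mean pulse duration (days).
#' @param chl_diel_amp Named numeric, per-buoy relative diel amplitude of the
#'   latent chlorophyll (vertical migration; larger at the dam).
#' @param ph_base Baseline pH.
#' @param ph_coupling Coefficient linking pH to `log1p(latent chlorophyll)`;
#'   a saturating link keeps pH physically plausible.
#' @param ph_diel_amp Diel pH amplitude (photosynthesis cycle).
#' @param temp_mean,temp_seasonal_amp,temp_diel_amp Water temperature model
#'   (deg C): annual mean, seasonal amplitude, diel amplitude.
#' @param cond_base Conductivity baseline, uS/cm.
#' @param cond_drought_amp Seasonal (drought) conductivity amplitude, uS/cm.
#' @param rain_rate Expected rain events per day; each event dilutes
#'   conductivity with an exponentially decaying drop.
#' @param rain_drop_mean Mean conductivity drop per rain event, uS/cm.
#' @param rain_tau_days Recovery time constant after rain, days.
#' @param batt_min,batt_max Battery voltage floor and full-charge level, V.
#' @param charge_hours Hours of daylight needed for a full recharge.
#' @param discharge_hours Hours of darkness that fully discharge the usable
#'   band (long winter nights reach the floor, short summer nights do not).
#' @param noise_sd Named list of per-variable Gaussian noise standard
#'   deviations; each element may be a single value or a named per-buoy
#'   vector.
#' @param spike_rate Per-sample probability of an ephemeral in-range
#'   chlorophyll spike (fluorescence sensor interference).
#' @param spike_range Range (ug/L) of injected spike magnitudes.
#' @param outlier_rate,missing_rate Default artifact rates consumed by
#'   [inject_artifacts()].
#' @param seed Master seed for [simulate_buoys()].
#'
#' @return A list of class `"synthetic_config"`.
#' @seealso [simulate_buoys()], [inject_artifacts()]
#' @export
synthetic_config <- function(start = "2018-01-01",
                             n_years = 3,
                             cadence_min = 15,
                             buoys = c("beach", "dam"),
                             chl_base = 2,
                             chl_peak = 14,
                             peak_doy = 248,
                             envelope_width_days = 45,
                             pulse_rate = 8,
                             pulse_meanlog = 2.6,
                             pulse_sdlog = 0.6,
                             pulse_duration_days = 3,
                             chl_diel_amp = c(beach = 0.08, dam = 0.35),
                             ph_base = 6.9,
                             ph_coupling = 0.35,
                             ph_diel_amp = 0.15,
                             temp_mean = 15,
                             temp_seasonal_amp = 9,
                             temp_diel_amp = 1.2,
                             cond_base = 65,
                             cond_drought_amp = 8,
                             rain_rate = 0.04,
                             rain_drop_mean = 12,
                             rain_tau_days = 5,
                             batt_min = 12.8,
                             batt_max = 14.6,
                             charge_hours = 3,
                             discharge_hours = 14,
                             noise_sd = list(
                               temperature = 0.25,
                               conductivity = c(beach = 2.0, dam = 1.2),
                               ph = 0.08,
                               battery = 0.05,
                               chlorophyll = c(beach = 1.0, dam = 0.6)
                             ),
                             spike_rate = 0,
                             spike_range = c(20, 120),
                             outlier_rate = 0.04,
                             missing_rate = 0.03,
                             seed = 42) {
  stopifnot(n_years > 0, cadence_min > 0, (24 * 60) %% cadence_min == 0)
  if (!all(buoys %in% c("beach", "dam"))) {
    abort("`buoys` must be a subset of c(\"beach\", \"dam\")")
  }
  rates <- c(pulse_rate = pulse_rate, rain_rate = rain_rate,
             spike_rate = spike_rate, outlier_rate = outlier_rate,
             missing_rate = missing_rate)
  if (any(rates < 0) || spike_rate > 1 || outlier_rate > 1 || missing_rate > 1) {
    abort("rates must be non-negative (and probabilities at most 1)")
  }
  amps <- c(chl_peak, envelope_width_days, ph_diel_amp, temp_seasonal_amp,
            temp_diel_amp, cond_drought_amp, chl_diel_amp)
  if (any(amps < 0)) abort("amplitudes must be non-negative")
  cfg <- as.list(environment())
  cfg$start <- lubridate::as_datetime(start, tz = "UTC")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  span    :", format(x$start), "+", x$n_years, "year(s) @",
      x$cadence_min, "min\n")
  cat("  buoys   :", paste(x$buoys, collapse = ", "), "\n")
  cat("  bloom   : peak", x$chl_peak, "ug/L around day-of-year", x$peak_doy, "\n")
  cat("  pH link :", x$ph_coupling, "per log1p(Chl-a)\n")
  cat("  seed    :", x$seed, "\n")
  invisible(x)
}

# Daylight geometry shared by battery and (indirectly) the bloom season:
# day length oscillates around 12 h, peaking at the June solstice.
.day_length <- function(doy) 12 + 3 * cos(2 * pi * (doy - 172) / 365.25)

.battery_charge <- function(doy, hour, charge_hours, discharge_hours) {
  len <- .day_length(doy)
  sunrise <- 12 - len / 2
  sunset <- 12 + len / 2
  f <- numeric(length(hour))
  day <- hour >= sunrise & hour <= sunset
  f[day] <- pmin(1, (hour[day] - sunrise[day]) / charge_hours)
  hs <- (hour[!day] - sunset[!day]) %% 24 # hours since sunset
  f[!day] <- pmax(0, 1 - hs / discharge_hours)
  f
}

# Latent (noiseless) chlorophyll for one buoy: seasonal envelope + log-normal
# bloom pulses centred on late summer, modulated by a diel migration term.
.latent_chl <- function(cfg, tnum, doy, hour, diel_amp) {
  days <- tnum / 86400
  env <- cfg$chl_base +
    cfg$chl_peak * exp(-0.5 * (((doy - cfg$peak_doy + 182.5) %% 365 - 182.5) /
                                 cfg$envelope_width_days)^2)
  n_pulse <- rpois(1, cfg$pulse_rate * cfg$n_years)
  pulses <- 0
  if (n_pulse > 0) {
    yr <- sample.int(cfg$n_years, n_pulse, replace = TRUE) - 1
    centre_doy <- pmin(304, pmax(152, rnorm(n_pulse, cfg$peak_doy, 30)))
    centre <- yr * 365.25 + centre_doy
    amp <- rlnorm(n_pulse, cfg$pulse_meanlog, cfg$pulse_sdlog)
    dur <- rlnorm(n_pulse, log(cfg$pulse_duration_days), 0.4)
    pulses <- rowSums(vapply(seq_len(n_pulse), function(i) {
      amp[i] * exp(-0.5 * ((days - centre[i]) / dur[i])^2)
    }, numeric(length(days))))
  }
  diel <- 1 + diel_amp * sin(2 * pi * (hour - 10) / 24)
  pmax(0, (env + pulses) * diel)
}

.noise_for <- function(noise_sd, var, buoy) {
  v <- noise_sd[[var]]
  if (length(v) > 1) v <- v[[buoy]]
  as.numeric(v)
}

#' Simulate multi-year buoy sensor records
#'
#' Generates a time-stamped sensor table for each configured buoy, together
#' with the ground truth needed for parameter-recovery tests: the latent
#' (noiseless) chlorophyll series, the injected spike positions, and the
#' coupling coefficients actually used. The output table has the same schema
#' as a real buoy export and is bit-identical for identical configurations
#' and seeds.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to the seed stored in `config`.
#'
#' @return A list of class `"buoy_sim"` with elements
#' \describe{
#'   \item{records}{tibble: `timestamp`, `buoy_id`, `temperature`,
#'     `conductivity`, `ph`, `battery`, `chlorophyll`.}
#'   \item{truth}{list with `latent` (tibble of noiseless chlorophyll per
#'     row), `spikes` (tibble of injected spike positions), `coupling`
#'     (coefficients used) and `artifacts` (filled by
#'     [inject_artifacts()], initially empty).}
#' }
#' @examples
#' sim <- simulate_buoys(synthetic_config(n_years = 1, cadence_min = 60,
#'                                        buoys = "beach"))
#' dplyr::glimpse(sim$records)
#' @export
simulate_buoys <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  cadence <- config$cadence_min * 60
  t_end <- config$start + lubridate::years(config$n_years)
  ts <- seq(config$start, t_end - 1, by = cadence)
  tnum <- as.numeric(ts) - as.numeric(config$start)
  doy <- lubridate::yday(ts)
  hour <- lubridate::hour(ts) + lubridate::minute(ts) / 60
  n <- length(ts)

  withr::with_seed(seed, {
    per_buoy <- purrr::map(config$buoys, function(buoy) {
      diel_amp <- config$chl_diel_amp[[buoy]]
      latent <- .latent_chl(config, tnum, doy, hour, diel_amp)

      temperature <- config$temp_mean +
        config$temp_seasonal_amp * cos(2 * pi * (doy - 208) / 365.25) +
        config$temp_diel_amp * sin(2 * pi * (hour - 15) / 24) +
        rnorm(n, 0, .noise_for(config$noise_sd, "temperature", buoy))

      ph <- config$ph_base +
        config$ph_coupling * log1p(latent) +
        config$ph_diel_amp * sin(2 * pi * (hour - 15) / 24) +
        rnorm(n, 0, .noise_for(config$noise_sd, "ph", buoy))
      ph <- pmin(14, pmax(0, ph))

      n_rain <- rpois(1, config$rain_rate * 365.25 * config$n_years)
      rain <- 0
      if (n_rain > 0) {
        at <- sort(runif(n_rain, 0, max(tnum)))
        drop <- rexp(n_rain, 1 / config$rain_drop_mean)
        tau <- config$rain_tau_days * 86400
        rain <- rowSums(vapply(seq_len(n_rain), function(i) {
          ifelse(tnum >= at[i], drop[i] * exp(-(tnum - at[i]) / tau), 0)
        }, numeric(n)))
      }
      conductivity <- config$cond_base +
        config$cond_drought_amp * cos(2 * pi * (doy - 235) / 365.25) -
        rain +
        rnorm(n, 0, .noise_for(config$noise_sd, "conductivity", buoy))
      conductivity <- pmax(1, conductivity)

      charge <- .battery_charge(doy, hour, config$charge_hours,
                                config$discharge_hours)
      battery <- config$batt_min + (config$batt_max - config$batt_min) * charge +
        rnorm(n, 0, .noise_for(config$noise_sd, "battery", buoy))

      chlorophyll <- pmax(0, latent +
        rnorm(n, 0, .noise_for(config$noise_sd, "chlorophyll", buoy)))
      spike_idx <- integer(0)
      if (config$spike_rate > 0) {
        spike_idx <- which(runif(n) < config$spike_rate)
        if (length(spike_idx)) {
          chlorophyll[spike_idx] <- chlorophyll[spike_idx] +
            runif(length(spike_idx), config$spike_range[1], config$spike_range[2])
        }
      }

      list(
        records = tibble::tibble(
          timestamp = ts, buoy_id = buoy,
          temperature = temperature, conductivity = conductivity,
          ph = ph, battery = battery, chlorophyll = chlorophyll
        ),
        latent = tibble::tibble(timestamp = ts, buoy_id = buoy,
                                chl_latent = latent),
        spikes = tibble::tibble(timestamp = ts[spike_idx], buoy_id = buoy)
      )
    })
  })

  records <- dplyr::arrange(purrr::list_rbind(purrr::map(per_buoy, "records")),
                            .data$buoy_id, .data$timestamp)
  structure(list(
    records = records,
    truth = list(
      latent = purrr::list_rbind(purrr::map(per_buoy, "latent")),
      spikes = purrr::list_rbind(purrr::map(per_buoy, "spikes")),
      coupling = list(ph_coupling = config$ph_coupling,
                      chl_diel_amp = config$chl_diel_amp[config$buoys]),
      artifacts = tibble::tibble(
        timestamp = records$timestamp[0], buoy_id = character(0),
        variable = character(0), kind = character(0),
        original = numeric(0), injected = numeric(0)
      )
    ),
    config = config
  ), class = "buoy_sim")
}

#' @export
print.buoy_sim <- function(x, ...) {
  cat("<buoy_sim> ", nrow(x$records), " records, buoys: ",
      paste(unique(x$records$buoy_id), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Inject sensor artifacts into simulated records
#'
#' Plants the three kinds of defect the cleaning stage must handle: values
#' pushed just *inside* the 5% snap band (a calibration-style offset that
#' should be snapped to the boundary), values pushed *beyond* the band (a
#' sensor fault whose whole row should be removed), and missing values.
#' At most one artifact is planted per row, so planted counts map one-to-one
#' onto the cleaning report's tallies.
#'
#' @param sim A `"buoy_sim"` object from [simulate_buoys()], or a plain
#'   records tibble.
#' @param outlier_rate Fraction of rows receiving an out-of-range value;
#'   split between the snap band and beyond it by `snap_fraction`.
#' @param missing_rate Fraction of rows receiving a missing value.
#' @param seed Integer seed.
#' @param ranges A [valid_ranges()] table defining the bands.
#' @param snap_fraction Share of outliers placed inside the snap band.
#'
#' @return The input with corrupted `records` and the artifact positions
#'   appended to `truth$artifacts` (columns `timestamp`, `buoy_id`,
#'   `variable`, `kind` in `snap`/`remove`/`missing`, `original`,
#'   `injected`). A plain tibble input returns a list with elements
#'   `records` and `artifacts`.
#' @export
inject_artifacts <- function(sim, outlier_rate = NULL, missing_rate = NULL,
                             seed = 1, ranges = valid_ranges(),
                             snap_fraction = 0.5) {
  is_sim <- inherits(sim, "buoy_sim")
  records <- if (is_sim) sim$records else sim
  outlier_rate <- outlier_rate %||%
    (if (is_sim) sim$config$outlier_rate else 0.01)
  missing_rate <- missing_rate %||%
    (if (is_sim) sim$config$missing_rate else 0.01)
  stopifnot(outlier_rate >= 0, outlier_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            snap_fraction >= 0, snap_fraction <= 1)

  n <- nrow(records)
  n_out <- round(n * outlier_rate)
  n_snap <- round(n_out * snap_fraction)
  n_miss <- round(n * missing_rate)
  arts <- tibble::tibble(
    timestamp = records$timestamp[0], buoy_id = character(0),
    variable = character(0), kind = character(0),
    original = numeric(0), injected = numeric(0)
  )

  if (n_out + n_miss > 0 && n > 0) {
    withr::with_seed(seed, {
      rows <- sample.int(n, min(n, n_out + n_miss))
      vars <- sample(.sensor_vars, length(rows), replace = TRUE)
      kind <- rep(c("snap", "remove", "missing"),
                  c(n_snap, n_out - n_snap, n_miss))[seq_along(rows)]
      side <- sample(c("low", "high"), length(rows), replace = TRUE)
      u <- runif(length(rows))
      arts <- purrr::pmap(
        list(rows, vars, kind, side, u),
        function(r, v, k, s, ui) {
          lim <- ranges[ranges$variable == v, ]
          span <- lim$max - lim$min
          orig <- records[[v]][r]
          inj <- switch(k,
            missing = NA_real_,
            # strictly outside [lo, hi] but within 5% of the span
            snap = if (s == "high") lim$max + span * (0.001 + 0.048 * ui)
                   else lim$min - span * (0.001 + 0.048 * ui),
            # strictly beyond the 5% band
            remove = if (s == "high") lim$max + span * (0.051 + 0.5 * ui)
                     else lim$min - span * (0.051 + 0.5 * ui)
          )
          records[[v]][r] <<- inj
          tibble::tibble(timestamp = records$timestamp[r],
                         buoy_id = records$buoy_id[r], variable = v,
                         kind = k, original = orig, injected = inj)
        }
      ) |> purrr::list_rbind()
    })
  }

  if (is_sim) {
    sim$records <- records
    sim$truth$artifacts <- dplyr::bind_rows(sim$truth$artifacts, arts)
    sim
  } else {
    list(records = records, artifacts = arts)
  }
}
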