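#' Plot raw or cleaned sensor records
#'
#' Faceted time-series view of the sensor channels, one panel per variable
#' per buoy — the first look one takes at a deployment (or a synthetic
#' stand-in) before modelling.
#'
#' @param records A sensor records tibble.
#' @param vars Variables to show (default: all present).
#' @return A ggplot object.
#' @export
plot_records <- function(records, vars = NULL) {
  vars <- vars %||% intersect(.sensor_vars, names(records))
  long <- tidyr::pivot_longer(records[, c("timestamp", "buoy_id", vars)],
                              dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$timestamp, .data$value,
                                     colour = .data$buoy_id)) +
    ggplot2::geom_line(linewidth = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL, colour = "buoy") +
    ggplot2::theme_minimal()
}

#' @describeIn assemble_oof Observed vs predicted chlorophyll-a over time,
#'   one panel per buoy, with the alarm threshold drawn as a horizontal
#'   line.
#' @param object An `"oof_predictions"` tibble.
#' @param threshold Alarm threshold to draw, ug/L.
#' @param ... Unused.
#' @export
autoplot.oof_predictions <- function(object, threshold = 10, ...) {
  long <- tidyr::pivot_longer(object, c("y_true", "y_pred"),
                              names_to = "series", values_to = "chl")
  ggplot2::ggplot(long, ggplot2::aes(.data$timestamp, .data$chl,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.25, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, colour = "darkgreen",
                        linetype = 2) +
    ggplot2::facet_wrap(~buoy_id, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(
      values = c(y_true = "grey35", y_pred = "#d95f02"),
      labels = c(y_true = "sensor", y_pred = "soft-sensor")) +
    ggplot2::labs(x = NULL, y = "Chl-a (ug/L)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn feature_importance Paired bar chart of importance shares and
#'   linear correlations for the top features.
#' @param object An `"importance_table"`.
#' @param top_n Number of features to display.
#' @param ... Unused.
#' @export
autoplot.importance_table <- function(object, top_n = 15, ...) {
  d <- utils::head(object, top_n) |>
    tidyr::pivot_longer(c("importance", "correlation"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$value,
                                  stats::reorder(.data$feature, .data$value))) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_search Mean validation MAE of every sampled
#'   configuration, best first.
#' @param object A `"soft_sensor_search"`.
#' @param ... Unused.
#' @export
autoplot.soft_sensor_search <- function(object, ...) {
  d <- dplyr::filter(object$leaderboard, !.data$failed)
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, .data$mean_mae)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "configuration rank",
                  y = "mean validation MAE (ug/L)",
                  title = paste("random search,", object$family)) +
    ggplot2::theme_minimal()
}

#' Plot per-month MAE and F1 for one or more models
#'
#' @param breakdown Output of [monthly_breakdown()], optionally row-bound
#'   across models with a `family` column.
#' @return A ggplot object with MAE and F1 panels per buoy.
#' @export
plot_monthly_metrics <- function(breakdown) {
  d <- breakdown |>
    dplyr::filter(!is.na(.data$month)) |>
    tidyr::pivot_longer(c("mae", "f1"), names_to = "metric",
                        values_to = "value")
  mapping <- if ("family" %in% names(d)) {
    ggplot2::aes(factor(.data$month), .data$value, fill = .data$family)
  } else {
    ggplot2::aes(factor(.data$month), .data$value)
  }
  ggplot2::ggplot(d, mapping) +
    ggplot2::geom_col(position = "dodge", na.rm = TRUE) +
    ggplot2::facet_grid(metric ~ buoy_id, scales = "free_y") +
    ggplot2::labs(x = "calendar month", y = NULL) +
    ggplot2::theme_minimal()
}
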