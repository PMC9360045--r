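#' Level-1 alarm flags for chlorophyll-a
#'
#' Flags values exceeding the WHO level-1 management threshold of 10 ug/L
#' chlorophyll-a. The default comparison is strict (`> threshold`); set
#' `inclusive = TRUE` for the "equal or higher" reading. Vigilance
#' (1 ug/L) or level-2 (50 ug/L) thresholds can be passed for flag
#' generation, but play no role in model selection.
#'
#' @param x Numeric chlorophyll-a values, ug/L; must be finite.
#' @param threshold Alarm threshold, ug/L (default 10).
#' @param inclusive Flag values equal to the threshold too?
#' @return Logical vector.
#' @examples
#' alarm_flags(c(9.99, 10, 10.01))
#' @export
alarm_flags <- function(x, threshold = 10, inclusive = FALSE) {
  if (any(!is.finite(x))) abort("alarm flags require finite values")
  if (inclusive) x >= threshold else x > threshold
}

.safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)

.group_keys <- function(data, by) {
  by <- intersect(by, names(data))
  if (length(by) == 0) NULL else by
}

#' Regression metrics, overall or by group
#'
#' Mean absolute error, mean squared error, and MAE scaled by the sample
#' standard deviation of the observed values (MAE/STD, a unitless score
#' that is comparable across output aggregations with different spreads).
#' A group with constant observations has no defined MAE/STD and reports
#' `NA`.
#'
#' @param data Tibble holding observed and predicted columns.
#' @param truth,estimate Column names (strings) of observed and predicted
#'   values.
#' @param by Optional character vector of grouping columns.
#' @return A tibble with `n`, `mae`, `mse`, `mae_over_std` per group.
#' @examples
#' regression_metrics(tibble::tibble(y = c(1, 2), p = c(2, 4)), "y", "p")
#' @export
regression_metrics <- function(data, truth = "y_true", estimate = "y_pred",
                               by = NULL) {
  stopifnot(all(c(truth, estimate) %in% names(data)), nrow(data) >= 1)
  by <- .group_keys(data, by)
  grouped <- if (is.null(by)) data else dplyr::group_by(data, dplyr::pick(dplyr::all_of(by)))
  grouped |>
    dplyr::summarise(
      n = dplyr::n(),
      mae = mean(abs(.data[[truth]] - .data[[estimate]])),
      mse = mean((.data[[truth]] - .data[[estimate]])^2),
      mae_over_std = {
        s <- sd(.data[[truth]])
        if (is.na(s) || s == 0) NA_real_ else
          mean(abs(.data[[truth]] - .data[[estimate]])) / s
      },
      .groups = "drop"
    )
}

#' Alarm classification metrics, overall or by group
#'
#' Confusion-matrix counts and precision, recall and F1 for boolean alarm
#' flags: precision = TP / (TP + FP), recall = TP / (TP + FN), and F1 their
#' harmonic mean. A zero denominator leaves precision or recall `NA` and
#' F1 is reported as 0.
#'
#' @param data Tibble holding the flag columns.
#' @param truth,estimate Column names (strings) of observed and predicted
#'   logical flags.
#' @param by Optional character vector of grouping columns.
#' @return A tibble with `n`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1` per group.
#' @export
classification_metrics <- function(data, truth = "true_flag",
                                   estimate = "pred_flag", by = NULL) {
  stopifnot(all(c(truth, estimate) %in% names(data)))
  by <- .group_keys(data, by)
  grouped <- if (is.null(by)) data else dplyr::group_by(data, dplyr::pick(dplyr::all_of(by)))
  grouped |>
    dplyr::summarise(
      n = dplyr::n(),
      tp = sum(.data[[truth]] & .data[[estimate]]),
      fp = sum(!.data[[truth]] & .data[[estimate]]),
      fn = sum(.data[[truth]] & !.data[[estimate]]),
      tn = sum(!.data[[truth]] & !.data[[estimate]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      precision = .safe_div(.data$tp, .data$tp + .data$fp),
      recall = .safe_div(.data$tp, .data$tp + .data$fn),
      f1 = dplyr::if_else(
        is.na(.data$precision) | is.na(.data$recall) |
          (.data$precision + .data$recall) == 0,
        0,
        2 * .data$precision * .data$recall /
          (.data$precision + .data$recall)
      )
    )
}

#' Evaluate out-of-fold soft-sensor predictions
#'
#' Combines regression and alarm metrics for a set of out-of-fold
#' predictions, overall or per group. Alarm truth uses the same target
#' series the regressor was trained on (instantaneous or aggregated), so
#' each aggregation experiment is evaluated self-consistently.
#'
#' @param oof An `"oof_predictions"` tibble from [assemble_oof()] (or any
#'   tibble with `y_true`/`y_pred` and the grouping columns).
#' @param by Optional character vector of grouping columns, e.g.
#'   `"buoy_id"` or `c("buoy_id", "month")`.
#' @param threshold,inclusive Alarm definition, see [alarm_flags()].
#' @return A tibble with regression and alarm metric columns per group.
#' @export
evaluate_predictions <- function(oof, by = NULL, threshold = 10,
                                 inclusive = FALSE) {
  oof <- dplyr::mutate(
    as.data.frame(oof) |> tibble::as_tibble(),
    true_flag = alarm_flags(.data$y_true, threshold, inclusive),
    pred_flag = alarm_flags(.data$y_pred, threshold, inclusive)
  )
  reg <- regression_metrics(oof, "y_true", "y_pred", by = by)
  cls <- classification_metrics(oof, "true_flag", "pred_flag", by = by)
  by <- .group_keys(oof, by)
  if (is.null(by)) {
    dplyr::bind_cols(reg, dplyr::select(cls, -"n"))
  } else {
    dplyr::left_join(reg, cls, by = c(by, "n"))
  }
}

#' Per-month, per-buoy evaluation of out-of-fold predictions
#'
#' One metrics row per `(buoy_id, calendar month)`, pooling every yearly
#' occurrence of that month (a three-year record contributes three
#' occurrences per month), plus an overall row per buoy (`month = NA`).
#' Month groups with no rows are still emitted with zero counts and absent
#' metrics so downstream tables stay rectangular.
#'
#' @inheritParams evaluate_predictions
#' @return A tibble with `buoy_id`, `month` (1-12 or `NA` for overall) and
#'   the metric columns of [evaluate_predictions()].
#' @export
monthly_breakdown <- function(oof, threshold = 10, inclusive = FALSE) {
  monthly <- evaluate_predictions(oof, by = c("buoy_id", "month"),
                                  threshold, inclusive)
  overall <- evaluate_predictions(oof, by = "buoy_id", threshold, inclusive) |>
    dplyr::mutate(month = NA_real_, .after = "buoy_id")
  full <- tidyr::expand_grid(buoy_id = unique(oof$buoy_id),
                             month = as.numeric(1:12))
  monthly <- dplyr::left_join(full, monthly, by = c("buoy_id", "month")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  dplyr::bind_rows(monthly, overall) |>
    dplyr::arrange(.data$buoy_id, .data$month)
}
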