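#' Run one soft-sensor experiment end to end
#'
#' Convenience wrapper chaining the full pipeline for one cell of the
#' experiment grid: build the input/output variant dataset from cleaned
#' records, run the chunked K-fold random search for each requested model
#' family, assemble out-of-fold predictions for each family's best
#' configuration, and evaluate regression and alarm metrics overall and
#' per buoy.
#'
#' @param records Cleaned sensor records (see [clean_records()]).
#' @param input_variant,output_variant Variant names, see
#'   [build_input_variant()] and [build_output_variant()].
#' @param families Model families to compare.
#' @param k,n_configs,seed,space Passed to [run_search()].
#' @param threshold,inclusive Alarm definition, see [alarm_flags()].
#' @param subset Optional [feature_subset()] applied to the input features
#'   before the search (e.g. `feature_subset("3-AGG")` on an `input_day`
#'   dataset).
#'
#' @return A list of class `"soft_sensor_experiment"` with `dataset`,
#'   `searches` (named by family), `oof` (row-bound predictions with a
#'   `family` column), `metrics` (overall per family), `by_buoy`, and the
#'   variant labels.
#' @export
run_experiment <- function(records, input_variant = "input_orig",
                           output_variant = "output_orig",
                           families = c("baseline", "lr", "cart", "rf"),
                           k = 10, n_configs = 25, seed = 1,
                           space = hyper_space(), threshold = 10,
                           inclusive = FALSE, subset = NULL) {
  dataset <- build_dataset(records, input_variant, output_variant)
  if (!is.null(subset)) dataset <- restrict_features(dataset, subset)
  searches <- purrr::map(setNames(families, families), function(fam) {
    run_search(dataset, family = fam, k = k, n_configs = n_configs,
               seed = seed, space = space)
  })
  oof <- purrr::imap(searches, function(s, fam) {
    dplyr::mutate(assemble_oof(dataset, s), family = fam, .before = 1)
  }) |> purrr::list_rbind()
  class(oof) <- c("oof_predictions", class(oof))
  metrics <- evaluate_predictions(oof, by = "family", threshold, inclusive)
  by_buoy <- evaluate_predictions(oof, by = c("family", "buoy_id"),
                                  threshold, inclusive)
  structure(list(dataset = dataset, searches = searches, oof = oof,
                 metrics = metrics, by_buoy = by_buoy,
                 input_variant = input_variant,
                 output_variant = output_variant,
                 threshold = threshold),
            class = "soft_sensor_experiment")
}

#' @export
print.soft_sensor_experiment <- function(x, ...) {
  cat("<soft_sensor_experiment> ", x$input_variant, " x ", x$output_variant,
      ", ", nrow(x$dataset), " rows\n", sep = "")
  print(as.data.frame(x$metrics), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.soft_sensor_experiment <- function(x, ...) x$by_buoy

#' @export
glance.soft_sensor_experiment <- function(x, ...) {
  dplyr::mutate(x$metrics, input_variant = x$input_variant,
                output_variant = x$output_variant)
}

#' Count the models scheduled by a full grid run
#'
#' The bookkeeping of the complete experiment: each of the
#' `nrow(grid)` dataset variations is searched with `n_configs`
#' configurations per tunable family, giving
#' `nrow(grid) * n_configs * n_families` unique hyperparameter settings,
#' and each setting trains `k` models (one per fold).
#'
#' @param grid An experiment grid, by default [experiment_grid()].
#' @param n_configs Configurations per family (default 25).
#' @param families Tunable families (default lr, cart, rf).
#' @param k Folds (default 10).
#' @return A one-row tibble: `n_variants`, `n_families`, `n_configs`,
#'   `k`, `unique_settings`, `scheduled_fits`.
#' @export
search_budget <- function(grid = experiment_grid(), n_configs = 25,
                          families = c("lr", "cart", "rf"), k = 10) {
  settings <- nrow(grid) * n_configs * length(families)
  tibble::tibble(
    n_variants = nrow(grid), n_families = length(families),
    n_configs = n_configs, k = k,
    unique_settings = settings,
    scheduled_fits = settings * k
  )
}
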