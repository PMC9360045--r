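#' Partition a time-sorted dataset into contiguous chunks
#'
#' Splits the row range into `k` contiguous, disjoint, near-equal chunks in
#' temporal order — never shuffling, so every chunk is a solid block of
#' time. Fold `i` uses chunk `i` for validation and the remaining `k - 1`
#' chunks (in their original order) for training, which preserves the
#' temporal relationship of the samples while still letting every calendar
#' month appear in some validation chunk.
#'
#' @param data A time-sorted dataset (or an integer row count).
#' @param k Number of chunks, at least 2 (default 10).
#' @return An object of class `"split_plan"`: list with `k`, `n`, `chunk`
#'   (per-row chunk index) and `sizes`.
#' @examples
#' plan <- make_chunks(101, k = 10)
#' plan$sizes
#' @export
make_chunks <- function(data, k = 10) {
  n <- if (is.numeric(data) && length(data) == 1) as.integer(data) else nrow(data)
  k <- as.integer(k)
  if (k < 2) abort("`k` must be at least 2")
  if (k > n) abort(paste0("cannot split ", n, " rows into ", k, " chunks"))
  base <- n %/% k
  sizes <- rep(base, k) + (seq_len(k) <= n %% k)
  chunk <- rep(seq_len(k), sizes)
  structure(list(k = k, n = n, chunk = chunk, sizes = sizes),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", x$n, " rows in ", x$k,
      " contiguous chunks (sizes ", min(x$sizes), "-", max(x$sizes),
      "), temporal order preserved\n", sep = "")
  invisible(x)
}

.fold_indices <- function(plan, fold, chunks = seq_len(plan$k)) {
  stopifnot(fold %in% chunks)
  list(train = which(plan$chunk %in% setdiff(chunks, fold)),
       val = which(plan$chunk == fold))
}

#' Chunked K-fold random hyperparameter search
#'
#' Evaluates randomly sampled hyperparameter configurations with
#' leave-one-chunk-out validation over the contiguous chunks of
#' [make_chunks()]: each configuration is represented by `k` models, each
#' trained on `k - 1` chunks and scored (MAE) on the held-out chunk, and
#' ranked by the mean of its `k` validation MAEs. The Yeo-Johnson +
#' standard-scaler normalizer is fitted per fold on the training chunks
#' only (it depends on the fold, not the configuration, so it is fitted
#' once per fold and shared). Ties in mean MAE go to the less complex
#' configuration (fewer estimators, then smaller depth, then smaller L2),
#' then to sampling order.
#'
#' @param data Time-sorted modelling dataset from [build_dataset()] (both
#'   buoys pooled; pass a filtered table for per-buoy training).
#' @param family One of `"lr"`, `"cart"`, `"rf"`, `"baseline"`.
#' @param target Target column name.
#' @param k Number of chunks (default 10).
#' @param n_configs Configurations to sample (default 25; the baseline has
#'   a single empty configuration).
#' @param seed Integer seed for config sampling and stochastic fits.
#' @param space A [hyper_space()].
#' @param configs Optional pre-sampled configuration tibble (overrides
#'   `n_configs`/`space`).
#' @param holdout_chunk Optional chunk index excluded from the search, for
#'   a final-test workflow where one contiguous block is reserved; see
#'   [assemble_oof()].
#' @param power_transform Passed to [fit_normalizer()]; set `FALSE` for
#'   affine-only (standard-scaler) normalization.
#'
#' @return An object of class `"soft_sensor_search"`: list with
#'   `leaderboard` (per-config mean and per-fold MAEs, ranked),
#'   `best_config`, `plan`, `family`, `target`, `seed`, `holdout_chunk`,
#'   and `n_models` (number of fits performed).
#' @export
run_search <- function(data, family = c("lr", "cart", "rf", "baseline"),
                       target = "target", k = 10, n_configs = 25, seed = 1,
                       space = hyper_space(), configs = NULL,
                       holdout_chunk = NULL, power_transform = TRUE) {
  family <- rlang::arg_match(family)
  plan <- make_chunks(data, k)
  search_chunks <- setdiff(seq_len(plan$k), holdout_chunk)
  if (length(search_chunks) < 2) abort("holdout leaves fewer than 2 chunks")
  configs <- configs %||% sample_configs(family, n = n_configs, seed = seed,
                                         space = space)
  configs <- configs[configs$family == family, , drop = FALSE]
  if (nrow(configs) == 0) abort("no configurations for this family")
  features <- setdiff(names(data), c("timestamp", "buoy_id", target))
  features <- features[vapply(data[features], is.numeric, logical(1))]

  folds <- purrr::map(search_chunks, .fold_indices, plan = plan,
                      chunks = search_chunks)
  normalizers <- if (family == "baseline") {
    vector("list", length(folds))
  } else {
    purrr::map(folds, function(f) {
      fit_normalizer(data[f$train, ], features, power_transform)
    })
  }

  n_models <- 0L
  rows <- purrr::map(seq_len(nrow(configs)), function(ci) {
    cfg <- configs[ci, ]
    fold_mae <- purrr::map_dbl(seq_along(folds), function(fi) {
      f <- folds[[fi]]
      res <- tryCatch({
        m <- fit_soft_sensor(data[f$train, c(features, target)],
                             target = target, family = family, config = cfg,
                             normalizer = normalizers[[fi]],
                             seed = seed + ci * 1000L + fi)
        n_models <<- n_models + 1L
        mean(abs(data[[target]][f$val] - predict(m, data[f$val, ])))
      }, error = function(e) NA_real_)
      res
    })
    dplyr::mutate(cfg, mean_mae = mean(fold_mae),
                  fold_mae = list(fold_mae),
                  failed = anyNA(fold_mae))
  }) |> purrr::list_rbind()

  ok <- rows[!rows$failed, , drop = FALSE]
  if (nrow(ok) == 0) abort("every configuration failed to fit")
  leaderboard <- ok |>
    dplyr::arrange(.data$mean_mae,
                   dplyr::coalesce(.data$n_estimators, 0L),
                   dplyr::coalesce(.data$max_depth, 0L),
                   dplyr::coalesce(.data$l2, 0),
                   .data$config_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (any(rows$failed)) {
    leaderboard <- dplyr::bind_rows(leaderboard,
                                    rows[rows$failed, , drop = FALSE])
  }

  structure(list(leaderboard = leaderboard,
                 best_config = leaderboard[1, ],
                 plan = plan, family = family, target = target,
                 features = features, seed = seed,
                 holdout_chunk = holdout_chunk,
                 search_chunks = search_chunks,
                 power_transform = power_transform,
                 n_models = n_models),
            class = "soft_sensor_search")
}

#' @export
print.soft_sensor_search <- function(x, ...) {
  b <- x$best_config
  cat("<soft_sensor_search> family ", x$family, ", ",
      nrow(x$leaderboard), " config(s) x ", length(x$search_chunks),
      " folds = ", x$n_models, " fits\n", sep = "")
  cat(sprintf("  best mean validation MAE: %.4f ug/L\n", b$mean_mae))
  invisible(x)
}

#' @export
tidy.soft_sensor_search <- function(x, ...) {
  dplyr::select(x$leaderboard, dplyr::all_of(
    c("rank", "family", "config_id", "l2", "max_depth", "n_estimators",
      "mean_mae", "failed")))
}

#' @export
glance.soft_sensor_search <- function(x, ...) {
  tibble::tibble(family = x$family, n_configs = nrow(x$leaderboard),
                 k = x$plan$k, n_models = x$n_models,
                 best_mean_mae = x$best_config$mean_mae)
}

#' Assemble out-of-fold predictions for the best configuration
#'
#' Refits the winning configuration once per fold and collects, for every
#' row, the prediction made by the model whose validation chunk contains
#' that row — so each row is predicted exactly once, by a model that never
#' saw it in training. The result carries buoy and calendar-month keys so a
#' three-year record yields, for each month, the three year-occurrences of
#' that month pooled for evaluation.
#'
#' If the search reserved a `holdout_chunk`, that chunk's rows are instead
#' predicted by a single model trained on all search chunks (the
#' reserved-test reading), and only those rows are returned.
#'
#' @param data The dataset the search was run on.
#' @param search A `"soft_sensor_search"` from [run_search()].
#' @return A tibble of class `"oof_predictions"`: `timestamp`, `buoy_id`,
#'   `month`, `fold`, `y_true`, `y_pred`.
#' @export
assemble_oof <- function(data, search) {
  stopifnot(inherits(search, "soft_sensor_search"))
  plan <- search$plan
  if (nrow(data) != plan$n) abort("`data` does not match the search's split plan")
  cfg <- search$best_config
  target <- search$target
  features <- search$features

  collect <- function(train_idx, val_idx, fold_id) {
    m <- fit_soft_sensor(data[train_idx, c(features, target)],
                         target = target, family = search$family,
                         config = cfg, seed = search$seed + fold_id,
                         power_transform = search$power_transform %||% TRUE)
    tibble::tibble(
      timestamp = data$timestamp[val_idx],
      buoy_id = if ("buoy_id" %in% names(data)) data$buoy_id[val_idx] else "all",
      month = lubridate::month(data$timestamp[val_idx]),
      fold = fold_id,
      y_true = data[[target]][val_idx],
      y_pred = predict(m, data[val_idx, ])
    )
  }

  out <- if (is.null(search$holdout_chunk)) {
    purrr::map(search$search_chunks, function(ch) {
      f <- .fold_indices(plan, ch, search$search_chunks)
      collect(f$train, f$val, ch)
    }) |> purrr::list_rbind()
  } else {
    train_idx <- which(plan$chunk %in% search$search_chunks)
    val_idx <- which(plan$chunk %in% search$holdout_chunk)
    collect(train_idx, val_idx, 0L)
  }
  class(out) <- c("oof_predictions", class(out))
  out
}
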