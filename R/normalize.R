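#' Fit a Yeo-Johnson + standard-scaler normalizer
#'
#' Estimates, per feature column, a Yeo-Johnson power-transform parameter
#' (a monotone family valid for zero and negative values, chosen because
#' battery and temperature anomalies may be non-positive) followed by a
#' location/scale standardization of the transformed values. Fitting must
#' only ever see training-fold rows; [apply_normalizer()] reuses the frozen
#' parameters and never refits, which is what keeps cross-validation free of
#' preprocessing leakage.
#'
#' Zero-variance columns get an identity transform and a scale of 1 (with a
#' warning) so they pass through centred but otherwise untouched.
#'
#' @param data A feature tibble; non-numeric and identifier/target columns
#'   (`timestamp`, `buoy_id`, `target`) are ignored.
#' @param columns Character vector of columns to normalize; defaults to all
#'   numeric feature columns.
#' @param power_transform If `FALSE`, skip the Yeo-Johnson step and
#'   standardize only (an affine map, useful when the features are already
#'   near-normal or when exact linearity must be preserved).
#'
#' @return An object of class `"normalizer"`: list with `columns`,
#'   `lambda` (named Yeo-Johnson parameters, `NA` for pass-through
#'   columns), `center`, `scale`, and `n_fit` (training rows used).
#' @examples
#' d <- tibble::tibble(a = rexp(50), b = rnorm(50, 10, 3))
#' nz <- fit_normalizer(d)
#' colMeans(apply_normalizer(nz, d)[, c("a", "b")])
#' @export
fit_normalizer <- function(data, columns = NULL, power_transform = TRUE) {
  columns <- columns %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))],
            c("timestamp", "buoy_id", "target"))
  if (nrow(data) == 0 || length(columns) == 0) {
    abort("cannot fit a normalizer on empty data")
  }
  x <- as.data.frame(data[, columns, drop = FALSE])
  sds <- vapply(x, sd, numeric(1))
  const <- is.na(sds) | sds == 0
  if (any(const)) {
    warn(paste0("zero-variance column(s), scale set to 1: ",
                paste(columns[const], collapse = ", ")))
  }
  lambda <- setNames(rep(NA_real_, length(columns)), columns)
  yj <- NULL
  yj_cols <- if (power_transform) columns[!const] else character(0)
  if (length(yj_cols)) {
    yj <- caret::preProcess(x[, yj_cols, drop = FALSE], method = "YeoJohnson")
    est <- unlist(yj$yj) # named lambdas; estimation may skip a column
    if (length(est)) lambda[names(est)] <- est
    x[, yj_cols] <- predict(yj, x[, yj_cols, drop = FALSE])
  }
  center <- vapply(x, mean, numeric(1))
  scale <- vapply(x, sd, numeric(1))
  scale[const | is.na(scale) | scale == 0] <- 1
  structure(list(columns = columns, lambda = lambda, yj = yj,
                 yj_cols = yj_cols, center = center, scale = scale,
                 n_fit = nrow(data)),
            class = "normalizer")
}

#' Apply a fitted normalizer to new data
#'
#' Transforms `data` with the frozen Yeo-Johnson parameters and
#' center/scale values of `state`; nothing is re-estimated, so applying the
#' same state to training and validation folds is leakage-safe by
#' construction.
#'
#' @param state A `"normalizer"` from [fit_normalizer()].
#' @param data A tibble containing all of `state$columns`.
#' @return `data` with the normalized columns replacing the originals.
#' @export
apply_normalizer <- function(state, data) {
  stopifnot(inherits(state, "normalizer"))
  missing <- setdiff(state$columns, names(data))
  if (length(missing)) {
    abort(paste0("data lacks normalized column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.data.frame(data[, state$columns, drop = FALSE])
  if (!is.null(state$yj) && length(state$yj_cols)) {
    x[, state$yj_cols] <- predict(state$yj,
                                  x[, state$yj_cols, drop = FALSE])
  }
  for (j in state$columns) {
    x[[j]] <- (x[[j]] - state$center[[j]]) / state$scale[[j]]
  }
  data[, state$columns] <- x
  data
}

#' @export
print.normalizer <- function(x, ...) {
  cat("<normalizer> Yeo-Johnson + standard scaler, ",
      length(x$columns), " column(s), fitted on ", x$n_fit, " rows\n", sep = "")
  invisible(x)
}

#' @export
tidy.normalizer <- function(x, ...) {
  tibble::tibble(column = x$columns, lambda = unname(x$lambda[x$columns]),
                 center = unname(x$center[x$columns]),
                 scale = unname(x$scale[x$columns]))
}
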