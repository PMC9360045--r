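#' Hyperparameter search space for the soft-sensor families
#'
#' Declares the random-search ranges: ridge (L2) coefficient in
#' `[1e-4, 1]` for linear regression (sampled log-uniformly, since the
#' range spans four decades), tree depth in `[1, 500]` for CART, and depth
#' in `[1, 500]` plus estimator count in `[2, 200]` for random forests.
#' The naive baseline has no hyperparameters.
#'
#' @param l2_range,depth_range,estimators_range Length-2 numeric ranges.
#' @return A list of class `"hyper_space"`.
#' @export
hyper_space <- function(l2_range = c(1e-4, 1),
                        depth_range = c(1L, 500L),
                        estimators_range = c(2L, 200L)) {
  stopifnot(l2_range[1] > 0, l2_range[1] < l2_range[2],
            depth_range[1] >= 1, depth_range[1] <= depth_range[2],
            estimators_range[1] >= 1,
            estimators_range[1] <= estimators_range[2])
  structure(list(l2_range = l2_range, depth_range = as.integer(depth_range),
                 estimators_range = as.integer(estimators_range)),
            class = "hyper_space")
}

.families <- c("lr", "cart", "rf", "baseline")

#' Randomly sample hyperparameter configurations
#'
#' Draws `n` configurations per requested family, uniformly over the
#' declared ranges (log-uniform for the L2 coefficient, uniform integers
#' for depths and estimator counts), reproducibly under `seed`. The
#' baseline family contributes a single empty configuration regardless of
#' `n` since it has nothing to tune.
#'
#' @param families Character vector among `"lr"`, `"cart"`, `"rf"`,
#'   `"baseline"`.
#' @param n Configurations per tunable family (default 25).
#' @param seed Integer seed.
#' @param space A [hyper_space()].
#'
#' @return A tibble with columns `family`, `config_id`, `l2`, `max_depth`,
#'   `n_estimators` (unused fields `NA`).
#' @export
sample_configs <- function(families = c("lr", "cart", "rf"), n = 25,
                           seed = 1, space = hyper_space()) {
  stopifnot(n >= 1)
  bad <- setdiff(families, .families)
  if (length(bad)) abort(paste0("unknown family: ", paste(bad, collapse = ", ")))
  withr::with_seed(seed, {
    purrr::map(families, function(fam) {
      if (fam == "baseline") {
        return(tibble::tibble(family = fam, config_id = 1L, l2 = NA_real_,
                              max_depth = NA_integer_,
                              n_estimators = NA_integer_))
      }
      tibble::tibble(
        family = fam,
        config_id = seq_len(n),
        l2 = if (fam == "lr") {
          exp(runif(n, log(space$l2_range[1]), log(space$l2_range[2])))
        } else NA_real_,
        max_depth = if (fam %in% c("cart", "rf")) {
          sample(space$depth_range[1]:space$depth_range[2], n, replace = TRUE)
        } else NA_integer_,
        n_estimators = if (fam == "rf") {
          sample(space$estimators_range[1]:space$estimators_range[2], n,
                 replace = TRUE)
        } else NA_integer_
      )
    }) |> purrr::list_rbind()
  })
}

.ridge_fit <- function(x, y, l2) {
  # exact ridge: minimizes ||y - b0 - X b||^2 + l2 * ||b||^2, intercept free
  x <- as.matrix(x)
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm)
  a <- crossprod(xc) + diag(l2, ncol(x))
  beta <- solve(a, crossprod(xc, y - ym))
  list(coef = drop(beta), intercept = ym - sum(xm * drop(beta)), names = colnames(x))
}

#' Fit one soft-sensor model
#'
#' Fits a single predictor of one of the four families on a feature matrix
#' and chlorophyll-a target: `"lr"` — linear regression with an exact L2
#' (ridge) penalty, intercept unpenalized; `"cart"` — an unpruned
#' squared-error regression tree grown to the configured depth (minimum
#' split 2, minimum leaf 1); `"rf"` — a bagged ensemble of such trees with
#' a random feature subset per split (a third of the features, the
#' regression convention) and bootstrap resampling; `"baseline"` — the
#' constant training-mean predictor every model must beat.
#'
#' A Yeo-Johnson + standard-scaler normalizer is fitted on the training
#' rows (or a prefitted, frozen one is attached via `normalizer`) and
#' applied before fitting; predictions reuse the frozen state.
#'
#' @param data Tibble with feature columns and the target.
#' @param target Name of the target column (default `"target"`).
#' @param family One of `"lr"`, `"cart"`, `"rf"`, `"baseline"`.
#' @param config One-row tibble or list with the family's hyperparameters
#'   (`l2`, `max_depth`, `n_estimators`); defaults to mid-range values.
#' @param normalizer Optional prefitted [fit_normalizer()] state, e.g. the
#'   fold-level one built by [run_search()].
#' @param seed Integer seed for the stochastic RF fit.
#' @param mtry_fraction Fraction of features tried per RF split.
#' @param min_node_size Minimum RF node size.
#' @param power_transform Passed to [fit_normalizer()] when no prefitted
#'   normalizer is supplied.
#'
#' @return An object of class `"soft_sensor"`.
#' @examples
#' d <- tibble::tibble(pH = rnorm(50, 8), target = rnorm(50, 5))
#' m <- fit_soft_sensor(d, family = "baseline")
#' predict(m, d)[1:3]
#' @export
fit_soft_sensor <- function(data, target = "target",
                            family = c("lr", "cart", "rf", "baseline"),
                            config = NULL, normalizer = NULL, seed = 1,
                            mtry_fraction = 1 / 3, min_node_size = 5,
                            power_transform = TRUE) {
  family <- rlang::arg_match(family)
  if (!target %in% names(data)) abort(paste0("no target column `", target, "`"))
  features <- setdiff(names(data), c("timestamp", "buoy_id", target))
  features <- features[vapply(data[features], is.numeric, logical(1))]
  if (nrow(data) == 0 || (length(features) == 0 && family != "baseline")) {
    abort("empty training data")
  }
  y <- data[[target]]
  if (anyNA(y) || anyNA(data[features])) abort("training data contains NA")
  config <- config %||% list(l2 = 0.01, max_depth = 30L, n_estimators = 100L)

  if (family != "baseline") {
    if (is.null(normalizer)) {
      normalizer <- fit_normalizer(data, features, power_transform)
    }
    xn <- apply_normalizer(normalizer, data[, features, drop = FALSE])
  } else {
    normalizer <- NULL
    xn <- NULL
  }

  fit <- switch(family,
    baseline = list(mean = mean(y)),
    lr = .ridge_fit(xn, y, config$l2),
    cart = {
      df <- as.data.frame(xn)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(
                     # rpart's depth ceiling is 30; with minbucket = 1 a
                     # depth-30 tree already exceeds any dataset here
                     maxdepth = min(config$max_depth, 30L),
                     cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                     maxsurrogate = 0, usesurrogate = 0))
    },
    rf = ranger::ranger(
      x = as.data.frame(xn), y = y,
      num.trees = config$n_estimators,
      max.depth = config$max_depth,
      mtry = max(1L, floor(length(features) * mtry_fraction)),
      min.node.size = min_node_size,
      importance = "impurity", seed = seed,
      num.threads = 1
    )
  )
  structure(list(family = family, config = config, fit = fit,
                 normalizer = normalizer, features = features,
                 target = target, n_train = nrow(data)),
            class = "soft_sensor")
}

#' Predict chlorophyll-a with a fitted soft-sensor
#'
#' @param object A `"soft_sensor"` model.
#' @param newdata Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted chlorophyll-a (ug/L), one per row.
#' @export
predict.soft_sensor <- function(object, newdata, ...) {
  if (object$family == "baseline") {
    return(rep(object$fit$mean, nrow(newdata)))
  }
  missing <- setdiff(object$features, names(newdata))
  extra_note <- setdiff(names(newdata),
                        c(object$features, "timestamp", "buoy_id",
                          object$target))
  if (length(missing)) {
    abort(paste0("newdata is missing feature column(s): ",
                 paste(missing, collapse = ", "),
                 if (length(extra_note)) paste0(" (extra: ",
                   paste(extra_note, collapse = ", "), ")") else ""))
  }
  xn <- apply_normalizer(object$normalizer,
                         newdata[, object$features, drop = FALSE])
  out <- switch(object$family,
    lr = {
      drop(as.matrix(xn[, object$fit$names, drop = FALSE]) %*%
             object$fit$coef) + object$fit$intercept
    },
    cart = unname(predict(object$fit, as.data.frame(xn))),
    rf = predict(object$fit, data = as.data.frame(xn),
                 num.threads = 1)$predictions
  )
  as.numeric(out)
}

#' @export
print.soft_sensor <- function(x, ...) {
  hp <- switch(x$family,
    lr = sprintf("l2 = %.4g", x$config$l2),
    cart = sprintf("max_depth = %d", x$config$max_depth),
    rf = sprintf("max_depth = %d, n_estimators = %d",
                 x$config$max_depth, x$config$n_estimators),
    baseline = sprintf("training mean = %.3f ug/L", x$fit$mean)
  )
  cat("<soft_sensor> ", x$family, " (", hp, "), trained on ", x$n_train,
      " rows\n", sep = "")
  invisible(x)
}

#' @export
tidy.soft_sensor <- function(x, ...) {
  switch(x$family,
    lr = tibble::tibble(term = c("(Intercept)", x$fit$names),
                        estimate = c(x$fit$intercept, unname(x$fit$coef))),
    baseline = tibble::tibble(term = "(Intercept)", estimate = x$fit$mean),
    cart = {
      imp <- x$fit$variable.importance
      if (is.null(imp)) imp <- setNames(numeric(0), character(0))
      tibble::tibble(term = names(imp), importance = unname(imp))
    },
    rf = tibble::tibble(term = names(x$fit$variable.importance),
                        importance = unname(x$fit$variable.importance))
  )
}

#' @export
glance.soft_sensor <- function(x, ...) {
  tibble::tibble(family = x$family, n_train = x$n_train,
                 n_features = length(x$features),
                 l2 = x$config$l2 %||% NA_real_,
                 max_depth = x$config$max_depth %||% NA_integer_,
                 n_estimators = x$config$n_estimators %||% NA_integer_)
}

#' Linear and nonlinear feature importance
#'
#' For a fitted random forest, reports each feature's impurity-decrease
#' importance normalized to sum to one (the nonlinear view: the more a
#' feature is used to split, the more important it is) alongside its
#' Pearson correlation with the target (the linear view). The two rankings
#' disagree exactly where the relationship is nonlinear.
#'
#' @param model A `"soft_sensor"` of family `"rf"`.
#' @param data The model's training data (features + target), used for the
#'   correlations.
#' @param target Target column name.
#' @return A tibble of class `"importance_table"`: `feature`, `importance`
#'   (shares summing to 1), `correlation`, sorted by decreasing importance.
#' @export
feature_importance <- function(model, data, target = "target") {
  if (!inherits(model, "soft_sensor") || model$family != "rf") {
    abort("feature importance requires a fitted random-forest soft_sensor")
  }
  imp <- model$fit$variable.importance
  imp <- pmax(imp, 0)
  share <- if (sum(imp) > 0) imp / sum(imp) else imp
  y <- data[[target]]
  out <- tibble::tibble(
    feature = names(share),
    importance = unname(share),
    correlation = vapply(names(share), function(v) {
      suppressWarnings(cor(data[[v]], y))
    }, numeric(1))
  ) |> dplyr::arrange(dplyr::desc(.data$importance))
  class(out) <- c("importance_table", class(out))
  out
}

#' Cumulative importance of a named feature subset
#'
#' @param importance An `"importance_table"` from [feature_importance()].
#' @param subset A [feature_subset()] or character vector of feature names.
#' @return The summed importance share of the subset's members.
#' @export
subset_importance <- function(importance, subset) {
  members <- if (inherits(subset, "feature_subset")) subset$features else subset
  missing <- setdiff(members, importance$feature)
  if (length(missing)) {
    abort(paste0("feature(s) absent from importance table: ",
                 paste(missing, collapse = ", ")))
  }
  sum(importance$importance[importance$feature %in% members])
}

#' Named feature subsets for reduced soft-sensors
#'
#' The two reduced input sets used to probe whether a handful of the most
#' important day-aggregated features can carry the model: `"3-AGG"`
#' (`pH_day_max`, `Temperature_day_min`, `SystemBattery_day_min`) and
#' `"5-AGG"` (those plus `Conductivity_day_max` and `pH_day_min`), or a
#' `"custom"` set of caller-chosen names.
#'
#' @param name `"3-AGG"`, `"5-AGG"` or `"custom"`.
#' @param features Member names when `name = "custom"`.
#' @return A list of class `"feature_subset"` with `name` and `features`.
#' @export
feature_subset <- function(name = c("3-AGG", "5-AGG", "custom"),
                           features = NULL) {
  name <- rlang::arg_match(name)
  three <- c("pH_day_max", "Temperature_day_min", "SystemBattery_day_min")
  members <- switch(name,
    "3-AGG" = three,
    "5-AGG" = c(three, "Conductivity_day_max", "pH_day_min"),
    custom = {
      if (is.null(features) || !length(features)) {
        abort("a custom subset needs `features`")
      }
      features
    }
  )
  structure(list(name = name, features = members), class = "feature_subset")
}

#' Restrict a feature matrix to a named subset
#'
#' @param data A feature tibble.
#' @param subset A [feature_subset()] or character vector of columns.
#' @return `data` with identifier/target columns plus only the subset's
#'   feature columns, in the subset's canonical order. Idempotent.
#' @export
restrict_features <- function(data, subset) {
  members <- if (inherits(subset, "feature_subset")) subset$features else subset
  missing <- setdiff(members, names(data))
  if (length(missing)) {
    abort(paste0("feature(s) not present: ", paste(missing, collapse = ", ")))
  }
  keep <- c(intersect(c("timestamp", "buoy_id"), names(data)), members,
            intersect("target", names(data)))
  data[, keep, drop = FALSE]
}
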