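# Gradient-boosted regression of conversion coefficients on collimator
# parameters, with the reference protocol: 3:2 train/validation split,
# exhaustive grid search with fourfold cross-validation, RMSE metric,
# permutation feature importance and a multiple-linear-regression
# baseline.  The boosted trees are backed by xgboost (squared-error
# objective, exact tree method, single thread for bit-reproducibility).

.ml_features <- c("hole_diameter", "septal_thickness", "length")

#' Random 3:2 train/validation split
#'
#' Seeded, disjoint and exhaustive; sizes within one row of the exact
#' ratio (210 rows -> 126 train / 84 validation).
#'
#' @param table data.frame (>= 5 rows).
#' @param seed RNG seed.
#' @param ratio train:validation ratio (two positive numbers).
#' @return list with `train` and `validation` data.frames.
#' @export
split_dataset <- function(table, seed, ratio = c(3, 2)) {
  n <- nrow(table)
  if (n < 5) stop("need at least 5 rows to split")
  n_train <- round(n * ratio[1] / sum(ratio))
  set.seed(seed)
  idx <- sample.int(n, n_train)
  list(train = table[idx, , drop = FALSE],
       validation = table[-idx, , drop = FALSE])
}

#' Default hyperparameter grid
#'
#' Discretization of the stated search ranges (learning rate 0.01-0.5,
#' 1-100 estimators, depth 1-8); includes the reported tuned point
#' (0.33, 25, 2).
#'
#' @return data.frame over `learning_rate`, `n_estimators`, `max_depth`.
#' @export
default_gbm_grid <- function() {
  expand.grid(learning_rate = c(0.01, 0.05, 0.1, 0.2, 0.33, 0.5),
              n_estimators = c(5, 10, 25, 50, 100),
              max_depth = 1:8)
}

.check_table <- function(table, features, target, min_rows = 20) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(c(features, target), names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(table) < min_rows)
    stop("feature table has ", nrow(table), " rows; need >= ", min_rows)
  if (anyNA(table[, c(features, target)]))
    stop("feature table contains missing values")
  if (any(as.matrix(table[, features, drop = FALSE]) <= 0))
    stop("collimator features must be positive")
  invisible(TRUE)
}

.xgb_fit <- function(x, y, pars, seed = 0L) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
  params <- list(objective = "reg:squarederror",
                 eta = pars$learning_rate,
                 max_depth = as.integer(pars$max_depth),
                 tree_method = "exact",
                 nthread = 1, seed = as.integer(seed))
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = as.integer(pars$n_estimators), verbose = 0)
}

#' Train the gradient-boosted regressor
#'
#' Exhaustive grid search over stagewise least-squares tree boosting,
#' selecting the hyperparameters with the best mean fourfold-CV RMSE on
#' the training set, then refitting on the full training set.  All seven
#' nonempty subsets of the three collimator features are supported.
#'
#' @param train training data.frame.
#' @param features character subset of `hole_diameter`,
#'   `septal_thickness`, `length`.
#' @param target name of the target column.
#' @param grid hyperparameter data.frame (`learning_rate`,
#'   `n_estimators`, `max_depth`).
#' @param folds number of CV folds (>= 2).
#' @param seed seed controlling fold assignment and the booster.
#' @return object of class `"trained_estimator"` with the fitted booster,
#'   chosen hyperparameters and the CV table.
#' @export
train_gbm <- function(train, features = .ml_features,
                      target = "compensated_cc", grid = default_gbm_grid(),
                      folds = 4, seed = 1L) {
  stopifnot(length(features) >= 1, all(features %in% .ml_features))
  .check_table(train, features, target)
  if (nrow(grid) < 1) stop("empty hyperparameter grid")
  if (folds < 2) stop("need >= 2 CV folds")
  if (any(grid$max_depth < 1) || any(grid$n_estimators < 1) ||
      any(grid$learning_rate <= 0))
    stop("invalid hyperparameter grid point")

  x <- as.matrix(train[, features, drop = FALSE])
  y <- train[[target]]
  n <- nrow(x)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))

  cv_rmse <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- .xgb_fit(x[tr, , drop = FALSE], y[tr], grid[i, ], seed)
      pred <- stats::predict(fit, as.matrix(x[!tr, , drop = FALSE]))
      sqrt(mean((pred - y[!tr])^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))

  best <- which.min(cv_rmse)
  booster <- .xgb_fit(x, y, grid[best, ], seed)
  structure(list(model_kind = "gbm",
                 booster = booster,
                 hyperparameters = as.list(grid[best, ]),
                 feature_subset = features,
                 target = target,
                 cv_results = cbind(grid, cv_rmse = cv_rmse),
                 train_target_range = range(y),
                 seed = seed),
            class = "trained_estimator")
}

#' Train the multiple linear regression baseline
#'
#' Ordinary least squares of the conversion coefficient on the selected
#' collimator parameters.
#'
#' @inheritParams train_gbm
#' @return a `"trained_estimator"` of kind `"linear"`.
#' @export
train_linear <- function(train, features = .ml_features,
                         target = "compensated_cc") {
  stopifnot(length(features) >= 1, all(features %in% .ml_features))
  .check_table(train, features, target, min_rows = length(features) + 2)
  fml <- stats::as.formula(paste(target, "~",
                                 paste(features, collapse = " + ")))
  fit <- stats::lm(fml, data = train)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: linear fit failed")
  structure(list(model_kind = "linear",
                 fit = fit,
                 hyperparameters = list(),
                 feature_subset = features,
                 target = target,
                 train_target_range = range(train[[target]])),
            class = "trained_estimator")
}

#' Predict conversion coefficients
#'
#' @param model a `"trained_estimator"`.
#' @param newdata a [collimator()], or a data.frame containing the
#'   model's feature columns.
#' @return predicted coefficient(s).
#' @export
predict_coefficient <- function(model, newdata) {
  if (!inherits(model, "trained_estimator")) stop("model is not fitted")
  if (inherits(newdata, "collimator"))
    newdata <- data.frame(hole_diameter = newdata$hole_diameter,
                          septal_thickness = newdata$septal_thickness,
                          length = newdata$length)
  if (model$model_kind == "gbm") {
    x <- as.matrix(newdata[, model$feature_subset, drop = FALSE])
    stats::predict(model$booster, x)
  } else {
    unname(stats::predict(model$fit, newdata))
  }
}

#' @export
print.trained_estimator <- function(x, ...) {
  cat(sprintf("<trained_estimator %s on {%s}%s>\n", x$model_kind,
              paste(x$feature_subset, collapse = ", "),
              if (x$model_kind == "gbm")
                sprintf(": lr=%.2f, n=%d, depth=%d",
                        x$hyperparameters$learning_rate,
                        x$hyperparameters$n_estimators,
                        x$hyperparameters$max_depth)
              else ""))
  invisible(x)
}

#' Validation RMSE of a fitted model
#'
#' @param model a `"trained_estimator"`.
#' @param data validation data.frame containing the feature and target
#'   columns.
#' @return root-mean-square prediction error.
#' @export
rmse <- function(model, data) {
  if (nrow(data) == 0) stop("validation set is empty")
  pred <- predict_coefficient(model, data)
  sqrt(mean((pred - data[[model$target]])^2))
}

#' Permutation feature importance
#'
#' Increase in validation mean squared error when one feature column is
#' randomly permuted, averaged over seeded repeats.
#'
#' @param model a `"trained_estimator"`.
#' @param data evaluation data.frame (typically the validation split).
#' @param repeats number of permutations per feature (>= 5).
#' @param seed RNG seed.
#' @return data.frame with `feature`, `importance` (mean MSE increase)
#'   and `sd`.
#' @export
permutation_importance <- function(model, data, repeats = 10, seed = 1L) {
  if (repeats < 5) stop("need >= 5 permutation repeats")
  y <- data[[model$target]]
  base_mse <- mean((predict_coefficient(model, data) - y)^2)
  set.seed(seed)
  imp <- lapply(model$feature_subset, function(f) {
    deltas <- vapply(seq_len(repeats), function(r) {
      perm <- data
      perm[[f]] <- sample(perm[[f]])
      mean((predict_coefficient(model, perm) - y)^2) - base_mse
    }, numeric(1))
    c(mean(deltas), stats::sd(deltas))
  })
  data.frame(feature = model$feature_subset,
             importance = vapply(imp, `[`, numeric(1), 1),
             sd = vapply(imp, `[`, numeric(1), 2),
             stringsAsFactors = FALSE)
}
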