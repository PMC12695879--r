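#' Stratified train/test split
#'
#' Randomly allocates `fraction` of the rows to training, stratified by a
#' grouping column so per-group proportions are preserved to within one
#' row. Disjoint and exhaustive; reproducible under `seed`.
#'
#' @param data data frame (>= 10 rows).
#' @param fraction training share (default 0.8).
#' @param seed integer seed.
#' @param strata name of the stratification column (default `"crop"`;
#'   `NULL` for simple random split).
#' @return list with `train` and `test` data frames.
#' @export
split_train_test <- function(data, fraction = 0.8, seed = 1, strata = "crop") {
  stopifnot(is.data.frame(data), nrow(data) >= 10, fraction > 0, fraction < 1)
  set.seed(seed)
  idx <- seq_len(nrow(data))
  groups <- if (!is.null(strata) && strata %in% names(data))
    split(idx, data[[strata]]) else list(idx)
  train_idx <- unlist(lapply(groups, function(g) {
    sample(g, round(length(g) * fraction))
  }), use.names = FALSE)
  list(train = data[sort(train_idx), , drop = FALSE],
       test = data[setdiff(idx, train_idx), , drop = FALSE])
}

#' Default hyper-parameter grid for forest tuning
#'
#' Tree count, candidate-feature count at each split, and minimum leaf
#' size; `mtry` defaults are the usual regression heuristics relative to
#' the number of features `p`.
#'
#' @param p number of features.
#' @param ntree,mtry,nodesize optional explicit axis values.
#' @return data frame of parameter combinations.
#' @export
rf_default_grid <- function(p, ntree = c(250, 500, 1000),
                            mtry = NULL, nodesize = c(1, 5, 10)) {
  if (is.null(mtry))
    mtry <- sort(unique(pmax(1, c(floor(p / 3), floor(sqrt(p)), round(p / 2)))))
  expand.grid(ntree = ntree, mtry = pmin(mtry, p), nodesize = nodesize)
}

# one-hot encode character/factor feature columns; numeric passthrough
encode_features <- function(data, features) {
  cols <- lapply(features, function(f) {
    v <- data[[f]]
    if (is.null(v)) stop("feature not found: ", f, call. = FALSE)
    if (is.numeric(v) || is.logical(v)) {
      out <- data.frame(as.numeric(v))
      names(out) <- f
      out
    } else {
      lev <- sort(unique(as.character(v)))
      out <- as.data.frame(lapply(lev, function(l) as.numeric(v == l)))
      names(out) <- paste(f, lev, sep = ".")
      out
    }
  })
  do.call(cbind, cols)
}

#' Tune and fit a random-forest model by grid search
#'
#' Exhaustive search over a hyper-parameter grid, scoring each combination
#' by root mean square error under k-fold cross-validation on the training
#' set, then refitting on the full training set at the argmin. The full CV
#' RMSE surface is retained so the parameter response can be inspected or
#' exported. Character/factor features are one-hot encoded; rows with
#' missing target are dropped (impute covariates beforehand, e.g. with
#' [impute_covariates()]).
#'
#' @param train training data frame.
#' @param target name of the numeric target column.
#' @param features character vector of feature columns.
#' @param grid data frame with `ntree`, `mtry`, `nodesize`
#'   (default [rf_default_grid()]).
#' @param seed integer seed (controls fold assignment and forest fitting).
#' @param folds number of CV folds (default 10).
#' @return object of class `nue_rf`: the fitted forest, `cv_surface`
#'   (grid plus `rmse`), chosen `params`, `features`, `target`.
#' @export
tune_and_fit <- function(train, target, features, grid = NULL, seed = 1,
                         folds = 10) {
  stopifnot(target %in% names(train))
  keep <- !is.na(train[[target]])
  train <- train[keep, , drop = FALSE]
  x <- encode_features(train, features)
  if (anyNA(x))
    stop("missing feature values; impute covariates before modelling",
         call. = FALSE)
  y <- train[[target]]
  if (is.null(grid)) grid <- rf_default_grid(ncol(x))
  stopifnot(nrow(grid) >= 1)
  if (stats::var(y) == 0) {
    warning("target has zero variance; returning a constant model")
    return(structure(list(forest = NULL, constant = mean(y),
                          cv_surface = cbind(grid, rmse = 0),
                          params = grid[1, , drop = FALSE],
                          features = features, encoded_names = names(x),
                          target = target, seed = seed),
                     class = "nue_rf"))
  }

  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(x)))
  rmse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sq_err <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (stats::var(y[tr]) == 0) {
        pred <- rep(mean(y[tr]), sum(!tr))
      } else {
        set.seed(seed + f)
        rf <- randomForest::randomForest(
          x = x[tr, , drop = FALSE], y = y[tr],
          ntree = grid$ntree[g], mtry = min(grid$mtry[g], ncol(x)),
          nodesize = grid$nodesize[g])
        pred <- stats::predict(rf, x[!tr, , drop = FALSE])
      }
      sq_err <- sq_err + sum((pred - y[!tr])^2)
    }
    rmse[g] <- sqrt(sq_err / nrow(x))
  }
  best <- which.min(rmse)
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = grid$ntree[best],
    mtry = min(grid$mtry[best], ncol(x)), nodesize = grid$nodesize[best])
  structure(list(forest = forest,
                 cv_surface = cbind(grid, rmse = rmse),
                 params = grid[best, , drop = FALSE],
                 features = features, encoded_names = names(x),
                 target = target, seed = seed),
            class = "nue_rf")
}

#' Predict with per-tree uncertainty
#'
#' Per-row mean and standard deviation over the individual trees of the
#' forest; the mean equals the ordinary forest prediction, the SD is the
#' between-tree spread used as a prediction uncertainty. Targets that are
#' percentages can be clipped to `[0, 100]` with `clip`.
#'
#' @param model a [tune_and_fit()] result.
#' @param newdata data frame containing the model's features.
#' @param clip optional length-2 numeric range to clip the mean to.
#' @return data frame with `mean` and `sd`.
#' @export
predict_with_uncertainty <- function(model, newdata, clip = NULL) {
  stopifnot(inherits(model, "nue_rf"))
  x <- encode_features(newdata, model$features)
  miss <- setdiff(model$encoded_names, names(x))
  for (m in miss) x[[m]] <- 0 # unseen one-hot level
  x <- x[, model$encoded_names, drop = FALSE]
  if (is.null(model$forest)) { # degenerate constant-target model
    mu <- rep(model$constant, nrow(x))
    if (!is.null(clip)) mu <- pmin(pmax(mu, clip[1]), clip[2])
    return(data.frame(mean = mu, sd = rep(0, nrow(x))))
  }
  all_pred <- stats::predict(model$forest, x, predict.all = TRUE)
  mu <- as.numeric(all_pred$aggregate)
  sdv <- apply(all_pred$individual, 1, stats::sd)
  if (model$forest$ntree == 1) sdv <- rep(0, length(mu))
  if (!is.null(clip)) mu <- pmin(pmax(mu, clip[1]), clip[2])
  data.frame(mean = mu, sd = as.numeric(sdv))
}

#' Hold-out evaluation of a fitted forest
#'
#' @param model a [tune_and_fit()] result.
#' @param test hold-out data frame containing the target.
#' @return list with `r2` (1 - SSres/SStot) and `rmse`.
#' @export
evaluate_holdout <- function(model, test) {
  keep <- !is.na(test[[model$target]])
  test <- test[keep, , drop = FALSE]
  pred <- predict_with_uncertainty(model, test)$mean
  obs <- test[[model$target]]
  list(r2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
       rmse = sqrt(mean((obs - pred)^2)))
}

#' Canonical feature set for soil-derived fraction models
#'
#' Climate, soil-property and management covariates used to predict the
#' soil-derived share of crop nutrient uptake.
#'
#' @return character vector of feature names.
#' @export
soil_fraction_features <- function() {
  c("mat", "map", "bd", "sand", "silt", "clay", "tc", "tn", "tp", "ap",
    "ph", "input_n", "input_p")
}
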