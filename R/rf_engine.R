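# Ensemble-of-trees chlorophyll models: regression on the raw Chla scale and
# classification at the 25 ug/L boundary. Backed by the randomForest package
# (bootstrap-resampled unpruned CART trees, mtry predictors per split,
# aggregation by averaging / majority vote); the surface here adds the fixed
# feature encoding, determinism via an explicit seed, and the tie-break rule.

#' Forest hyperparameters
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Predictors sampled per split; default `floor(p/3)` (at least
#'   1) for regression and `floor(sqrt(p))` for classification, resolved at
#'   fit time.
#' @param min_node_size Minimum terminal node size; default 5 for regression,
#'   1 for classification.
#' @param rng_seed Integer seed consumed at fit time.
#' @return An object of class `forest_hyperparams`.
#' @export
forest_hyperparams <- function(n_trees = 500, mtry = NULL,
                               min_node_size = NULL, rng_seed = 1L) {
  stopifnot(n_trees >= 1, is.null(mtry) || mtry >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = min_node_size,
                 rng_seed = as.integer(rng_seed)),
            class = "forest_hyperparams")
}

.resolve_hyperparams <- function(hp, p, mode) {
  mtry <- hp$mtry
  if (is.null(mtry)) {
    mtry <- if (mode == "regression") max(1, floor(p / 3))
            else max(1, floor(sqrt(p)))
  }
  if (mtry > p) stop("mtry (", mtry, ") exceeds predictor count (", p, ")",
                     call. = FALSE)
  nodesize <- hp$min_node_size
  if (is.null(nodesize)) nodesize <- if (mode == "regression") 5 else 1
  list(n_trees = hp$n_trees, mtry = mtry, nodesize = nodesize,
       rng_seed = hp$rng_seed)
}

.clf_levels <- c("not_eutrophic", "eutrophic")

#' Fit a tree ensemble on an encoded feature matrix
#'
#' @param x Numeric feature matrix (rows = lake x season observations).
#' @param y Response: numeric chlorophyll a for `mode = "regression"`, a
#'   logical eutrophic indicator for `mode = "classification"` (both classes
#'   must be present).
#' @param mode "regression" or "classification".
#' @param hyperparams A [forest_hyperparams()].
#' @return An object of class `chla_forest` wrapping the fitted ensemble,
#'   the resolved hyperparameters and the training feature order. Regression
#'   predictions are leaf averages and therefore never leave the training
#'   response range.
#' @export
fit_forest <- function(x, y, mode = c("regression", "classification"),
                       hyperparams = forest_hyperparams()) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need at least 10 training rows", call. = FALSE)
  if (length(y) != nrow(x)) stop("response length does not match feature rows",
                                 call. = FALSE)
  hp <- .resolve_hyperparams(hyperparams, ncol(x), mode)
  if (mode == "regression") {
    if (!is.numeric(y)) stop("regression response must be numeric", call. = FALSE)
    yy <- y
  } else {
    if (!is.logical(y)) stop("classification response must be logical", call. = FALSE)
    if (length(unique(y)) < 2) {
      stop("classification training data must contain both classes", call. = FALSE)
    }
    yy <- factor(ifelse(y, .clf_levels[2], .clf_levels[1]), levels = .clf_levels)
  }
  set.seed(hp$rng_seed)
  fit <- randomForest::randomForest(x = x, y = yy, ntree = hp$n_trees,
                                    mtry = hp$mtry, nodesize = hp$nodesize)
  structure(list(mode = mode, fit = fit, hyperparams = hp,
                 feature_names = colnames(x),
                 y_range = if (mode == "regression") range(y) else NULL),
            class = "chla_forest")
}

#' Predict from a fitted tree ensemble
#'
#' Regression: the mean of the tree predictions. Classification: majority
#' vote, with the vote fraction for the eutrophic class reported; a 0.5 tie
#' is broken towards "not eutrophic", mirroring the strict > 25 ug/L rule.
#'
#' @param model A `chla_forest`.
#' @param x Feature matrix with the training feature order.
#' @return Numeric predictions (regression) or a data frame with logical
#'   `label` and numeric `vote` columns (classification).
#' @export
predict_forest <- function(model, x) {
  stopifnot(inherits(model, "chla_forest"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names) ||
      !identical(colnames(x), model$feature_names)) {
    stop("feature matrix does not match the training feature order",
         call. = FALSE)
  }
  if (model$mode == "regression") {
    return(as.numeric(predict(model$fit, x)))
  }
  votes <- predict(model$fit, x, type = "vote")[, .clf_levels[2]]
  data.frame(label = votes > 0.5, vote = as.numeric(votes))
}

#' Fit the paired chlorophyll models on a lake table
#'
#' Computes normalisation statistics from the training rows, encodes every
#' observation, and fits the continuous (regression) and binomial
#' (classification at `threshold`) ensembles with season as a predictor.
#'
#' @param records,observations Training lake table.
#' @param hyperparams A [forest_hyperparams()]; the classification model
#'   consumes `rng_seed + 1` so the two fits are independent.
#' @param threshold Eutrophication boundary, ug/L.
#' @return An object of class `chla_models`: list with `regression`,
#'   `classification`, `norm`, `threshold`.
#' @export
fit_chla_models <- function(records, observations,
                            hyperparams = forest_hyperparams(),
                            threshold = 25) {
  idx <- match(observations$lake_id, records$lake_id)
  norm <- compute_norm_stats(records[idx, , drop = FALSE])
  enc <- .encode_dataset(records, observations, norm)
  reg <- fit_forest(enc$x, enc$y, "regression", hyperparams)
  hp2 <- hyperparams
  hp2$rng_seed <- hyperparams$rng_seed + 1L
  clf <- fit_forest(enc$x, classify_eutrophic(enc$y, threshold),
                    "classification", hp2)
  structure(list(regression = reg, classification = clf, norm = norm,
                 threshold = threshold),
            class = "chla_models")
}

#' Predict chlorophyll a for lake records across seasons
#'
#' @param models A [fit_chla_models()] result.
#' @param records Lake records to predict for.
#' @param seasons Seasons to expand each lake over (default all four).
#' @return Data frame with `lake_id`, `connectivity`, `season`, regression
#'   prediction `chla_pred`, and the classification `label` and `vote`.
#' @export
predict_chla <- function(models, records, seasons = lake_seasons) {
  stopifnot(inherits(models, "chla_models"))
  ord <- rep(seq_len(nrow(records)), each = length(seasons))
  seas <- rep(seasons, times = nrow(records))
  x <- .design_matrix(records[ord, , drop = FALSE], seas, models$norm)
  clf <- if (is.null(models$classification)) {
    data.frame(label = rep(NA, length(seas)), vote = rep(NA_real_, length(seas)))
  } else {
    predict_forest(models$classification, x)
  }
  data.frame(lake_id = records$lake_id[ord],
             connectivity = records$connectivity[ord],
             season = seas,
             chla_pred = predict_forest(models$regression, x),
             label = clf$label, vote = clf$vote,
             stringsAsFactors = FALSE)
}
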