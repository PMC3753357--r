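# Repeated-holdout evaluation: averaged R-squared for the continuous model,
# averaged Cohen's kappa for the binomial model.

#' R-squared between observed and predicted values
#'
#' Default definition: squared Pearson correlation between observed and
#' predicted, the reading of "R-squared between observed and predicted"
#' usual in cross-validation reports (invariant to affine rescaling of the
#' predictions, always in \[0, 1\]). The Nash-Sutcliffe / coefficient-of-
#' determination form `1 - SSE/SST` is available as `method = "nse"` (it can
#' be negative and penalises bias).
#'
#' @param observed,predicted Numeric vectors of equal length (at least 3).
#' @param method "correlation" (default) or "nse".
#' @return Scalar.
#' @export
r_squared <- function(observed, predicted,
                      method = c("correlation", "nse")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted) || length(observed) < 3) {
    stop("observed and predicted must have equal length >= 3", call. = FALSE)
  }
  if (sd(observed) == 0 || (method == "correlation" && sd(predicted) == 0)) {
    stop("zero variance in observed or predicted values", call. = FALSE)
  }
  if (method == "correlation") {
    cor(observed, predicted)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}

#' Cohen's kappa for two binary labelings
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and chance
#' agreement `p_e` from the marginal proportions. When `p_e = 1` (both
#' labelings constant and identical, hence perfect agreement) kappa is 1.
#'
#' @param labels_true,labels_pred Logical vectors of equal length (>= 1).
#' @return Scalar in \[-1, 1\].
#' @export
cohens_kappa <- function(labels_true, labels_pred) {
  stopifnot(is.logical(labels_true), is.logical(labels_pred),
            length(labels_true) == length(labels_pred),
            length(labels_true) >= 1)
  po <- mean(labels_true == labels_pred)
  pt <- mean(labels_true)
  pp <- mean(labels_pred)
  pe <- pt * pp + (1 - pt) * (1 - pp)
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Repeated holdout validation of the paired chlorophyll models
#'
#' Per repeat: draw a random train/test split (by default whole lakes travel
#' together so the four seasonal observations of a lake never straddle the
#' split), compute normalisation statistics on the training rows only, fit
#' the regression and classification ensembles on the training rows, predict
#' the held-out rows, and record the R-squared of the continuous predictions
#' and Cohen's kappa of the binomial ones. Reports per-repeat values and
#' their means; a repeat whose test split is degenerate (single truth class
#' for kappa, or zero variance for R-squared) records a missing value,
#' excluded from the mean, with a warning.
#'
#' @param records,observations The lake table.
#' @param train_frac Fraction of split units used for training (default 0.8).
#' @param n_repeats Number of random splits (default 30).
#' @param split_unit "lake" (default) or "observation".
#' @param hyperparams Forest hyperparameters (per-repeat seeds are derived
#'   from `rng_seed`).
#' @param threshold Eutrophication boundary, ug/L.
#' @param r2_method Passed to [r_squared()].
#' @param rng_seed Seed governing the split draws.
#' @param pooled If TRUE, additionally compute R-squared and kappa on the
#'   predictions pooled across all repeats.
#' @param keep_details If TRUE, keep each repeat's test lake ids and
#'   normalisation statistics (for leakage audits).
#' @return An object of class `validation_report`: list with `per_repeat`
#'   data frame, `mean_r2`, `mean_kappa`, the settings, and optionally
#'   `pooled_r2`, `pooled_kappa`, `details`.
#' @export
repeated_holdout <- function(records, observations, train_frac = 0.8,
                             n_repeats = 30, split_unit = c("lake", "observation"),
                             hyperparams = forest_hyperparams(),
                             threshold = 25,
                             r2_method = c("correlation", "nse"),
                             rng_seed = 1L, pooled = FALSE,
                             keep_details = FALSE) {
  split_unit <- match.arg(split_unit)
  r2_method <- match.arg(r2_method)
  stopifnot(train_frac > 0, train_frac < 1, n_repeats >= 1)
  set.seed(rng_seed)
  # pre-draw split randomness so fit-time seeding cannot disturb it
  units <- if (split_unit == "lake") records$lake_id else seq_len(nrow(observations))
  n_units <- length(units)
  n_train <- floor(train_frac * n_units)
  if (n_train < 2 || n_train >= n_units) {
    stop("dataset too small for the requested train fraction", call. = FALSE)
  }
  splits <- lapply(seq_len(n_repeats), function(i) sample(units, n_train))
  pooled_obs <- pooled_pred <- numeric(0)
  pooled_truth <- pooled_lab <- logical(0)
  details <- vector("list", n_repeats)
  res <- lapply(seq_len(n_repeats), function(i) {
    in_train <- if (split_unit == "lake") {
      observations$lake_id %in% splits[[i]]
    } else {
      seq_len(nrow(observations)) %in% splits[[i]]
    }
    train_obs <- observations[in_train, , drop = FALSE]
    test_obs <- observations[!in_train, , drop = FALSE]
    hp <- hyperparams
    hp$rng_seed <- hyperparams$rng_seed + 2L * i
    models <- fit_chla_models(records, train_obs, hp, threshold)
    enc_test <- .encode_dataset(records, test_obs, models$norm)
    pred <- predict_forest(models$regression, enc_test$x)
    clf <- predict_forest(models$classification, enc_test$x)
    truth <- classify_eutrophic(test_obs$chla, threshold)
    r2 <- if (sd(test_obs$chla) == 0 || sd(pred) == 0) {
      warning("repeat ", i, ": degenerate test split for R-squared; recorded as NA",
              call. = FALSE)
      NA_real_
    } else r_squared(test_obs$chla, pred, r2_method)
    kap <- if (length(unique(truth)) < 2) {
      warning("repeat ", i, ": single-class test split; kappa recorded as NA",
              call. = FALSE)
      NA_real_
    } else cohens_kappa(truth, clf$label)
    if (pooled) {
      pooled_obs <<- c(pooled_obs, test_obs$chla)
      pooled_pred <<- c(pooled_pred, pred)
      pooled_truth <<- c(pooled_truth, truth)
      pooled_lab <<- c(pooled_lab, clf$label)
    }
    if (keep_details) {
      details[[i]] <<- list(test_ids = if (split_unit == "lake")
        setdiff(units, splits[[i]]) else which(!in_train),
        norm = models$norm)
    }
    data.frame(repeat_id = i, r2 = r2, kappa = kap, n_test = nrow(test_obs))
  })
  per_repeat <- do.call(rbind, res)
  out <- list(per_repeat = per_repeat,
              mean_r2 = mean(per_repeat$r2, na.rm = TRUE),
              mean_kappa = mean(per_repeat$kappa, na.rm = TRUE),
              n_repeats = n_repeats, train_frac = train_frac,
              split_unit = split_unit, threshold = threshold,
              r2_method = r2_method, rng_seed = rng_seed)
  if (pooled) {
    out$pooled_r2 <- r_squared(pooled_obs, pooled_pred, r2_method)
    out$pooled_kappa <- cohens_kappa(pooled_truth, pooled_lab)
  }
  if (keep_details) out$details <- details
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Repeated holdout validation (%d repeats, %.0f%%/%.0f%% by %s)\n",
              x$n_repeats, 100 * x$train_frac, 100 * (1 - x$train_frac),
              x$split_unit))
  cat(sprintf("  mean R-squared (%s): %.3f\n", x$r2_method, x$mean_r2))
  cat(sprintf("  mean Cohen's kappa:  %.3f\n", x$mean_kappa))
  invisible(x)
}
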