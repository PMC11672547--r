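#' Random-forest regressor configuration
#'
#' The target is always `log10(Ki / 1 nM)`: the families span 250–750-fold Ki
#' ranges, so an untransformed target would be dominated by the weakest
#' binders.
#'
#' @param n_trees Number of trees.
#' @param max_depth Optional depth cap (`NULL` = unlimited, the forest
#'   default).
#' @param min_samples_leaf Minimum node size.
#' @param max_features Fraction of features tried per split, or `"default"`
#'   for the regression rule (p/3).
#' @param seed Integer seed; the fit is run-to-run deterministic given it.
#' @return A `regressor_config`.
#' @export
regressor_config <- function(n_trees = 500, max_depth = NULL,
                             min_samples_leaf = 1, max_features = "default",
                             seed = 1) {
  if (n_trees < 1) abort("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_features = max_features, seed = as.integer(seed)),
            class = "regressor_config")
}

rf_fit_once <- function(x, y, config) {
  mtry <- if (identical(config$max_features, "default")) {
    max(floor(ncol(x) / 3), 1)
  } else {
    max(1, floor(config$max_features * ncol(x)))
  }
  args <- list(x = x, y = y, ntree = config$n_trees, mtry = mtry,
               nodesize = config$min_samples_leaf)
  if (!is.null(config$max_depth)) args$maxnodes <- 2^config$max_depth
  do.call(randomForest::randomForest, args)
}

#' Fit the random-forest Ki regressor
#'
#' Trains on `y = log10(Ki / 1 nM)` and reports a k-fold cross-validated RMSE
#' (`k = min(5, n)`, folds drawn once from the seed) next to the in-sample
#' RMSE; their difference is the overfitting gap that is substantial in the
#' small-n regime these families live in.
#'
#' @param records Affinity tibble (`id`, `sequence`, `ki` in molar) from
#'   [read_affinity_table()] or [affinity_records()].
#' @param scaffold A [scaffold()].
#' @param spec A [feature_spec()].
#' @param config A [regressor_config()].
#' @return A `ki_regressor`: list with the fitted `forest`, `spec`,
#'   `scaffold`, `config` and `report` (`cv_rmse`, `train_rmse`,
#'   `overfit_gap`, `folds`).
#' @export
fit_regressor <- function(records, scaffold, spec = feature_spec(),
                          config = regressor_config()) {
  n <- nrow(records)
  if (n < 5) abort("need at least 5 records to fit the regressor")
  if (any(records$ki <= 0)) abort("all Ki must be > 0")
  x <- featurize(records$sequence, scaffold, spec)
  y <- log10(records$ki / 1e-9)
  if (length(unique(y)) == 1L) {
    warn("constant target: the regressor will predict a constant")
  }
  k <- min(5L, n)
  set.seed(config$seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  cv_pred <- numeric(n)
  for (f in seq_len(k)) {
    hold <- fold == f
    set.seed(config$seed + f)
    m <- rf_fit_once(x[!hold, , drop = FALSE], y[!hold], config)
    cv_pred[hold] <- predict(m, x[hold, , drop = FALSE])
  }
  set.seed(config$seed)
  forest <- rf_fit_once(x, y, config)
  train_pred <- predict(forest, x)
  report <- tibble(cv_rmse = sqrt(mean((cv_pred - y)^2)),
                   train_rmse = sqrt(mean((train_pred - y)^2)),
                   overfit_gap = NA_real_, folds = k)
  report$overfit_gap <- report$cv_rmse - report$train_rmse
  structure(list(forest = forest, spec = spec, scaffold = scaffold,
                 config = config, report = report,
                 feature_names = colnames(x)),
            class = "ki_regressor")
}

#' @export
print.ki_regressor <- function(x, ...) {
  cat(sprintf("<ki_regressor> %d trees; cv RMSE %.3f, train RMSE %.3f (log10 nM)\n",
              x$config$n_trees, x$report$cv_rmse, x$report$train_rmse))
  invisible(x)
}

#' @export
glance.ki_regressor <- function(x, ...) x$report

#' @export
tidy.ki_regressor <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(feature = rownames(imp), importance = as.vector(imp[, 1])) |>
    arrange(desc(.data$importance))
}

#' Predict inhibition constants for new sequences
#'
#' Averages the per-tree outputs on the log10-nM scale and back-transforms to
#' molar units; predictions are therefore strictly positive.
#'
#' @param model A `ki_regressor`.
#' @param sequences Character vector of scaffold-conformant sequences.
#' @return Numeric vector of predicted Ki in molar units.
#' @export
predict_ki <- function(model, sequences) {
  x <- featurize(sequences, model$scaffold, model$spec)
  if (!identical(colnames(x), model$feature_names)) {
    abort(sprintf("feature mismatch: model expects %d features (%s...), got %d",
                  length(model$feature_names), model$feature_names[1], ncol(x)))
  }
  yhat <- unname(predict(model$forest, x))
  10^yhat * 1e-9
}

#' Linear-interpolation percentile of a reference set
#'
#' `pct = 50` is the sample median under the usual linear-interpolation
#' convention (R quantile type 7).
#'
#' @param values Nonempty numeric vector.
#' @param pct Percentile in `(0, 100]` (100 returns the maximum, which under
#'   the strict selection rule keeps everything but the top ties).
#' @return Scalar threshold.
#' @export
percentile_threshold <- function(values, pct = 50) {
  if (!length(values)) abort("empty reference set")
  if (pct <= 0 || pct > 100) abort("pct must be in (0, 100]")
  unname(quantile(values, pct / 100, type = 7))
}

#' Keep entries strictly below a threshold
#'
#' @param sequences,predictions Parallel vectors.
#' @param threshold Scalar cutoff; selection is strict (`<`), matching the
#'   "predicted to be lower than" rule.
#' @return Tibble `sequence`, `prediction` (input order preserved) with the
#'   selected fraction as attribute `fraction`.
#' @export
filter_by_threshold <- function(sequences, predictions, threshold) {
  if (length(sequences) != length(predictions)) {
    abort("sequences and predictions differ in length")
  }
  keep <- predictions < threshold
  out <- tibble(sequence = sequences[keep], prediction = predictions[keep])
  attr(out, "fraction") <- if (length(keep)) mean(keep) else 0
  out
}
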