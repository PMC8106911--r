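#' Split a labeled dataset into training and testing partitions
#'
#' Uniform (non-stratified) random partition of the genomes into a
#' training set of `round(train_fraction * n)` genomes and a testing set
#' of the remainder — a 60:40 split of 1,057 genomes gives 634 and 423.
#' The returned partitions carry a `"partition"` attribute (`"train"` /
#' `"test"`); all model-development operations accept only the train
#' partition and raise if handed the test partition, so the test set
#' cannot leak into hyperparameter tuning.
#'
#' @param dataset Labeled dataset from [assemble_dataset()].
#' @param train_fraction Fraction of genomes assigned to training
#'   (default 0.6).
#' @param seed Integer seed; the same seed always yields the same
#'   partition.
#' @return A list with elements `train` and `test` (labeled datasets).
#' @export
train_test_split <- function(dataset, train_fraction = 0.6, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1")
  }
  n <- nrow(dataset)
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    abort("dataset too small to split")
  }
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  train <- dataset[sort(idx), , drop = FALSE]
  test <- dataset[setdiff(seq_len(n), idx), , drop = FALSE]
  for (part in list(train, test)) {
    if (dplyr::n_distinct(part$lifestyle) < 2) {
      abort("split left a partition with a single lifestyle; use more data or another seed")
    }
  }
  attr(train, "partition") <- "train"
  attr(test, "partition") <- "test"
  list(train = train, test = test)
}

assert_train_partition <- function(dataset, fn) {
  tag <- attr(dataset, "partition", exact = TRUE)
  if (identical(tag, "test")) {
    abort(sprintf(
      "%s() refuses the test partition: the testing set must stay untouched during model development",
      fn
    ))
  }
  if (!identical(tag, "train")) {
    abort(sprintf(
      "%s() requires the train partition from train_test_split() (missing partition tag)",
      fn
    ))
  }
  invisible(dataset)
}

#' Hyperparameter grid for random-forest model selection
#'
#' The default grid is the full published search space: bootstrap on/off,
#' two balanced class-weighting modes, minimum leaf sizes 1 and 2, 10 to
#' 100 trees in steps of 5 (19 values) and maximum depths 10 to 40 in
#' steps of 2 (16 values) — 2 x 2 x 2 x 19 x 16 = 1,216 combinations.
#'
#' @param bootstrap,class_weight,min_samples_leaf,n_estimators,max_depth
#'   Candidate values for each hyperparameter (non-empty).
#' @return A `grid_spec` list of candidate values.
#' @export
rf_grid <- function(bootstrap = c(TRUE, FALSE),
                    class_weight = c("balanced", "balanced_subsample"),
                    min_samples_leaf = c(1L, 2L),
                    n_estimators = seq(10L, 100L, by = 5L),
                    max_depth = seq(10L, 40L, by = 2L)) {
  spec <- list(
    bootstrap = bootstrap, class_weight = class_weight,
    min_samples_leaf = as.integer(min_samples_leaf),
    n_estimators = as.integer(n_estimators),
    max_depth = as.integer(max_depth)
  )
  if (any(lengths(spec) == 0)) {
    abort("all grid dimensions must be non-empty")
  }
  structure(spec, class = "grid_spec")
}

#' Enumerate a hyperparameter grid
#'
#' Cartesian product of the grid dimensions in the documented fixed order:
#' `bootstrap` varies slowest, then `class_weight`, `min_samples_leaf`,
#' `n_estimators`, and `max_depth` fastest. The row number is the
#' combination's enumeration index used for tie-breaking in
#' [select_best()].
#'
#' @param grid A grid from [rf_grid()].
#' @return A tibble with one row per combination.
#' @export
grid_combinations <- function(grid) {
  tidyr::expand_grid(
    bootstrap = grid$bootstrap,
    class_weight = grid$class_weight,
    min_samples_leaf = grid$min_samples_leaf,
    n_estimators = grid$n_estimators,
    max_depth = grid$max_depth
  )
}

# One train/validation resplit of the training partition: returns row
# indices of the inner training set.
resplit_indices <- function(n, validation_fraction, seed) {
  n_val <- max(1L, round(validation_fraction * n))
  if (n_val >= n) {
    abort("`validation_fraction` leaves no inner training data")
  }
  withr::with_seed(seed, sample.int(n, n - n_val))
}

#' Evaluate a hyperparameter grid over repeated validation resplits
#'
#' For each hyperparameter combination, fits the forest on each of
#' `n_resplits` random sub-splits of the training partition and records
#' the validation-set accuracy (and, for inspection, the validation F1
#' with temperate as the positive class). The same `n_resplits` inner
#' partitions — derived deterministically from `seed` — are reused across
#' all combinations, so combinations are compared on identical validation
#' sets. Only the training partition from [train_test_split()] is
#' accepted.
#'
#' @param train The train partition.
#' @param grid A [rf_grid()].
#' @param n_resplits Number of train/validation resplits (default 20).
#' @param validation_fraction Fraction of the training partition held out
#'   as the validation set in each resplit (default 0.25).
#' @param seed Integer seed; resplit `r` uses seed `seed + r`.
#' @return A tibble with one row per combination: the hyperparameter
#'   columns, list-columns `accuracies` and `f1s` (length `n_resplits`),
#'   and summary columns `min_accuracy` and `mean_accuracy`.
#' @export
evaluate_grid <- function(train, grid = rf_grid(), n_resplits = 20,
                          validation_fraction = 0.25, seed = 1L) {
  assert_train_partition(train, "evaluate_grid")
  combos <- grid_combinations(grid)
  n <- nrow(train)
  splits <- purrr::map(
    seq_len(n_resplits),
    ~ resplit_indices(n, validation_fraction, seed + .x)
  )
  eval_combo <- function(bootstrap, class_weight, min_samples_leaf,
                         n_estimators, max_depth) {
    hp <- lifestyle_hyperparameters(
      bootstrap = bootstrap, class_weight = class_weight,
      min_samples_leaf = min_samples_leaf,
      n_estimators = n_estimators, max_depth = max_depth
    )
    res <- purrr::map(splits, function(inner_idx) {
      inner_train <- train[inner_idx, , drop = FALSE]
      validation <- train[-inner_idx, , drop = FALSE]
      model <- fit_lifestyle_model(inner_train, hp, seed = seed)
      pred <- predict(model, validation)
      cm <- confusion_matrix(validation$lifestyle, pred$call)
      classification_metrics(cm)[c("accuracy", "f1")]
    })
    tibble(
      accuracies = list(map_dbl(res, "accuracy")),
      f1s = list(map_dbl(res, "f1"))
    )
  }
  scores <- purrr::pmap(combos, eval_combo)
  out <- dplyr::bind_cols(combos, dplyr::bind_rows(scores))
  out$min_accuracy <- map_dbl(out$accuracies, min)
  out$mean_accuracy <- map_dbl(out$accuracies, mean)
  out
}

#' Select the best hyperparameter combination
#'
#' The operative rule is max-min validation accuracy: the chosen
#' combination is the one whose worst validation-resplit accuracy is
#' highest. Ties are broken by higher mean accuracy, then by grid
#' enumeration order (first row wins).
#'
#' @param grid_result Result tibble from [evaluate_grid()] (columns
#'   `min_accuracy` and `mean_accuracy` plus hyperparameter columns).
#' @return A one-row tibble of the selected hyperparameters, as accepted
#'   by [fit_lifestyle_model()].
#' @export
select_best <- function(grid_result) {
  if (nrow(grid_result) == 0) {
    abort("`grid_result` is empty")
  }
  i <- order(
    -grid_result$min_accuracy, -grid_result$mean_accuracy,
    seq_len(nrow(grid_result))
  )[1]
  row <- grid_result[i, , drop = FALSE]
  lifestyle_hyperparameters(
    bootstrap = row$bootstrap,
    class_weight = row$class_weight,
    min_samples_leaf = row$min_samples_leaf,
    n_estimators = row$n_estimators,
    max_depth = row$max_depth
  )
}

#' Refit the selected hyperparameters on the full training partition
#'
#' The final model is obtained by refitting the selected configuration on
#' the entire training partition (not on any inner resplit).
#'
#' @param train The train partition from [train_test_split()].
#' @param hyperparameters Selected hyperparameters (e.g. from
#'   [select_best()]).
#' @param seed Integer seed for the refit.
#' @return A `lifestyle_model`.
#' @export
finalize_model <- function(train, hyperparameters, seed = 1L) {
  assert_train_partition(train, "finalize_model")
  fit_lifestyle_model(train, hyperparameters, seed = seed)
}
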