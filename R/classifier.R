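MODEL_FORMAT_VERSION <- "1"

#' Random-forest hyperparameters for lifestyle classification
#'
#' Constructor for the hyperparameter set understood by
#' [fit_lifestyle_model()]. The defaults are the final published
#' configuration of the classifier: 80 trees of depth at most 40, leaves
#' of at least 1 sample, no bootstrap resampling (every tree sees the full
#' training set; trees still differ through random feature selection at
#' each split), and balanced class weighting to correct for the unequal
#' number of temperate and virulent training genomes.
#'
#' `class_weight` accepts `"balanced"` or `"balanced_subsample"`; with
#' bootstrap disabled the two are equivalent (per-tree subsample weights
#' reduce to full-sample weights), and both are implemented as class
#' weights inversely proportional to class frequency.
#'
#' @param bootstrap Logical; draw a bootstrap sample per tree?
#' @param class_weight `"balanced"` or `"balanced_subsample"`.
#' @param min_samples_leaf Minimum samples per leaf (>= 1).
#' @param n_estimators Number of trees (>= 1).
#' @param max_depth Maximum tree depth (>= 1).
#' @return A one-row tibble of hyperparameters.
#' @export
lifestyle_hyperparameters <- function(bootstrap = FALSE,
                                      class_weight = "balanced_subsample",
                                      min_samples_leaf = 1,
                                      n_estimators = 80,
                                      max_depth = 40) {
  class_weight <- match.arg(class_weight, c("balanced", "balanced_subsample"))
  stopifnot(
    is.logical(bootstrap), length(bootstrap) == 1,
    min_samples_leaf >= 1, n_estimators >= 1, max_depth >= 1
  )
  tibble(
    bootstrap = bootstrap,
    class_weight = class_weight,
    min_samples_leaf = as.integer(min_samples_leaf),
    n_estimators = as.integer(n_estimators),
    max_depth = as.integer(max_depth)
  )
}

balanced_class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

#' Fit the lifestyle random-forest model
#'
#' Trains a probability random forest on a labeled presence/absence
#' dataset. The fitted model stores the exact ordered domain set it was
#' trained on (prediction refuses inputs with a different feature
#' contract), the hyperparameters, the seed, and a fingerprint of the
#' training matrix and labels, so retraining is reproducible and a saved
#' model is self-describing.
#'
#' @param dataset Labeled dataset from [assemble_dataset()] with >= 2
#'   genomes in each class and strictly 0/1 feature values.
#' @param hyperparameters A row from [lifestyle_hyperparameters()].
#' @param seed Integer seed controlling forest construction.
#' @return An object of class `lifestyle_model`.
#' @export
fit_lifestyle_model <- function(dataset,
                                hyperparameters = lifestyle_hyperparameters(),
                                seed = 1L) {
  hp <- hyperparameters
  y <- as_lifestyle(dataset$lifestyle, arg = "dataset$lifestyle")
  if (any(table(y) < 2)) {
    abort("training data must contain at least 2 genomes of each lifestyle")
  }
  x <- dataset_features(dataset)
  check_binary_features(as.data.frame(x))
  if (ncol(x) == 0) {
    abort("training data has no feature columns")
  }
  forest <- ranger::ranger(
    x = as.data.frame(x), y = y,
    probability = TRUE,
    num.trees = hp$n_estimators,
    max.depth = hp$max_depth,
    min.node.size = hp$min_samples_leaf,
    replace = hp$bootstrap,
    sample.fraction = 1,
    class.weights = balanced_class_weights(y)[LIFESTYLES],
    importance = "impurity",
    seed = seed,
    num.threads = 1
  )
  structure(
    list(
      forest = forest,
      domain_set = colnames(x),
      hyperparameters = hp,
      seed = as.integer(seed),
      n_train = nrow(x),
      class_counts = as.integer(table(y)[LIFESTYLES]),
      training_fingerprint = rlang::hash(list(x, as.character(y))),
      format_version = MODEL_FORMAT_VERSION
    ),
    class = "lifestyle_model"
  )
}

#' @export
print.lifestyle_model <- function(x, ...) {
  cat(sprintf(
    "<lifestyle_model> %d domains, trained on %d genomes (%d virulent, %d temperate)\n",
    length(x$domain_set), x$n_train, x$class_counts[1], x$class_counts[2]
  ))
  cat(sprintf(
    "  trees=%d depth<=%d min_leaf=%d bootstrap=%s class_weight=%s seed=%d\n",
    x$hyperparameters$n_estimators, x$hyperparameters$max_depth,
    x$hyperparameters$min_samples_leaf, x$hyperparameters$bootstrap,
    x$hyperparameters$class_weight, x$seed
  ))
  cat(sprintf("  fingerprint %s\n", x$training_fingerprint))
  invisible(x)
}

# Call rule: temperate only on positive evidence (p_temperate > 0.5);
# a tie is called virulent, matching the prior that an input genome is a
# complete virulent phage until domain evidence overrides it.
lifestyle_call <- function(p_temperate) {
  ifelse(p_temperate > 0.5, "temperate", "virulent")
}

annotate_predictions <- function(genome_id, p_temperate, confidence_threshold) {
  tibble(
    genome_id = genome_id,
    p_virulent = 1 - p_temperate,
    p_temperate = p_temperate,
    call = lifestyle_call(p_temperate),
    confident = pmax(p_temperate, 1 - p_temperate) >= confidence_threshold
  )
}

#' Predict phage lifestyle from presence/absence vectors
#'
#' Applies a fitted lifestyle model to a wide presence table. Class
#' probabilities always sum to 1; the call is `"temperate"` only when
#' `p_temperate > 0.5` (a tie is called virulent), and a prediction is
#' flagged `confident` when the larger probability is at or above
#' `confidence_threshold`.
#'
#' @param object A `lifestyle_model`.
#' @param newdata A tibble with column `genome_id` plus exactly the 0/1
#'   domain columns the model was trained on (extra non-feature columns
#'   `lifestyle` is tolerated and ignored).
#' @param confidence_threshold Inclusive probability threshold for the
#'   `confident` flag (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `genome_id`, `p_virulent`, `p_temperate`,
#'   `call`, `confident`.
#' @export
predict.lifestyle_model <- function(object, newdata,
                                    confidence_threshold = 0.95, ...) {
  stopifnot(is.data.frame(newdata), "genome_id" %in% names(newdata))
  feats <- setdiff(names(newdata), c("genome_id", "lifestyle"))
  if (length(feats) != length(object$domain_set) ||
      !setequal(feats, object$domain_set)) {
    abort(sprintf(
      "feature mismatch: model expects %d domain columns, received %d matching",
      length(object$domain_set), length(intersect(feats, object$domain_set))
    ))
  }
  x <- newdata[object$domain_set]
  check_binary_features(x)
  pr <- predict(
    object$forest, data = as.data.frame(x), num.threads = 1
  )$predictions
  annotate_predictions(
    newdata$genome_id, pr[, "temperate"], confidence_threshold
  )
}

#' Persist and restore a lifestyle model
#'
#' The model file is a single serialized artifact embedding the trained
#' forest, the ordered domain set, hyperparameters, seed, fingerprint and
#' a format-version tag; loading verifies the tag and fails loudly on
#' corrupt or incompatible files. Round-tripping preserves predictions
#' exactly.
#'
#' @param model A `lifestyle_model`.
#' @param path File path for the model artifact.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `lifestyle_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lifestyle_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("model file not found: '%s'", path))
  }
  model <- tryCatch(
    readRDS(path),
    error = function(e) {
      abort(sprintf("cannot read model file '%s': %s", path, conditionMessage(e)))
    }
  )
  if (!inherits(model, "lifestyle_model")) {
    abort(sprintf("'%s' is not a lifestyle model artifact", path))
  }
  if (!identical(model$format_version, MODEL_FORMAT_VERSION)) {
    abort(sprintf(
      "model format version '%s' is not supported (expected '%s')",
      model$format_version %||% "<missing>", MODEL_FORMAT_VERSION
    ))
  }
  model
}

#' Feature importances of a fitted lifestyle model
#'
#' `tidy()` returns one row per domain in descending impurity-importance
#' order, with importances normalized to sum to 1 and a cumulative-share
#' column (so e.g. the share of total importance carried by the top 20 or
#' top 50 domains can be read off directly). `glance()` returns a one-row
#' model summary.
#'
#' @param x A `lifestyle_model`.
#' @param ... Unused.
#' @return For `tidy()`: a tibble with columns `accession`, `importance`,
#'   `rank`, `cumulative_share`. For `glance()`: a one-row tibble of
#'   training metadata.
#' @method tidy lifestyle_model
#' @export
tidy.lifestyle_model <- function(x, ...) {
  imp <- ranger::importance(x$forest)
  total <- sum(imp)
  share <- if (total > 0) imp / total else imp
  ord <- order(share, decreasing = TRUE)
  tibble(
    accession = names(imp)[ord],
    importance = unname(share[ord]),
    rank = seq_along(imp),
    cumulative_share = cumsum(unname(share[ord]))
  )
}

#' @rdname tidy.lifestyle_model
#' @method glance lifestyle_model
#' @export
glance.lifestyle_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      n_domains = length(x$domain_set),
      n_train = x$n_train,
      n_virulent = x$class_counts[1],
      n_temperate = x$class_counts[2],
      seed = x$seed,
      fingerprint = x$training_fingerprint
    ),
    x$hyperparameters
  )
}

#' @rdname tidy.lifestyle_model
#' @export
feature_importances <- function(x) {
  tidy.lifestyle_model(x)
}
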