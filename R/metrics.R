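#' Confusion matrix for lifestyle predictions
#'
#' Builds the 2x2 confusion matrix with true classes in rows and
#' predicted classes in columns, both in the fixed order (virulent,
#' temperate). `as_confusion_matrix()` coerces an existing 2x2 count
#' matrix (e.g. transcribed from a report) into the same classed object.
#'
#' @param truth,estimate Equal-length vectors of lifestyle labels
#'   (`"virulent"` / `"temperate"`).
#' @return A `confusion_matrix` (an integer matrix with dimnames
#'   `true`/`predicted`).
#' @export
confusion_matrix <- function(truth, estimate) {
  truth <- as_lifestyle(truth, "truth")
  estimate <- as_lifestyle(estimate, "estimate")
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length")
  }
  m <- table(true = truth, predicted = estimate)
  as_confusion_matrix(unclass(m))
}

#' @rdname confusion_matrix
#' @param counts A 2x2 non-negative count matrix, rows = true classes
#'   (virulent, temperate), columns = predicted classes in the same order.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("`counts` must be a 2x2 matrix of non-negative integers")
  }
  m <- matrix(
    as.integer(counts), 2, 2,
    dimnames = list(true = LIFESTYLES, predicted = LIFESTYLES)
  )
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Performance metrics from a confusion matrix
#'
#' Computes the four reported performance measures for the binary
#' lifestyle task, with **temperate as the positive class** throughout
#' (this is the convention under which the published scores for
#' domain-presence classifiers are recovered from their confusion
#' matrices):
#'
#' * `accuracy` — trace / total.
#' * `balanced_accuracy` — *adjusted* balanced accuracy: the mean of
#'   temperate recall (sensitivity) and virulent recall (specificity),
#'   rescaled as `(mean - 0.5) / 0.5` so random guessing scores 0 and a
#'   perfect model scores 1.
#' * `mcc` — Matthews correlation coefficient by the standard 2x2
#'   formula, defined as 0 when any marginal is zero.
#' * `f1` — `2 TP / (2 TP + FP + FN)` with TP = temperate predicted
#'   temperate.
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble: `accuracy`, `balanced_accuracy`, `mcc`,
#'   `f1`, `n`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  if (n == 0) {
    abort("confusion matrix is empty")
  }
  tp <- cm["temperate", "temperate"]
  tn <- cm["virulent", "virulent"]
  fp <- cm["virulent", "temperate"]
  fn <- cm["temperate", "virulent"]
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  tibble(
    accuracy = (tp + tn) / n,
    balanced_accuracy = (mean(c(sens, spec)) - 0.5) / 0.5,
    mcc = mcc,
    f1 = f1,
    n = as.integer(n)
  )
}

#' Confidence-stratified prediction accuracy
#'
#' Splits predictions into a confident stratum (larger class probability
#' at or above `threshold`) and an uncertain stratum, and reports per
#' stratum the number of genomes, errors, percent correct, and percent of
#' the total — the basis for recommending that downstream analyses be
#' restricted to confident calls.
#'
#' @param predictions Prediction tibble from [predict.lifestyle_model()]
#'   (columns `genome_id`, `p_temperate`, `call`).
#' @param truth Data frame with columns `genome_id` and `lifestyle`, or a
#'   label vector aligned to `predictions` rows.
#' @param threshold Inclusive confidence threshold (default 0.95);
#'   `threshold = 0` puts everything in the confident stratum.
#' @return A tibble with one row per stratum: `stratum`, `n`, `n_errors`,
#'   `percent_correct`, `percent_of_total` (percentages to 1 decimal).
#' @export
confidence_strata <- function(predictions, truth, threshold = 0.95) {
  if (is.data.frame(truth)) {
    missing <- setdiff(predictions$genome_id, truth$genome_id)
    if (length(missing) > 0) {
      abort(sprintf(
        "no true label for genome(s): %s", paste(missing, collapse = ", ")
      ))
    }
    truth <- truth$lifestyle[match(predictions$genome_id, truth$genome_id)]
  }
  truth <- as_lifestyle(truth, "truth")
  if (length(truth) != nrow(predictions)) {
    abort("`truth` must provide one label per prediction")
  }
  p_max <- pmax(predictions$p_temperate, 1 - predictions$p_temperate)
  confident <- p_max >= threshold
  correct <- predictions$call == as.character(truth)
  one_stratum <- function(sel, name) {
    tibble(
      stratum = name,
      n = sum(sel),
      n_errors = sum(sel & !correct),
      percent_correct = if (sum(sel) > 0) {
        round(100 * sum(sel & correct) / sum(sel), 1)
      } else {
        NA_real_
      },
      percent_of_total = round(100 * sum(sel) / length(sel), 1)
    )
  }
  dplyr::bind_rows(
    one_stratum(confident, "confident"),
    one_stratum(!confident, "uncertain")
  )
}
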