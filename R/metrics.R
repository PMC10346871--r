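#' Multiclass confusion matrix
#'
#' Counts with rows indexed by the true class and columns by the predicted
#' class.  Labels may be integers indexing `class_names` or the class names
#' themselves; anything outside `class_names` is rejected.
#'
#' @param true,predicted Equal-length label vectors.
#' @param class_names Ordered class labels fixing the matrix dimensions.
#' @return A `C x C` integer matrix of class `"confusion_matrix"` with
#'   `class_names` as dimnames.
#' @export
confusion_matrix <- function(true, predicted, class_names) {
  if (length(true) != length(predicted))
    stop("label vectors differ in length")
  to_idx <- function(v, what) {
    if (is.numeric(v)) {
      v <- as.integer(v)
      if (any(v < 1L | v > length(class_names)))
        stop(what, " labels outside 1..", length(class_names))
      v
    } else {
      i <- match(as.character(v), class_names)
      if (anyNA(i))
        stop(what, " label '", as.character(v)[which(is.na(i))[1L]],
             "' not in class_names")
      i
    }
  }
  ti <- to_idx(true, "true"); pi <- to_idx(predicted, "predicted")
  k <- length(class_names)
  m <- matrix(0L, k, k, dimnames = list(true = class_names,
                                        predicted = class_names))
  for (i in seq_along(ti)) m[ti[i], pi[i]] <- m[ti[i], pi[i]] + 1L
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Overall multiclass accuracy
#'
#' Fraction of correctly classified samples: the trace of the confusion
#' matrix over its total.  For a 2x2 diagonal-dominant matrix this is the
#' usual (TP + TN) / (TP + TN + FP + FN).
#'
#' @param cm A [confusion_matrix()].
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

#' Per-class precision and recall (one-vs-rest)
#'
#' For class i, precision is `TP / (TP + FP)` (the class's column) and recall
#' is `TP / (TP + FN)` (the class's row).  A zero denominator yields 0 with a
#' logical `"undefined"` attribute flagging the affected classes.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector over all classes, with attribute
#'   `"undefined"`.
#' @export
per_class_precision <- function(cm) {
  tp <- diag(cm); denom <- colSums(cm)
  out <- ifelse(denom == 0, 0, tp / denom)
  names(out) <- colnames(cm)
  attr(out, "undefined") <- denom == 0
  out
}

#' @rdname per_class_precision
#' @export
per_class_recall <- function(cm) {
  tp <- diag(cm); denom <- rowSums(cm)
  out <- ifelse(denom == 0, 0, tp / denom)
  names(out) <- rownames(cm)
  attr(out, "undefined") <- denom == 0
  out
}

#' Macro-averaged precision
#'
#' Unweighted arithmetic mean of per-class precision values (any scale; the
#' published comparison tables use percentages).
#'
#' @param per_class Non-empty numeric vector of per-class precisions.
#' @return Their mean.
#' @export
#' @examples
#' macro_precision(c(99.2, 99.2, 99.8, 93.4, 95.8, 100))
macro_precision <- function(per_class) {
  if (length(per_class) == 0L) stop("empty precision vector")
  mean(as.numeric(per_class))
}

#' Feature reduction ratio
#'
#' Percentage of features eliminated by a selection:
#' `100 * (1 - subset_size / t_size)`.
#'
#' @param subset_size Number of selected features (> 0).
#' @param t_size Total number of features (>= subset_size).
#' @return Percentage in \[0, 100).
#' @export
#' @examples
#' reduction_ratio(265, 561)  # the published 52.7% reduction
reduction_ratio <- function(subset_size, t_size) {
  stopifnot(t_size >= 1)
  if (subset_size < 1 || subset_size > t_size)
    stop("subset_size must lie in 1..t_size")
  100 * (1 - subset_size / t_size)
}

#' Aggregate repeated optimizer runs
#'
#' Best/average/standard deviation of per-run best costs, the convention
#' used to compare stochastic optimizers over repeated runs.  The standard
#' deviation uses the sample (n - 1) convention and is 0 for a single run.
#'
#' @param costs Per-run best fitness values (non-empty).
#' @param accuracies Optional per-run accuracies, same length.
#' @return A list of class `"run_aggregate"`: `best_cost`, `avg_cost`,
#'   `std_cost`, `run_count`, `mean_accuracy` (NA when no accuracies given).
#' @export
aggregate_runs <- function(costs, accuracies = NULL) {
  if (length(costs) == 0L) stop("no runs to aggregate")
  if (!is.null(accuracies) && length(accuracies) != length(costs))
    stop("accuracies must match costs in length")
  structure(list(best_cost = min(costs),
                 avg_cost = mean(costs),
                 std_cost = if (length(costs) > 1L) stats::sd(costs) else 0,
                 run_count = length(costs),
                 mean_accuracy = if (is.null(accuracies)) NA_real_
                                 else mean(accuracies)),
            class = "run_aggregate")
}

#' @export
print.run_aggregate <- function(x, ...) {
  cat(sprintf("%d runs: best cost %.6g, avg %.6g, std %.6g",
              x$run_count, x$best_cost, x$avg_cost, x$std_cost))
  if (!is.na(x$mean_accuracy))
    cat(sprintf(", mean accuracy %.4f", x$mean_accuracy))
  cat("\n")
  invisible(x)
}

# Truncate (not round) to d decimals -- display convention of the published
# comparison tables (52.763 -> 52.7, 97.666 -> 97.66).
trunc_dec <- function(x, d) trunc(x * 10^d) / 10^d

#' Evaluate a feature mask on the test partition
#'
#' Trains the classifier on the training partition restricted to the mask's
#' columns, predicts the test partition, and assembles the full report:
#' confusion matrix, accuracy, per-class precision/recall, macro precision,
#' subset size and reduction ratio.
#'
#' @param mask Integer 0/1 vector (or a path to a file with one bit per
#'   line).
#' @param dataset A [feature_dataset()].
#' @param classifier A [classifier_spec()].
#' @return An object of class `"evaluation_report"`.
#' @export
evaluation_report <- function(mask, dataset, classifier = classifier_spec()) {
  if (is.character(mask) && length(mask) == 1L)
    mask <- as.integer(trimws(readLines(mask)))
  mask <- assert_mask(mask)
  stopifnot(inherits(dataset, "feature_dataset"))
  if (length(mask) != ncol(dataset$train_x))
    stop("mask length ", length(mask), " does not match the ",
         ncol(dataset$train_x), " features")
  adapter <- classifier_adapter(classifier)
  cols <- which(mask == 1L)
  model <- adapter$fit(dataset$train_x[, cols, drop = FALSE],
                       dataset$train_y)
  pred <- adapter$predict(model, dataset$test_x[, cols, drop = FALSE])
  cm <- confusion_matrix(dataset$test_y, pred, dataset$class_names)
  prec <- per_class_precision(cm)
  structure(list(accuracy = accuracy(cm),
                 per_class_precision = prec,
                 per_class_recall = per_class_recall(cm),
                 macro_precision = macro_precision(prec),
                 subset_size = sum(mask),
                 t_size = length(mask),
                 reduction_ratio = reduction_ratio(sum(mask), length(mask)),
                 confusion = cm),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.4f  (macro precision %.1f%%)\n",
              x$accuracy, trunc_dec(100 * x$macro_precision, 1)))
  cat(sprintf("Selected %d of %d features (reduction ratio %.1f%%)\n",
              x$subset_size, x$t_size, trunc_dec(x$reduction_ratio, 1)))
  cat("Confusion matrix (rows = true):\n")
  print(unclass(x$confusion))
  invisible(x)
}
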