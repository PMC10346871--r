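#' Classification error of a feature subset
#'
#' Trains the configured classifier on the training partition restricted to
#' the mask's selected columns and returns the misclassification fraction on
#' the evaluation partition chosen by `protocol` (see [fitness_spec()] for
#' the protocols).  The validation split and fold assignment are
#' deterministic functions of the dataset, so repeated calls with the same
#' arguments return the same value.
#'
#' @param mask Integer 0/1 vector with at least one set bit.
#' @param dataset A [feature_dataset()].
#' @param classifier A [classifier_spec()].
#' @param protocol `"holdout-test"`, `"validation-split"` or `"k-fold"`.
#' @param validation_fraction Held-out share of the training partition under
#'   `"validation-split"`.
#' @param folds Fold count under `"k-fold"`.
#' @return Error rate in \[0, 1\].
#' @export
classifier_error <- function(mask, dataset, classifier = classifier_spec(),
                             protocol = c("holdout-test", "validation-split",
                                          "k-fold"),
                             validation_fraction = 0.2, folds = 5L) {
  protocol <- match.arg(protocol)
  mask <- assert_mask(mask)
  stopifnot(inherits(dataset, "feature_dataset"))
  if (length(mask) != ncol(dataset$train_x))
    stop("mask length ", length(mask), " does not match the ",
         ncol(dataset$train_x), " features")
  if (sum(mask) == 0L) stop("empty mask: no features selected")
  adapter <- classifier_adapter(classifier)
  cols <- which(mask == 1L)

  if (protocol == "holdout-test") {
    model <- adapter$fit(dataset$train_x[, cols, drop = FALSE],
                         dataset$train_y)
    pred <- adapter$predict(model, dataset$test_x[, cols, drop = FALSE])
    return(mean(pred != dataset$test_y))
  }

  if (protocol == "validation-split") {
    fit_idx <- stratified_split(dataset$train_y, 1 - validation_fraction)
    val_idx <- setdiff(seq_along(dataset$train_y), fit_idx)
    model <- adapter$fit(dataset$train_x[fit_idx, cols, drop = FALSE],
                         dataset$train_y[fit_idx])
    pred <- adapter$predict(model,
                            dataset$train_x[val_idx, cols, drop = FALSE])
    return(mean(pred != dataset$train_y[val_idx]))
  }

  # k-fold: cyclic fold assignment within each class, in data order
  y <- dataset$train_y
  fold_of <- integer(length(y))
  for (cl in sort(unique(y))) {
    rows <- which(y == cl)
    fold_of[rows] <- rep_len(seq_len(folds), length(rows))
  }
  if (classifier$kind == "knn")
    return(knn_cv_error(dataset$train_x[, cols, drop = FALSE], y, fold_of,
                        classifier))
  wrong <- 0L
  for (f in seq_len(folds)) {
    hold <- which(fold_of == f)
    if (length(hold) == 0L) next
    model <- adapter$fit(dataset$train_x[-hold, cols, drop = FALSE],
                         y[-hold])
    pred <- adapter$predict(model,
                            dataset$train_x[hold, cols, drop = FALSE])
    wrong <- wrong + sum(pred != y[hold])
  }
  wrong / length(y)
}

# Cross-validated native-KNN error sharing one pairwise distance matrix
# across folds. Identical predictions to fold-wise knn_predict (same metric,
# same stable tie-breaking); only the distance computation is shared.
knn_cv_error <- function(x, y, fold_of, classifier) {
  dmat <- pairwise_dist(x, x, classifier$metric, classifier$p)
  n <- length(y)
  wrong <- 0L
  for (f in sort(unique(fold_of))) {
    hold <- which(fold_of == f)
    keep <- which(fold_of != f)
    if (classifier$k > length(keep))
      stop("k = ", classifier$k, " exceeds the ", length(keep),
           " training rows of a fold")
    pred <- knn_classify_dmat(dmat[hold, keep, drop = FALSE], y[keep],
                              classifier$k)
    wrong <- wrong + sum(pred != y[hold])
  }
  wrong / n
}

#' Build the wrapper fitness function for an optimizer run
#'
#' Returns a closure scoring a mask as
#' `a * epsilon + (1 - a) * s_size / t_size`.  When caching is enabled the
#' classifier error `epsilon` is memoized by mask bits; the fitness value is
#' always recomputed from the cached error, so caching never changes a
#' returned value (only the number of classifier fits), including in the
#' random-`a` mode where a fresh `a ~ U(0, 1)` is drawn per evaluation.
#'
#' @param dataset A [feature_dataset()].
#' @param spec A [fitness_spec()].
#' @return A function `mask -> list(fitness, epsilon, s_size, t_size, a)`.
#'   The closure carries attributes-free state; inspect cache usage with the
#'   `"n_fits"` element of `environment(fn)$stats_env`.
#' @export
make_fitness <- function(dataset, spec = fitness_spec()) {
  stopifnot(inherits(dataset, "feature_dataset"),
            inherits(spec, "fitness_spec"))
  t_size <- ncol(dataset$train_x)
  cache <- new.env(parent = emptyenv())
  stats_env <- new.env(parent = emptyenv())
  stats_env$n_fits <- 0L
  stats_env$n_calls <- 0L

  function(mask) {
    mask <- assert_mask(mask)
    stats_env$n_calls <- stats_env$n_calls + 1L
    key <- paste(mask, collapse = "")
    eps <- if (spec$cache) cache[[key]] else NULL
    if (is.null(eps)) {
      eps <- classifier_error(mask, dataset, spec$classifier, spec$protocol,
                              spec$validation_fraction, spec$folds)
      stats_env$n_fits <- stats_env$n_fits + 1L
      if (spec$cache) cache[[key]] <- eps
    }
    a <- if (spec$a_mode == "random") stats::runif(1L) else spec$a
    s_size <- sum(mask)
    list(fitness = a * eps + (1 - a) * s_size / t_size,
         epsilon = eps, s_size = s_size, t_size = t_size, a = a)
  }
}

#' Score one mask with the wrapper objective
#'
#' One-shot convenience around [make_fitness()].
#'
#' @inheritParams make_fitness
#' @param mask Integer 0/1 vector.
#' @return A list: `fitness`, `epsilon`, `s_size`, `t_size`, `a`.
#' @export
#' @examples
#' syn <- generate_synthetic(n_classes = 3, n_per_class = 20,
#'                           n_informative = 3, n_redundant = 0,
#'                           n_noise = 3, seed = 1)
#' fitness_eval(rep(1L, 6), syn$dataset)
fitness_eval <- function(mask, dataset, spec = fitness_spec()) {
  make_fitness(dataset, spec)(mask)
}
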