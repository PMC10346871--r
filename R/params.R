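#' Parameters of the COVIDOA population stage
#'
#' Bundles and validates the knobs of the coronavirus-replication population
#' loop: population size, iteration budget, the number of frameshifted protein
#' copies produced per replication (`nop`), the per-position mutation rate
#' (`mr`), the problem dimension `d` (number of candidate features), and the
#' bounds `lb`/`ub` of the real-valued seeding vectors that are binarized to
#' form the initial population.
#'
#' @param n_pop Population size (positive integer). Default 20.
#' @param max_iter Number of generations (non-negative integer). Default 50.
#' @param nop Number of proteins generated per replication (positive integer).
#'   Default 2.
#' @param mr Mutation rate, the probability that a position of an offspring is
#'   replaced by a fresh random bit. Must lie in \[0.005, 0.5\]. Default 0.1.
#' @param d Problem dimension: the number of features a mask covers.
#' @param lb,ub Lower and upper bound of the uniform real-valued seeding
#'   vectors (used only to build the initial population). Defaults -1 and 1.
#'
#' @return An object of class `"covidoa_params"` (a validated list).
#' @seealso [sa_params()], [covid_sa()]
#' @export
#' @examples
#' covidoa_params(d = 10)
covidoa_params <- function(n_pop = 20L, max_iter = 50L, nop = 2L, mr = 0.1,
                           d, lb = -1, ub = 1) {
  n_pop <- as.integer(n_pop); max_iter <- as.integer(max_iter)
  nop <- as.integer(nop); d <- as.integer(d)
  stopifnot(length(n_pop) == 1L, n_pop >= 1L,
            length(max_iter) == 1L, max_iter >= 0L,
            length(nop) == 1L, nop >= 1L,
            length(d) == 1L, d >= 1L,
            is.numeric(mr), length(mr) == 1L,
            is.numeric(lb), is.numeric(ub), length(lb) == 1L, length(ub) == 1L)
  if (mr < 0.005 || mr > 0.5)
    stop("'mr' must lie in [0.005, 0.5], got ", mr)
  if (!(lb < ub)) stop("'lb' must be strictly less than 'ub'")
  structure(list(n_pop = n_pop, max_iter = max_iter, nop = nop, mr = mr,
                 d = d, lb = lb, ub = ub),
            class = "covidoa_params")
}

#' Parameters of the simulated-annealing refinement stage
#'
#' The geometric cooling schedule: start at temperature `t0`, multiply by the
#' cooling rate `cooling` after every step, stop once the temperature falls to
#' `t_end` or below.  A schedule with `t0 <= t_end` is allowed and runs zero
#' steps (the refinement becomes a no-op), which is occasionally useful to
#' compare the hybrid against the population stage alone.
#'
#' @param t0 Initial temperature (> 0). Default 1.
#' @param t_end Final temperature (> 0). Default 1e-4.
#' @param cooling Cooling rate in (0, 1); the temperature is multiplied by
#'   this factor each step. Default 0.99.
#'
#' @return An object of class `"sa_params"`.
#' @seealso [covidoa_params()], [sa_refine()]
#' @export
sa_params <- function(t0 = 1, t_end = 1e-4, cooling = 0.99) {
  stopifnot(is.numeric(t0), length(t0) == 1L, t0 > 0,
            is.numeric(t_end), length(t_end) == 1L, t_end > 0,
            is.numeric(cooling), length(cooling) == 1L)
  if (cooling <= 0 || cooling >= 1)
    stop("'cooling' must lie strictly between 0 and 1, got ", cooling)
  structure(list(t0 = t0, t_end = t_end, cooling = cooling),
            class = "sa_params")
}

#' Classifier specification for the wrapper objective
#'
#' Describes the classifier used to score feature subsets.  The default is the
#' package's native k-nearest-neighbour classifier with k = 5 and Euclidean
#' distance.  Any other learner can be plugged in through the adapter seam:
#' supply `kind = "adapter"` together with `fit` (a function of a feature
#' matrix and an integer label vector returning a model) and `predict` (a
#' function of that model and a feature matrix returning integer labels).
#'
#' @param kind `"knn"` for the native classifier or `"adapter"`.
#' @param k Number of neighbours (positive integer, at most the number of
#'   training rows at evaluation time). Default 5.
#' @param metric Distance: `"euclidean"`, `"manhattan"` or `"minkowski"`.
#' @param p Minkowski exponent (used only when `metric = "minkowski"`).
#' @param fit,predict Adapter functions, see Details.
#'
#' @return An object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(kind = c("knn", "adapter"), k = 5L,
                            metric = c("euclidean", "manhattan", "minkowski"),
                            p = 3, fit = NULL, predict = NULL) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L, is.numeric(p), length(p) == 1L, p >= 1)
  if (kind == "adapter") {
    if (!is.function(fit) || !is.function(predict))
      stop("adapter classifiers need both 'fit' and 'predict' functions")
  }
  structure(list(kind = kind, k = k, metric = metric, p = p,
                 fit = fit, predict = predict),
            class = "classifier_spec")
}

#' Wrapper-fitness specification
#'
#' The wrapper objective scores a mask as
#' `a * epsilon + (1 - a) * s_size / t_size`, where `epsilon` is the
#' classification error of the selected columns, `s_size` the number of
#' selected features and `t_size` the total number of features.  `a` close to
#' 1 makes the error dominate; the remaining weight penalizes large subsets.
#'
#' `a_mode = "random"` redraws `a` uniformly on \[0, 1\] at every evaluation.
#' That variant makes the objective non-stationary — two evaluations of the
#' same mask return different values — so candidate ranking becomes noise
#' dominated; the stationary default `a = 0.99` is recommended and is what all
#' package defaults use.
#'
#' @param a Error weight in \[0, 1\] (used when `a_mode = "fixed"`).
#'   Default 0.99.
#' @param a_mode `"fixed"` or `"random"` (a fresh uniform `a` per evaluation).
#' @param classifier A [classifier_spec()].
#' @param protocol How the error is estimated: `"holdout-test"` trains on the
#'   training partition and measures error on the test partition;
#'   `"validation-split"` carves a stratified validation set out of the
#'   training partition (leakage-free, recommended when the test partition
#'   must stay untouched); `"k-fold"` averages stratified cross-validation
#'   folds within the training partition.
#' @param validation_fraction Fraction of the training partition held out
#'   under `"validation-split"`. Default 0.2.
#' @param folds Number of folds under `"k-fold"`. Default 5.
#' @param cache Cache classifier-error values by mask? The cache stores the
#'   error rate only, so it never changes a returned fitness value — including
#'   under `a_mode = "random"` — only the number of classifier fits.
#'
#' @return An object of class `"fitness_spec"`.
#' @export
fitness_spec <- function(a = 0.99, a_mode = c("fixed", "random"),
                         classifier = classifier_spec(),
                         protocol = c("holdout-test", "validation-split",
                                      "k-fold"),
                         validation_fraction = 0.2, folds = 5L,
                         cache = TRUE) {
  a_mode <- match.arg(a_mode)
  protocol <- match.arg(protocol)
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0, a <= 1,
            inherits(classifier, "classifier_spec"),
            is.numeric(validation_fraction), validation_fraction > 0,
            validation_fraction < 1,
            is.logical(cache), length(cache) == 1L)
  folds <- as.integer(folds)
  stopifnot(folds >= 2L)
  structure(list(a = a, a_mode = a_mode, classifier = classifier,
                 protocol = protocol,
                 validation_fraction = validation_fraction,
                 folds = folds, cache = cache),
            class = "fitness_spec")
}

# Shared mask helpers ---------------------------------------------------------

assert_mask <- function(mask) {
  if (!is.numeric(mask) && !is.integer(mask))
    stop("mask must be a numeric 0/1 vector")
  if (length(mask) == 0L || !all(mask %in% c(0L, 1L)))
    stop("mask entries must all be 0 or 1")
  invisible(as.integer(mask))
}

#' Repair an empty feature mask
#'
#' The wrapper objective is undefined on a mask with no selected features, so
#' every operator that could produce the all-zero mask routes its output
#' through this repair: a single uniformly chosen bit is set.
#'
#' @param mask Integer 0/1 vector.
#' @return The mask, with one random bit set if it had none.
#' @export
repair_mask <- function(mask) {
  mask <- assert_mask(mask)
  if (sum(mask) == 0L) mask[sample.int(length(mask), 1L)] <- 1L
  mask
}
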