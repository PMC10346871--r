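#' Hybrid coronavirus-optimization / simulated-annealing feature selection
#'
#' Fits a feature-subset model to a train/test dataset: the COVIDOA
#' population stage searches the space of bit masks with the wrapper
#' objective `a * error + (1 - a) * subset/total`, and the optimum it reaches
#' seeds a simulated-annealing refinement pass that polishes it with
#' single-bit moves.  The default classifier behind the objective is the
#' native 5-nearest-neighbour classifier with Euclidean distance.
#'
#' @param dataset A [feature_dataset()] (from [load_ucihar()], [load_csv()]
#'   or [generate_synthetic()]).
#' @param covidoa A [covidoa_params()]; when `NULL`, defaults with
#'   `d = ncol(dataset$train_x)`.
#' @param sa A [sa_params()].
#' @param fitness A [fitness_spec()].
#' @param seed Optional integer seed.  The same seed, dataset and
#'   configuration reproduce the entire result bit for bit.  Because the
#'   population stage runs first on the seeded stream, a run with an empty
#'   annealing schedule shares its population stage with the full hybrid at
#'   the same seed.
#' @return An object of class `"covid_sa"` with components `best` (bits,
#'   fitness, epsilon, s_size), `covidoa_trace`, `sa_trace`,
#'   `covidoa_stage_best`, `seed`, `config` (echo of all parameters),
#'   `dataset`, `n_fits` (classifier fits performed).  Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`.
#' @seealso [covid_sa_runs()] for repeated-run aggregation.
#' @export
#' @examples
#' syn <- generate_synthetic(n_classes = 3, n_per_class = 20,
#'                           n_informative = 3, n_redundant = 2,
#'                           n_noise = 3, seed = 7)
#' fit <- covid_sa(syn$dataset,
#'                 covidoa = covidoa_params(n_pop = 10, max_iter = 5, d = 8),
#'                 sa = sa_params(t0 = 0.1, t_end = 0.01), seed = 1)
#' fit
#' coef(fit)
covid_sa <- function(dataset, covidoa = NULL, sa = sa_params(),
                     fitness = fitness_spec(), seed = NULL) {
  stopifnot(inherits(dataset, "feature_dataset"))
  d <- ncol(dataset$train_x)
  if (is.null(covidoa)) covidoa <- covidoa_params(d = d)
  stopifnot(inherits(covidoa, "covidoa_params"), inherits(sa, "sa_params"),
            inherits(fitness, "fitness_spec"))
  if (covidoa$d != d)
    stop("covidoa$d = ", covidoa$d, " but the dataset has ", d, " features")
  if (!is.null(seed)) set.seed(seed)

  fn <- make_fitness(dataset, fitness)
  res <- hybrid_run(covidoa, sa, fn)

  structure(list(best = res$best,
                 covidoa_trace = res$covidoa_trace,
                 sa_trace = res$sa_trace,
                 covidoa_stage_best = res$covidoa_stage_best,
                 seed = seed,
                 config = list(covidoa = covidoa, sa = sa,
                               fitness = fitness),
                 dataset = dataset,
                 n_fits = environment(fn)$stats_env$n_fits,
                 n_evals = environment(fn)$stats_env$n_calls),
            class = "covid_sa")
}

#' @export
print.covid_sa <- function(x, ...) {
  cat("Hybrid COVIDOA-SA feature selection\n")
  cat(sprintf("  best fitness  : %.6f (classifier error %.4f)\n",
              x$best$fitness, x$best$epsilon))
  cat(sprintf("  selected      : %d of %d features (reduction %.1f%%)\n",
              x$best$s_size, length(x$best$bits),
              trunc_dec(reduction_ratio(x$best$s_size,
                                        length(x$best$bits)), 1)))
  cat(sprintf("  stage optimum : %.6f before annealing, %.6f after\n",
              x$covidoa_stage_best, x$best$fitness))
  if (!is.null(x$seed)) cat("  seed          :", x$seed, "\n")
  invisible(x)
}

#' @export
coef.covid_sa <- function(object, ...) {
  stats::setNames(object$best$bits, object$dataset$feature_names)
}

#' Names of the selected features
#' @param object A fitted [covid_sa()] object.
#' @return Character vector of selected feature names.
#' @export
selected_features <- function(object) {
  stopifnot(inherits(object, "covid_sa"))
  object$dataset$feature_names[object$best$bits == 1L]
}

#' @export
summary.covid_sa <- function(object, ...) {
  rep <- evaluation_report(object$best$bits, object$dataset,
                           object$config$fitness$classifier)
  structure(list(fit = object, report = rep), class = "summary.covid_sa")
}

#' @export
print.summary.covid_sa <- function(x, ...) {
  print(x$fit)
  cat("\nTest-partition evaluation of the selected subset:\n")
  print(x$report)
  invisible(x)
}

#' Predict class labels with the selected feature subset
#'
#' Trains the configured classifier on the training partition restricted to
#' the selected columns and predicts `newdata` (defaulting to the test
#' partition).
#'
#' @param object A fitted [covid_sa()] object.
#' @param newdata Numeric matrix with one column per original feature;
#'   default is the dataset's test partition.
#' @param ... Unused.
#' @return Factor of predicted class names.
#' @export
predict.covid_sa <- function(object, newdata = NULL, ...) {
  ds <- object$dataset
  if (is.null(newdata)) newdata <- ds$test_x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$best$bits))
    stop("newdata must have ", length(object$best$bits), " columns")
  adapter <- classifier_adapter(object$config$fitness$classifier)
  cols <- which(object$best$bits == 1L)
  model <- adapter$fit(ds$train_x[, cols, drop = FALSE], ds$train_y)
  pred <- adapter$predict(model, newdata[, cols, drop = FALSE])
  factor(ds$class_names[pred], levels = ds$class_names)
}

#' Convergence plot of a hybrid run
#'
#' Best-so-far fitness over the concatenated population-stage generations
#' and annealing temperature steps, with the stage boundary marked.
#'
#' @param x A fitted [covid_sa()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.covid_sa <- function(x, ...) {
  tr <- c(x$covidoa_trace, x$sa_trace)
  n1 <- length(x$covidoa_trace)
  graphics::plot(seq_along(tr), tr, type = "s", xlab = "iteration",
                 ylab = "best fitness", main = "Hybrid convergence", ...)
  if (n1 > 0L && length(x$sa_trace) > 0L) {
    graphics::abline(v = n1 + 0.5, lty = 2, col = "grey40")
    graphics::mtext("annealing starts", at = n1 + 0.5, side = 3,
                    cex = 0.8, col = "grey40")
  }
  invisible(x)
}

#' Repeated hybrid runs with best/average/std aggregation
#'
#' Executes `run_count` independent hybrid runs with per-run seeds
#' `seed, seed + 1, ...`, evaluates each selected subset on the test
#' partition, and aggregates the per-run best costs (see
#' [aggregate_runs()]).
#'
#' @inheritParams covid_sa
#' @param run_count Number of runs. Default 20.
#' @param seed Base seed of the first run.
#' @return An object of class `"covid_sa_runs"`: `fits` (list of
#'   [covid_sa()] objects), `aggregate` (a `run_aggregate`), `accuracies`,
#'   `subset_sizes`, `best_run` (index of the lowest-cost run).
#' @export
covid_sa_runs <- function(dataset, run_count = 20L, covidoa = NULL,
                          sa = sa_params(), fitness = fitness_spec(),
                          seed = 1L) {
  run_count <- as.integer(run_count)
  stopifnot(run_count >= 1L)
  fits <- vector("list", run_count)
  for (r in seq_len(run_count)) {
    fits[[r]] <- covid_sa(dataset, covidoa = covidoa, sa = sa,
                          fitness = fitness, seed = seed + r - 1L)
  }
  costs <- vapply(fits, function(f) f$best$fitness, 0)
  accs <- vapply(fits, function(f)
    evaluation_report(f$best$bits, dataset,
                      fits[[1L]]$config$fitness$classifier)$accuracy, 0)
  sizes <- vapply(fits, function(f) f$best$s_size, 0L)
  structure(list(fits = fits,
                 aggregate = aggregate_runs(costs, accs),
                 accuracies = accs,
                 subset_sizes = sizes,
                 best_run = which.min(costs)),
            class = "covid_sa_runs")
}

#' @export
print.covid_sa_runs <- function(x, ...) {
  print(x$aggregate)
  cat(sprintf("mean subset size %.1f of %d features\n",
              mean(x$subset_sizes), length(x$fits[[1L]]$best$bits)))
  invisible(x)
}
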