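# Reproducible run orchestration: config echo, hashing, artifact writing.

#' Assemble a run configuration
#'
#' Bundles a dataset source with optimizer, annealing and fitness parameters
#' plus the repeated-run convention (20 runs by default).  The dataset source
#' is either a ready [feature_dataset()] or a one-element description:
#' `list(type = "ucihar", directory = ...)`,
#' `list(type = "csv", path = ..., label_column = ...)`, or
#' `list(type = "synth", args = list(...))` with arguments for
#' [generate_synthetic()].
#'
#' @param source Dataset source (see Details).
#' @param covidoa A [covidoa_params()] or `NULL` for defaults sized to the
#'   data.
#' @param sa A [sa_params()].
#' @param fitness A [fitness_spec()].
#' @param run_count Number of independent runs. Default 20.
#' @param seed Base seed. Default 1.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(source, covidoa = NULL, sa = sa_params(),
                       fitness = fitness_spec(), run_count = 20L,
                       seed = 1L) {
  run_count <- as.integer(run_count); seed <- as.integer(seed)
  stopifnot(run_count >= 1L)
  ok <- inherits(source, "feature_dataset") ||
    (is.list(source) && !is.null(source$type) &&
       source$type %in% c("ucihar", "csv", "synth"))
  if (!ok)
    stop("invalid dataset source: supply a feature_dataset or a ",
         "list(type = 'ucihar'|'csv'|'synth', ...)")
  structure(list(source = source, covidoa = covidoa, sa = sa,
                 fitness = fitness, run_count = run_count, seed = seed),
            class = "run_config")
}

resolve_source <- function(source) {
  if (inherits(source, "feature_dataset")) return(source)
  switch(source$type,
    ucihar = load_ucihar(source$directory),
    csv = load_csv(source$path,
                   label_column = source$label_column %||% "label"),
    synth = do.call(generate_synthetic, source$args %||% list())$dataset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JSON-serializable echo of the effective configuration (functions dropped).
config_echo <- function(config, d) {
  cv <- config$covidoa %||% covidoa_params(d = d)
  cls <- config$fitness$classifier
  list(covidoa = unclass(cv),
       sa = unclass(config$sa),
       fitness = list(a = config$fitness$a, a_mode = config$fitness$a_mode,
                      protocol = config$fitness$protocol,
                      validation_fraction = config$fitness$validation_fraction,
                      folds = config$fitness$folds,
                      cache = config$fitness$cache,
                      classifier = list(kind = cls$kind, k = cls$k,
                                        metric = cls$metric, p = cls$p)),
       run_count = config$run_count,
       seed = config$seed)
}

#' Hash of an effective configuration
#'
#' MD5 of the canonical JSON serialization of the configuration echo; two
#' runs with equal hashes produce equal machine-readable artifacts.
#'
#' @param echo A configuration echo list (as embedded in run summaries).
#' @return Hex MD5 string.
#' @export
config_hash <- function(echo) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(echo, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Execute a configured selection experiment and write its artifacts
#'
#' Runs `run_count` hybrid selections with per-run seeds derived from the
#' base seed, then writes machine-readable artifacts into `out_dir`:
#' `run_<r>.json` (per-run best mask and fitness breakdown),
#' `trace_run<r>.csv` (two-column convergence trace with a stage marker),
#' `summary.json` (best/avg/std aggregate, config echo and hash), and
#' `evaluation.json` + `confusion.csv` for the best run's mask on the test
#' partition.  No timestamps are written, so identical configurations yield
#' byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose 0 = silent, 1 = per-run progress, 2 = also the per-
#'   iteration best-fitness trace of every run.
#' @return Invisibly, a list with the `covid_sa_runs` object, the evaluation
#'   report and the paths written.
#' @export
run_select <- function(config, out_dir, verbose = 1L) {
  stopifnot(inherits(config, "run_config"))
  dataset <- resolve_source(config$source)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  echo <- config_echo(config, ncol(dataset$train_x))
  hash <- config_hash(echo)

  runs <- covid_sa_runs(dataset, run_count = config$run_count,
                        covidoa = config$covidoa, sa = config$sa,
                        fitness = config$fitness, seed = config$seed)
  paths <- character(0)
  for (r in seq_along(runs$fits)) {
    f <- runs$fits[[r]]
    if (verbose >= 1L)
      message(sprintf("run %d/%d: best fitness %.6f (%d features)",
                      r, config$run_count, f$best$fitness, f$best$s_size))
    if (verbose >= 2L)
      message("  trace: ",
              paste(sprintf("%.6f", c(f$covidoa_trace, f$sa_trace)),
                    collapse = " "))
    p <- file.path(out_dir, sprintf("run_%d.json", r))
    write_json_file(list(seed = f$seed, config_hash = hash,
                         fitness = f$best$fitness,
                         epsilon = f$best$epsilon,
                         s_size = f$best$s_size,
                         t_size = length(f$best$bits),
                         mask = f$best$bits), p)
    tr <- data.frame(
      iteration = seq_len(length(f$covidoa_trace) + length(f$sa_trace)),
      best_fitness = c(f$covidoa_trace, f$sa_trace),
      stage = rep(c("covidoa", "sa"),
                  c(length(f$covidoa_trace), length(f$sa_trace))))
    tp <- file.path(out_dir, sprintf("trace_run%d.csv", r))
    utils::write.csv(tr, tp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p, tp)
  }

  sp <- file.path(out_dir, "summary.json")
  write_json_file(list(config = echo, config_hash = hash,
                       aggregate = unclass(runs$aggregate),
                       subset_sizes = runs$subset_sizes,
                       accuracies = runs$accuracies,
                       best_run = runs$best_run), sp)

  best_fit <- runs$fits[[runs$best_run]]
  report <- write_evaluation_report(best_fit$best$bits, dataset, out_dir,
                                    config$fitness$classifier, hash)
  if (verbose >= 1L)
    message(sprintf("best of %d runs: cost %.6f, test accuracy %.4f",
                    config$run_count, runs$aggregate$best_cost,
                    report$accuracy))
  invisible(list(runs = runs, report = report,
                 paths = c(paths, sp,
                           file.path(out_dir, c("evaluation.json",
                                                "confusion.csv")))))
}

#' Write an evaluation report as JSON plus a confusion-matrix CSV
#'
#' @param mask Integer 0/1 vector or path to a one-bit-per-line mask file.
#' @param dataset A [feature_dataset()].
#' @param out_dir Output directory.
#' @param classifier A [classifier_spec()].
#' @param hash Optional config hash to stamp into the report.
#' @return The [evaluation_report()], invisibly.
#' @export
write_evaluation_report <- function(mask, dataset, out_dir,
                                    classifier = classifier_spec(),
                                    hash = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- evaluation_report(mask, dataset, classifier)
  write_json_file(list(config_hash = hash,
                       accuracy = rep$accuracy,
                       per_class_precision =
                         as.list(stats::setNames(as.numeric(rep$per_class_precision),
                                                 names(rep$per_class_precision))),
                       per_class_recall =
                         as.list(stats::setNames(as.numeric(rep$per_class_recall),
                                                 names(rep$per_class_recall))),
                       macro_precision = rep$macro_precision,
                       subset_size = rep$subset_size,
                       t_size = rep$t_size,
                       reduction_ratio = rep$reduction_ratio),
                  file.path(out_dir, "evaluation.json"))
  utils::write.csv(as.data.frame.matrix(unclass(rep$confusion)),
                   file.path(out_dir, "confusion.csv"))
  invisible(rep)
}

#' Materialize a synthetic dataset on disk
#'
#' Generates a synthetic feature table (see [generate_synthetic()]) and
#' writes it in the UCI-HAR on-disk dialect together with the ground-truth
#' informative mask (`informative_mask.txt`, one bit per line) and the
#' feature names (`feature_names.txt`).
#'
#' @param out_dir Output directory.
#' @param ... Arguments passed to [generate_synthetic()].
#' @return Invisibly, the generated list (`dataset`, `informative_mask`).
#' @export
make_synth <- function(out_dir, ...) {
  syn <- generate_synthetic(...)
  write_ucihar(syn$dataset, out_dir)
  writeLines(as.character(syn$informative_mask),
             file.path(out_dir, "informative_mask.txt"))
  writeLines(syn$dataset$feature_names,
             file.path(out_dir, "feature_names.txt"))
  invisible(syn)
}
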