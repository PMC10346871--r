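# The fitted-model surface: covid_sa() and its methods, repeated runs, and
# the artifact-writing layer.

small_fit <- function(seed = 1L) {
  syn <- generate_synthetic(n_classes = 3L, n_per_class = 20L,
                            n_informative = 3L, n_redundant = 2L,
                            n_noise = 3L, seed = 30)
  fit <- covid_sa(syn$dataset,
                  covidoa = covidoa_params(n_pop = 8L, max_iter = 8L, d = 8L),
                  sa = sa_params(t0 = 0.1, t_end = 0.005),
                  seed = seed)
  list(syn = syn, fit = fit)
}

test_that("the fitted object honours the trace and boundary invariants", {
  sf <- small_fit()
  fit <- sf$fit
  expect_s3_class(fit, "covid_sa")
  expect_true(all(diff(fit$covidoa_trace) <= 0))
  expect_true(all(diff(c(fit$covidoa_trace, fit$sa_trace)) <= 0))
  expect_lte(fit$best$fitness, fit$covidoa_stage_best)
  expect_equal(fit$best$fitness, fit$sa_trace[length(fit$sa_trace)])
  expect_identical(fit$best$s_size, sum(fit$best$bits))
  expect_gte(fit$best$s_size, 1L)

  # same seed, same config: identical result record
  fit2 <- small_fit()$fit
  expect_identical(fit$best, fit2$best)
  expect_identical(fit$sa_trace, fit2$sa_trace)

  expect_error(covid_sa(sf$syn$dataset,
                        covidoa = covidoa_params(d = 5L)), "features")
})

test_that("methods expose coefficients, predictions, summaries and plots", {
  sf <- small_fit()
  fit <- sf$fit

  cf <- coef(fit)
  expect_named(cf, sf$syn$dataset$feature_names)
  expect_true(all(cf %in% 0:1))
  expect_identical(selected_features(fit), names(cf)[cf == 1L])

  pred <- predict(fit)
  expect_s3_class(pred, "factor")
  expect_identical(levels(pred), sf$syn$dataset$class_names)
  expect_length(pred, nrow(sf$syn$dataset$test_x))
  expect_error(predict(fit, matrix(0, 2L, 5L)), "columns")

  s <- summary(fit)
  expect_s3_class(s$report, "evaluation_report")
  expect_gte(s$report$accuracy, 0); expect_lte(s$report$accuracy, 1)
  expect_identical(s$report$subset_size, fit$best$s_size)

  expect_output(print(fit), "best fitness")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("repeated runs aggregate with best <= average", {
  syn <- generate_synthetic(n_classes = 3L, n_per_class = 20L,
                            n_informative = 3L, n_redundant = 2L,
                            n_noise = 3L, seed = 31)
  runs <- covid_sa_runs(syn$dataset, run_count = 3L,
                        covidoa = covidoa_params(n_pop = 8L, max_iter = 6L,
                                                 d = 8L),
                        sa = sa_params(t0 = 0.05, t_end = 0.005),
                        seed = 5L)
  expect_length(runs$fits, 3L)
  expect_lte(runs$aggregate$best_cost, runs$aggregate$avg_cost)
  expect_identical(runs$aggregate$run_count, 3L)
  expect_identical(runs$fits[[2L]]$seed, 6L)
  expect_equal(runs$aggregate$best_cost,
               runs$fits[[runs$best_run]]$best$fitness)
})

test_that("run_select writes reproducible machine-readable artifacts", {
  cfg <- run_config(list(type = "synth",
                         args = list(n_classes = 3L, n_per_class = 20L,
                                     n_informative = 3L, n_redundant = 2L,
                                     n_noise = 3L, seed = 32)),
                    covidoa = covidoa_params(n_pop = 8L, max_iter = 6L,
                                             d = 8L),
                    sa = sa_params(t0 = 0.05, t_end = 0.005),
                    run_count = 2L, seed = 9L)
  d1 <- withr::local_tempdir()
  res <- run_select(cfg, d1, verbose = 0L)

  expect_setequal(list.files(d1),
                  c("run_1.json", "run_2.json", "trace_run1.csv",
                    "trace_run2.csv", "summary.json", "evaluation.json",
                    "confusion.csv"))
  smry <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_lte(smry$aggregate$best_cost, smry$aggregate$avg_cost)
  expect_identical(smry$config$run_count, 2L)
  expect_match(smry$config_hash, "^[0-9a-f]{32}$")
  r1 <- jsonlite::read_json(file.path(d1, "run_1.json"))
  expect_identical(r1$config_hash, smry$config_hash)
  tr <- utils::read.csv(file.path(d1, "trace_run1.csv"))
  expect_identical(names(tr), c("iteration", "best_fitness", "stage"))
  expect_true(all(diff(tr$best_fitness) <= 0))

  # identical config: byte-identical artifacts
  d2 <- withr::local_tempdir()
  run_select(cfg, d2, verbose = 0L)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  expect_error(run_config(list(type = "nope")), "invalid dataset source")
})

test_that("evaluation reports rank masks by their information content", {
  set.seed(33)
  syn <- generate_synthetic(n_classes = 3L, n_per_class = 20L,
                            n_informative = 3L, n_redundant = 0L,
                            n_noise = 5L, class_sep = 8, seed = 34)
  dir <- withr::local_tempdir()
  rep_all <- write_evaluation_report(rep(1L, 8L), syn$dataset, dir)
  expect_true(file.exists(file.path(dir, "evaluation.json")))
  expect_true(file.exists(file.path(dir, "confusion.csv")))
  # strong separation: all features still classify perfectly
  expect_equal(rep_all$accuracy, 1)

  gt <- syn$informative_mask
  rep_gt <- evaluation_report(gt, syn$dataset)
  rep_noise <- evaluation_report(1L - gt, syn$dataset)
  expect_gt(rep_gt$accuracy, rep_noise$accuracy)
  expect_error(evaluation_report(c(1L, 0L), syn$dataset), "match")

  # mask files are accepted in place of vectors
  mf <- file.path(dir, "mask.txt")
  writeLines(as.character(gt), mf)
  expect_equal(evaluation_report(mf, syn$dataset)$accuracy, rep_gt$accuracy)
})
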