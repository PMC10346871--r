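test_that("native KNN agrees with a brute-force oracle", {
  set.seed(101)
  # 100 random small instances across metrics and k
  for (i in 1:100) {
    n <- sample(10:50, 1L)
    d <- sample(2:5, 1L)
    k <- sample(c(1L, 3L, 5L), 1L)
    metric <- sample(c("euclidean", "manhattan", "minkowski"), 1L)
    tx <- matrix(stats::rnorm(n * d), n)
    ty <- sample.int(3L, n, replace = TRUE)
    q <- matrix(stats::rnorm(8L * d), 8L)
    expect_identical(knn_predict(tx, ty, q, k = k, metric = metric),
                     oracle_knn(tx, ty, q, k, metric))
  }
})

test_that("KNN contracts: lone neighbour, majority over proximity, errors", {
  # one training point
  expect_identical(knn_predict(matrix(0, 1, 1), 2L, 5, k = 1L), 2L)
  # two A's at distance 1 beat one B at distance 0.5
  tx <- matrix(c(1, -1, 0.5), ncol = 1)
  expect_identical(knn_predict(tx, c(1L, 1L, 2L), 0, k = 3L), 1L)
  expect_error(knn_predict(matrix(0, 2, 1), 1:2, 0, k = 3L), "exceeds")
  expect_error(knn_predict(matrix(0, 2, 2), 1:2, 0, k = 1L), "columns")
})

test_that("classifier error reflects separation and protocol", {
  set.seed(5)
  ds <- separable_dataset(n_per_class = 12L, d = 3L, gap = 10)
  cls1 <- classifier_spec(k = 1L)
  # perfect separation on the informative feature
  expect_identical(classifier_error(c(1L, 0L, 0L), ds, cls1), 0)
  # memorized points predict themselves
  ds2 <- feature_dataset(ds$train_x, ds$train_y, ds$train_x, ds$train_y)
  expect_identical(classifier_error(rep(1L, 3L), ds2, cls1), 0)
  expect_error(classifier_error(rep(0L, 3L), ds, cls1), "empty mask")
  expect_error(classifier_error(c(1L, 0L), ds, cls1), "match")

  # informative-only vs noise-only masks, paired over 10 generated datasets
  diffs <- vapply(1:10, function(s) {
    syn <- generate_synthetic(n_classes = 3L, n_per_class = 20L,
                              n_informative = 1L, n_redundant = 0L,
                              n_noise = 9L, class_sep = 3, seed = 400 + s)
    m_inf <- syn$informative_mask
    classifier_error(m_inf, syn$dataset) -
      classifier_error(1L - m_inf, syn$dataset)
  }, 0)
  expect_lt(mean(diffs), 0)

  # the three protocols all return values in [0, 1] and are deterministic
  for (pr in c("holdout-test", "validation-split", "k-fold")) {
    e1 <- classifier_error(c(1L, 1L, 0L), ds, cls1, pr)
    e2 <- classifier_error(c(1L, 1L, 0L), ds, cls1, pr)
    expect_identical(e1, e2)
    expect_gte(e1, 0); expect_lte(e1, 1)
  }
})

test_that("wrapper fitness combines error and size penalty", {
  set.seed(6)
  # deterministic stand-in classifier forcing a known error rate via an
  # adapter: predicts class 1 always; test labels are 10% class 2
  ds <- feature_dataset(matrix(stats::rnorm(561 * 4), 4), rep(1:2, 2),
                        matrix(stats::rnorm(561 * 10), 10),
                        c(rep(1L, 9L), 2L))
  const1 <- classifier_spec(kind = "adapter",
                            fit = function(x, y) NULL,
                            predict = function(m, x) rep(1L, nrow(x)))
  mask <- c(rep(1L, 265L), rep(0L, 561L - 265L))

  # a = 1: fitness is the error alone
  fb <- fitness_eval(mask, ds, fitness_spec(a = 1, classifier = const1))
  expect_equal(fb$fitness, 0.1)
  expect_equal(fb$epsilon, 0.1)
  # a = 0: fitness is the size fraction alone
  fb <- fitness_eval(mask, ds, fitness_spec(a = 0, classifier = const1))
  expect_equal(fb$fitness, 265 / 561)
  expect_identical(fb$s_size, 265L)
  # a = 0.99 with error 0.1 and 265 of 561 features
  fb <- fitness_eval(mask, ds, fitness_spec(a = 0.99, classifier = const1))
  expect_equal(fb$fitness, 0.99 * 0.1 + 0.01 * 265 / 561)
  expect_equal(fb$fitness, 0.103724, tolerance = 1e-5)
})

test_that("fitness lies in [0,1] and shrinks with the subset at fixed error", {
  set.seed(9)
  syn <- generate_synthetic(n_classes = 3L, n_per_class = 15L,
                            n_informative = 2L, n_redundant = 2L,
                            n_noise = 4L, seed = 55)
  fn <- make_fitness(syn$dataset)
  for (i in 1:25) {
    m <- repair_mask(sample(0:1, 8L, replace = TRUE))
    fb <- fn(m)
    expect_gte(fb$fitness, 0); expect_lte(fb$fitness, 1)
    expect_identical(fb$s_size, sum(m))
  }
  # at equal error the smaller subset wins for any a < 1
  const0 <- classifier_spec(kind = "adapter",
                            fit = function(x, y) NULL,
                            predict = function(m, x) rep(1L, nrow(x)))
  spec <- fitness_spec(a = 0.9, classifier = const0)
  f_small <- fitness_eval(c(1L, rep(0L, 7L)), syn$dataset, spec)$fitness
  f_large <- fitness_eval(rep(1L, 8L), syn$dataset, spec)$fitness
  expect_lt(f_small, f_large)
})

test_that("the error cache changes call counts, never values", {
  set.seed(10)
  syn <- generate_synthetic(n_classes = 3L, n_per_class = 15L,
                            n_informative = 2L, n_redundant = 0L,
                            n_noise = 4L, seed = 77)
  masks <- replicate(20, repair_mask(sample(0:1, 6L, replace = TRUE)),
                     simplify = FALSE)
  masks <- c(masks, masks)        # repeats exercise the cache

  fn_on <- make_fitness(syn$dataset, fitness_spec(cache = TRUE))
  fn_off <- make_fitness(syn$dataset, fitness_spec(cache = FALSE))
  v_on <- vapply(masks, function(m) fn_on(m)$fitness, 0)
  v_off <- vapply(masks, function(m) fn_off(m)$fitness, 0)
  expect_identical(v_on, v_off)
  expect_lt(environment(fn_on)$stats_env$n_fits,
            environment(fn_off)$stats_env$n_fits)

  # random-a mode: epsilon is stable, the mixing weight varies per call
  fn_r <- make_fitness(syn$dataset, fitness_spec(a_mode = "random"))
  m <- repair_mask(rep(1L, 6L))
  draws <- replicate(20, fn_r(m), simplify = FALSE)
  expect_length(unique(vapply(draws, `[[`, 0, "epsilon")), 1L)
  expect_gt(length(unique(vapply(draws, `[[`, 0, "a"))), 1L)
})
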