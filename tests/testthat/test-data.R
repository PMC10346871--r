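test_that("UCI-HAR layout round-trips through write and load", {
  syn <- generate_synthetic(n_classes = 6L, n_per_class = 4L,
                            n_informative = 4L, n_redundant = 2L,
                            n_noise = 4L, seed = 3)
  dir <- withr::local_tempdir()
  write_ucihar(syn$dataset, dir)
  back <- load_ucihar(dir)
  expect_equal(back$train_x, syn$dataset$train_x, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(back$train_y, syn$dataset$train_y)
  expect_identical(back$test_y, syn$dataset$test_y)
  expect_identical(back$class_names, har_classes)
  # second round trip is textually identical
  dir2 <- withr::local_tempdir()
  write_ucihar(back, dir2)
  expect_identical(readLines(file.path(dir, "X_train.txt")),
                   readLines(file.path(dir2, "X_train.txt")))
})

test_that("malformed layout files are rejected with file and line", {
  dir <- withr::local_tempdir()
  syn <- generate_synthetic(n_classes = 2L, n_per_class = 4L,
                            n_informative = 2L, n_redundant = 0L,
                            n_noise = 0L, seed = 4)
  write_ucihar(syn$dataset, dir)

  ylines <- readLines(file.path(dir, "y_train.txt"))
  ylines[3L] <- "7"
  writeLines(ylines, file.path(dir, "y_train.txt"))
  expect_error(load_ucihar(dir, n_classes = 6L), "line 3.*outside 1..6")

  write_ucihar(syn$dataset, dir)
  xlines <- readLines(file.path(dir, "X_train.txt"))
  xlines[2L] <- paste(xlines[2L], "0.5")        # ragged row
  writeLines(xlines, file.path(dir, "X_train.txt"))
  expect_error(load_ucihar(dir), "line 2.*columns")

  write_ucihar(syn$dataset, dir)
  xlines <- readLines(file.path(dir, "X_test.txt"))
  xlines[1L] <- sub("^[-0-9.e+]+", "abc", xlines[1L])
  writeLines(xlines, file.path(dir, "X_test.txt"))
  expect_error(load_ucihar(dir), "line 1.*non-numeric")
})

test_that("CSV loading splits stratified at the published fraction", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "six.csv")
  utils::write.csv(data.frame(f1 = stats::rnorm(6), f2 = stats::rnorm(6),
                              label = rep(c("a", "b"), each = 3L)),
                   p, row.names = FALSE)
  ds <- load_csv(p, "label", train_fraction = 0.5)
  expect_identical(nrow(ds$train_x), 3L)
  expect_identical(nrow(ds$test_x), 3L)
  # class balance preserved within one sample
  expect_true(all(abs(tabulate(ds$train_y, 2L) - 1.5) <= 0.5))

  # header-only file
  writeLines("f1,f2,label", p)
  expect_error(load_csv(p, "label"), "no data rows")
  # missing label column
  utils::write.csv(data.frame(f1 = 1:3), p, row.names = FALSE)
  expect_error(load_csv(p, "label"), "no column named")
  # non-numeric feature
  utils::write.csv(data.frame(f1 = c("x", "y"), label = c("a", "b")), p,
                   row.names = FALSE)
  expect_error(load_csv(p, "label"), "non-numeric")

  # 1000 rows at the default fraction: train share within one sample of
  # the published 71.39% training split
  set.seed(15)
  big <- data.frame(f1 = stats::rnorm(1000), f2 = stats::rnorm(1000),
                    label = sample(c("a", "b", "c"), 1000, replace = TRUE))
  utils::write.csv(big, p, row.names = FALSE)
  ds <- load_csv(p, "label")
  expect_lte(abs(nrow(ds$train_x) - 0.7139 * 1000), 1)
})

test_that("the synthetic generator honours its contract", {
  a <- generate_synthetic(n_per_class = 10L, seed = 20)
  b <- generate_synthetic(n_per_class = 10L, seed = 20)
  expect_identical(a, b)                     # bit-identical under one seed
  c <- generate_synthetic(n_per_class = 10L, seed = 21)
  expect_false(identical(a$dataset$train_x, c$dataset$train_x))

  syn <- generate_synthetic(n_classes = 6L, n_per_class = 50L, seed = 22)
  y_all <- c(syn$dataset$train_y, syn$dataset$test_y)
  expect_identical(tabulate(y_all, 6L), rep(50L, 6L))
  expect_identical(sum(syn$informative_mask), 8L)
  expect_length(syn$informative_mask, 40L)
  # stratified split: per-class train share within one sample of target
  tr_counts <- tabulate(syn$dataset$train_y, 6L)
  expect_true(all(abs(tr_counts - 0.7139 * 50) < 1))

  # huge separation, no redundancy noise: 1-NN on informative columns is
  # perfect on the test partition
  sep <- generate_synthetic(n_classes = 4L, n_per_class = 15L,
                            n_informative = 3L, n_redundant = 2L,
                            n_noise = 5L, class_sep = 10, noise_sd = 0,
                            seed = 23)
  err <- classifier_error(sep$informative_mask, sep$dataset,
                          classifier_spec(k = 1L))
  expect_identical(err, 0)
})

test_that("materialized synthetic datasets reload and keep class counts", {
  dir <- withr::local_tempdir()
  syn <- make_synth(dir, n_classes = 6L, n_per_class = 50L, seed = 24)
  ds <- load_ucihar(dir)
  expect_identical(tabulate(c(ds$train_y, ds$test_y), 6L), rep(50L, 6L))
  gt <- as.integer(readLines(file.path(dir, "informative_mask.txt")))
  expect_identical(gt, syn$informative_mask)
  # identical seed, identical files
  dir2 <- withr::local_tempdir()
  make_synth(dir2, n_classes = 6L, n_per_class = 50L, seed = 24)
  expect_identical(readLines(file.path(dir, "X_train.txt")),
                   readLines(file.path(dir2, "X_train.txt")))
})
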