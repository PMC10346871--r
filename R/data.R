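#' Six-activity class labels
#'
#' Default class-name mapping for activity-recognition feature tables:
#' 1 = WK (walking), 2 = WU (walking upstairs), 3 = WD (walking downstairs),
#' 4 = ST (sitting), 5 = SD (standing), 6 = LD (laying).
#' @export
har_classes <- c("WK", "WU", "WD", "ST", "SD", "LD")

#' Construct a train/test feature dataset
#'
#' The container every other function consumes: numeric feature matrices for
#' the training and test partitions, integer class labels (1-based, indexing
#' `class_names`), and feature/class name vectors.
#'
#' @param train_x,test_x Numeric matrices, samples in rows; equal column
#'   counts, no non-finite entries.
#' @param train_y,test_y Integer labels in `1..length(class_names)`.
#' @param feature_names Optional character vector, one per column.
#' @param class_names Ordered class labels; defaults to [har_classes] when
#'   there are six classes, else `"C1"..."Ck"`.
#' @return An object of class `"feature_dataset"`.
#' @export
feature_dataset <- function(train_x, train_y, test_x, test_y,
                            feature_names = NULL, class_names = NULL) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.integer(train_y); test_y <- as.integer(test_y)
  if (ncol(train_x) != ncol(test_x))
    stop("train and test partitions disagree on feature count")
  if (nrow(train_x) != length(train_y) || nrow(test_x) != length(test_y))
    stop("label length must match the number of rows")
  if (any(!is.finite(train_x)) || any(!is.finite(test_x)))
    stop("feature matrices contain non-finite values")
  n_cls <- max(train_y, test_y)
  if (is.null(class_names))
    class_names <- if (n_cls == 6L) har_classes else paste0("C", seq_len(n_cls))
  if (min(train_y, test_y) < 1L || n_cls > length(class_names))
    stop("labels must index class_names (1..", length(class_names), ")")
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(train_x)))
  if (length(feature_names) != ncol(train_x))
    stop("feature_names length must equal the feature count")
  structure(list(train_x = train_x, train_y = train_y,
                 test_x = test_x, test_y = test_y,
                 feature_names = feature_names,
                 class_names = class_names),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat("Feature dataset:", ncol(x$train_x), "features,",
      nrow(x$train_x), "train /", nrow(x$test_x), "test samples,",
      length(x$class_names), "classes (",
      paste(x$class_names, collapse = ", "), ")\n")
  invisible(x)
}

# Parse a whitespace-separated numeric matrix file, reporting the offending
# file and line on malformed input.
parse_matrix_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(path, ": empty feature file")
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  width <- length(toks[[1L]])
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != width)
      stop(path, " line ", i, ": expected ", width, " columns, found ",
           length(toks[[i]]))
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- which(vapply(toks, function(tk)
      anyNA(suppressWarnings(as.numeric(tk))), TRUE))[1L]
    stop(path, " line ", bad, ": non-numeric cell")
  }
  matrix(vals, ncol = width, byrow = TRUE)
}

parse_label_file <- function(path, n_classes) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(path, ": empty label file")
  y <- suppressWarnings(as.integer(trimws(lines)))
  bad <- which(is.na(y) | y < 1L | y > n_classes)
  if (length(bad) > 0L)
    stop(path, " line ", bad[1L], ": label '", lines[bad[1L]],
         "' outside 1..", n_classes)
  y
}

ucihar_file <- function(directory, sub, name) {
  cand <- c(file.path(directory, sub, name), file.path(directory, name))
  hit <- cand[file.exists(cand)]
  if (length(hit) == 0L)
    stop("cannot find ", name, " under ", directory)
  hit[1L]
}

#' Read a feature table in the UCI-HAR on-disk layout
#'
#' The standard layout of the six-activity smartphone benchmark:
#' whitespace-separated real-valued feature matrices (`X_train.txt`,
#' `X_test.txt`, one sample per row) and one-integer-per-line label files
#' (`y_train.txt`, `y_test.txt`) with labels 1-6 mapped to
#' WK, WU, WD, ST, SD, LD.  Files are accepted either directly in
#' `directory` or in `train/` and `test/` subdirectories.  Malformed rows
#' (ragged width, non-numeric cells, out-of-range labels) are reported with
#' file and line number.
#'
#' @param directory Path holding the layout.
#' @param n_classes Number of label classes the label files may use.
#'   Default 6.
#' @return A [feature_dataset()].
#' @export
load_ucihar <- function(directory, n_classes = 6L) {
  train_x <- parse_matrix_file(ucihar_file(directory, "train", "X_train.txt"))
  train_y <- parse_label_file(ucihar_file(directory, "train", "y_train.txt"),
                              n_classes)
  test_x <- parse_matrix_file(ucihar_file(directory, "test", "X_test.txt"))
  test_y <- parse_label_file(ucihar_file(directory, "test", "y_test.txt"),
                             n_classes)
  if (nrow(train_x) != length(train_y))
    stop("X_train has ", nrow(train_x), " rows but y_train has ",
         length(train_y))
  if (nrow(test_x) != length(test_y))
    stop("X_test has ", nrow(test_x), " rows but y_test has ", length(test_y))
  feature_dataset(train_x, train_y, test_x, test_y,
                  class_names = if (n_classes == 6L) har_classes else NULL)
}

#' Write a feature dataset in the UCI-HAR on-disk layout
#'
#' Inverse of [load_ucihar()]; useful to materialize synthetic datasets for
#' external tools.  Values are written with full `%.10g` precision so that a
#' write/read round trip reproduces the matrix to that precision.
#'
#' @param dataset A [feature_dataset()].
#' @param directory Output directory (created if missing).
#' @return `directory`, invisibly.
#' @export
write_ucihar <- function(dataset, directory) {
  stopifnot(inherits(dataset, "feature_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(m) apply(m, 1L, function(r) paste(sprintf("%.10g", r),
                                                    collapse = " "))
  writeLines(fmt(dataset$train_x), file.path(directory, "X_train.txt"))
  writeLines(as.character(dataset$train_y),
             file.path(directory, "y_train.txt"))
  writeLines(fmt(dataset$test_x), file.path(directory, "X_test.txt"))
  writeLines(as.character(dataset$test_y),
             file.path(directory, "y_test.txt"))
  invisible(directory)
}

#' Stratified train-partition indices
#'
#' Allocates `round(fraction * n)` training slots across classes by largest
#' remainder, so every class's train share deviates from `fraction` by less
#' than one sample and the total deviates by at most rounding.  Rows are
#' taken in data order within each class (shuffle beforehand for a random
#' split).
#'
#' @param y Integer class labels.
#' @param fraction Train fraction in (0, 1).
#' @return Integer vector of training-row indices.
#' @export
stratified_split <- function(y, fraction) {
  stopifnot(fraction > 0, fraction < 1, length(y) > 0L)
  y <- as.integer(y)
  classes <- sort(unique(y))
  n_c <- vapply(classes, function(cl) sum(y == cl), 0L)
  target <- round(fraction * length(y))
  base <- floor(fraction * n_c)
  rem <- fraction * n_c - base
  extra <- target - sum(base)
  if (extra > 0L) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1L
  }
  base <- pmin(pmax(base, 0L), n_c)
  idx <- unlist(lapply(seq_along(classes), function(i) {
    which(y == classes[i])[seq_len(base[i])]
  }))
  sort(idx)
}

#' Read a generic labelled CSV as a feature dataset
#'
#' Expects a header row and a label column; every other column must be
#' numeric.  When the file carries no partition information the rows are
#' split into train/test with a stratified split at `train_fraction`
#' (default the 71.39% training share of the published six-activity
#' benchmark).
#'
#' @param path CSV file path.
#' @param label_column Name of the label column.
#' @param train_fraction Train share in (0, 1). Default 0.7139.
#' @param seed Optional integer; when given, rows are shuffled reproducibly
#'   before the stratified split, otherwise rows are taken in file order.
#' @return A [feature_dataset()].
#' @export
load_csv <- function(path, label_column = "label",
                     train_fraction = 0.7139, seed = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop(path, ": no data rows")
  if (!label_column %in% names(df))
    stop(path, ": no column named '", label_column, "'")
  y_raw <- df[[label_column]]
  x <- df[, setdiff(names(df), label_column), drop = FALSE]
  for (nm in names(x)) {
    v <- suppressWarnings(as.numeric(x[[nm]]))
    if (anyNA(v))
      stop(path, ": non-numeric value in feature column '", nm, "'")
    x[[nm]] <- v
  }
  x <- as.matrix(x)
  lev <- sort(unique(y_raw))
  y <- match(y_raw, lev)
  if (!is.null(seed)) {
    ord <- withr_seed_sample(seed, nrow(x))
    x <- x[ord, , drop = FALSE]; y <- y[ord]
  }
  tr <- stratified_split(y, train_fraction)
  te <- setdiff(seq_along(y), tr)
  feature_dataset(x[tr, , drop = FALSE], y[tr],
                  x[te, , drop = FALSE], y[te],
                  feature_names = colnames(x),
                  class_names = as.character(lev))
}

# Reproducible permutation without disturbing the caller's RNG stream.
withr_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(n)
}

#' Generate a synthetic multi-class feature table
#'
#' Emulates an engineered activity-recognition feature table at configurable
#' scale so the whole selection pipeline is testable offline.  Three feature
#' blocks are produced and then column-shuffled:
#' \describe{
#'   \item{informative}{class-conditional Gaussians with unit variance;
#'     class mean vectors are drawn at random in the informative subspace and
#'     rescaled so the minimum pairwise distance between class means equals
#'     `class_sep`.}
#'   \item{redundant}{random unit-norm linear combinations of the informative
#'     block plus Gaussian noise with standard deviation `noise_sd` — they
#'     carry class signal but no information beyond the informative block.}
#'   \item{noise}{standard Gaussians independent of the class.}
#' }
#' Rows are shuffled and split stratified at `train_fraction`.
#'
#' @param n_classes Number of classes (>= 2). Default 6.
#' @param n_per_class Samples per class before splitting. Default 120,
#'   which matches the samples-per-feature ratio of the emulated benchmark
#'   (about 18 samples per feature at the default 40 features).
#' @param n_informative,n_redundant,n_noise Block sizes. Defaults 8 / 8 / 24
#'   (a 40-feature instance).
#' @param class_sep Minimum distance between class means in the informative
#'   subspace. Default 3: strong enough that a classifier on the
#'   ground-truth informative columns approaches the high-accuracy regime of
#'   engineered activity-recognition feature tables, yet weak enough that no
#'   small sub-subset drives the error to zero, so each informative feature
#'   contributes measurable error reduction (identifiable ground truth).
#' @param noise_sd Noise standard deviation of the redundant block.
#'   Default 0.5.
#' @param train_fraction Train share. Default 0.7139.
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   bit for bit.
#' @return A list with `dataset` (a [feature_dataset()]) and
#'   `informative_mask` (integer 0/1 vector marking the ground-truth
#'   informative columns after the column shuffle).
#' @export
generate_synthetic <- function(n_classes = 6L, n_per_class = 120L,
                               n_informative = 8L, n_redundant = 8L,
                               n_noise = 24L, class_sep = 3,
                               noise_sd = 0.5, train_fraction = 0.7139,
                               seed = NULL) {
  stopifnot(n_classes >= 2L, n_per_class >= 2L, n_informative >= 1L,
            n_redundant >= 0L, n_noise >= 0L, class_sep > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_classes * n_per_class
  y <- rep(seq_len(n_classes), each = n_per_class)

  mu <- matrix(stats::rnorm(n_classes * n_informative), n_classes)
  dmin <- min(stats::dist(mu))
  mu <- mu * (class_sep / dmin)

  x_inf <- mu[y, , drop = FALSE] +
    matrix(stats::rnorm(n * n_informative), n)
  blocks <- list(x_inf)
  kinds <- rep("inf", n_informative)
  if (n_redundant > 0L) {
    w <- matrix(stats::rnorm(n_informative * n_redundant), n_informative)
    w <- sweep(w, 2L, sqrt(colSums(w^2)), "/")
    x_red <- x_inf %*% w +
      noise_sd * matrix(stats::rnorm(n * n_redundant), n)
    blocks <- c(blocks, list(x_red))
    kinds <- c(kinds, rep("red", n_redundant))
  }
  if (n_noise > 0L) {
    blocks <- c(blocks, list(matrix(stats::rnorm(n * n_noise), n)))
    kinds <- c(kinds, rep("noise", n_noise))
  }
  x <- do.call(cbind, blocks)
  fnames <- paste0(kinds, stats::ave(seq_along(kinds), kinds, FUN = seq_along))

  perm <- sample.int(ncol(x))
  x <- x[, perm, drop = FALSE]
  fnames <- fnames[perm]
  informative_mask <- as.integer(kinds[perm] == "inf")

  ord <- sample.int(n)
  x <- x[ord, , drop = FALSE]; y <- y[ord]
  tr <- stratified_split(y, train_fraction)
  te <- setdiff(seq_len(n), tr)
  ds <- feature_dataset(x[tr, , drop = FALSE], y[tr],
                        x[te, , drop = FALSE], y[te],
                        feature_names = fnames)
  list(dataset = ds, informative_mask = informative_mask)
}
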