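#' Native k-nearest-neighbour prediction
#'
#' A deterministic KNN classifier written for the wrapper objective.  A query
#' is assigned the majority label among its `k` nearest training rows under
#' the chosen metric.  All ties are resolved deterministically: ties in
#' neighbour distance are broken by training-row order; ties in the majority
#' vote are broken by the smallest mean neighbour distance among the tied
#' labels, then by the smallest label index.
#'
#' @param train_x Numeric training matrix (rows = samples).
#' @param train_y Integer label vector, one per training row.
#' @param query Numeric matrix of query rows (or a single vector).
#' @param k Number of neighbours; must not exceed `nrow(train_x)`.
#' @param metric `"euclidean"` (default), `"manhattan"` or `"minkowski"`.
#' @param p Minkowski exponent (only for `metric = "minkowski"`).
#' @return Integer vector of predicted labels, one per query row.
#' @export
#' @examples
#' x <- matrix(c(0, 0, 1, 1, 10, 10), ncol = 2, byrow = TRUE)
#' knn_predict(x, c(1L, 1L, 2L), c(0.2, 0.1), k = 1)
knn_predict <- function(train_x, train_y, query, k = 5L,
                        metric = c("euclidean", "manhattan", "minkowski"),
                        p = 3) {
  metric <- match.arg(metric)
  if (is.vector(query)) query <- matrix(query, nrow = 1L)
  train_x <- as.matrix(train_x)
  k <- as.integer(k)
  n <- nrow(train_x)
  if (n == 0L) stop("empty training set")
  if (length(train_y) != n) stop("length(train_y) must equal nrow(train_x)")
  if (ncol(query) != ncol(train_x))
    stop("query has ", ncol(query), " columns but training data has ",
         ncol(train_x))
  if (k > n) stop("k = ", k, " exceeds the ", n, " training rows")
  train_y <- as.integer(train_y)

  dmat <- pairwise_dist(query, train_x, metric, p)  # queries x train rows
  knn_classify_dmat(dmat, train_y, k)
}

# Classify every row of a query-by-train distance matrix: extract the k
# nearest columns per row (distance ties keep the lowest row index, i.e.
# training order) with k vectorized max.col passes, then take the majority
# label; rows with vote ties fall back to the full tie-breaking rule.
knn_classify_dmat <- function(dmat, train_y, k) {
  nq <- nrow(dmat)
  n_cls <- max(train_y)
  labm <- matrix(0L, nq, k)
  dm <- matrix(0, nq, k)
  sub <- dmat
  rows <- seq_len(nq)
  for (i in seq_len(k)) {
    j <- max.col(-sub, ties.method = "first")
    idx <- cbind(rows, j)
    dm[, i] <- dmat[idx]
    labm[, i] <- train_y[j]
    sub[idx] <- Inf
  }
  counts <- matrix(0L, nq, n_cls)
  for (cl in seq_len(n_cls)) counts[, cl] <- rowSums(labm == cl)
  pred <- max.col(counts, ties.method = "first")
  maxc <- counts[cbind(rows, pred)]
  tied <- which(rowSums(counts == maxc) > 1L)
  for (q in tied) pred[q] <- vote_majority(labm[q, ], dm[q, ])
  pred
}

# Majority vote with deterministic tie-breaking: count, then smallest mean
# neighbour distance, then smallest label index.
vote_majority <- function(labels, dists) {
  counts <- tabulate(labels)
  top <- which(counts == max(counts))
  if (length(top) == 1L) return(top)
  md <- vapply(top, function(l) mean(dists[labels == l]), 0)
  top <- top[md == min(md)]
  top[1L]                                   # smallest label index
}

# Dense query-by-train distance matrix.
pairwise_dist <- function(query, train, metric, p = 3) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(query^2), rowSums(train^2), "+") -
      2 * tcrossprod(query, train)
    sqrt(pmax(d2, 0))
  } else {
    ex <- if (metric == "manhattan") 1 else p
    out <- matrix(0, nrow(query), nrow(train))
    tt <- t(train)
    for (q in seq_len(nrow(query))) {
      out[q, ] <- colSums(abs(tt - query[q, ])^ex)^(1 / ex)
    }
    out
  }
}

# Wrap a classifier_spec into the adapter contract used by the fitness
# wrapper and the evaluation report: fit(x, y) -> model; predict(model, x)
# -> integer labels.
classifier_adapter <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$kind == "knn") {
    list(
      fit = function(x, y) list(x = as.matrix(x), y = as.integer(y)),
      predict = function(model, newx)
        knn_predict(model$x, model$y, as.matrix(newx), k = spec$k,
                    metric = spec$metric, p = spec$p)
    )
  } else {
    list(fit = spec$fit, predict = spec$predict)
  }
}
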