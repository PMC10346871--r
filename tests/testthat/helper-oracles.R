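# Independent oracles and fixture builders used across the suite.

# Brute-force KNN oracle: per-query elementwise distances, full stable sort,
# explicit vote with the documented tie-breaks. Shares no code with the
# package's vectorized implementation.
oracle_knn <- function(train_x, train_y, query, k,
                       metric = "euclidean", p = 3) {
  train_x <- as.matrix(train_x)
  if (is.vector(query)) query <- matrix(query, nrow = 1L)
  one_dist <- function(a, b) {
    switch(metric,
           euclidean = sqrt(sum((a - b)^2)),
           manhattan = sum(abs(a - b)),
           minkowski = sum(abs(a - b)^p)^(1 / p))
  }
  apply(query, 1L, function(q) {
    d <- vapply(seq_len(nrow(train_x)),
                function(i) one_dist(train_x[i, ], q), 0)
    nb <- order(d)[seq_len(k)]
    labs <- as.integer(train_y[nb])
    counts <- table(labs)
    winners <- as.integer(names(counts)[counts == max(counts)])
    if (length(winners) > 1L) {
      md <- vapply(winners, function(l) mean(d[nb][labs == l]), 0)
      winners <- winners[md == min(md)]
    }
    min(winners)
  })
}

# Tiny two-class dataset, linearly separated on feature 1; features 2..d are
# pure noise. Train rows alternate classes.
separable_dataset <- function(n_per_class = 10L, d = 3L, gap = 10) {
  x1 <- c(stats::rnorm(n_per_class), gap + stats::rnorm(n_per_class))
  y <- rep(1:2, each = n_per_class)
  x <- cbind(x1, matrix(stats::rnorm(2 * n_per_class * (d - 1L)),
                        ncol = d - 1L))
  idx <- rep(c(TRUE, FALSE), n_per_class)
  feature_dataset(x[idx, , drop = FALSE], y[idx],
                  x[!idx, , drop = FALSE], y[!idx])
}

# A fitness function on bit masks that needs no classifier: weighted bit sum
# with known exhaustive optimum (select exactly the negative weights).
linear_fitness <- function(w) {
  offset <- sum(abs(w))   # keep values nonnegative
  function(mask) {
    f <- (sum(w * mask) + offset) / (2 * offset + 1)
    list(fitness = f, epsilon = f, s_size = sum(mask), t_size = length(w))
  }
}

three_sigma <- function(p, n) 3 * sqrt(p * (1 - p) / n)
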