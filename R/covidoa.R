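#' Roulette-wheel parent selection for a minimization objective
#'
#' Fitness-proportionate selection assumes bigger is better, so the fitness
#' values are first reflected: individual i gets weight
#' `(max(f) - f_i) + delta`, with a small positive `delta` so that a
#' population of identical fitness still selects uniformly.
#'
#' @param fitness Numeric vector of finite fitness values (to be minimized),
#'   one per individual.
#' @param delta Small positive constant added to every weight. Default 1e-9.
#' @return The selected index in `seq_along(fitness)`.
#' @export
roulette_select <- function(fitness, delta = 1e-9) {
  if (length(fitness) == 0L) stop("empty population")
  if (!all(is.finite(fitness))) stop("non-finite fitness")
  w <- (max(fitness) - fitness) + delta
  sample.int(length(fitness), 1L, prob = w)
}

#' Frameshift replication of a parent mask
#'
#' The replication operator of the coronavirus-optimization algorithm: each of
#' the `nop` protein copies is the parent shifted one position to the right —
#' positions `2..d` of the copy equal positions `1..(d-1)` of the parent — with
#' a fresh random bit in position 1.  For `d = 1` the copy is a single random
#' bit.
#'
#' @param parent Integer 0/1 vector (the parent "protein sequence").
#' @param nop Number of protein copies to generate (positive integer).
#' @return A list of `nop` integer 0/1 vectors, each the parent's length.
#' @export
frameshift_replicate <- function(parent, nop) {
  parent <- assert_mask(parent)
  nop <- as.integer(nop)
  stopifnot(nop >= 1L)
  d <- length(parent)
  lapply(seq_len(nop), function(i) {
    v <- integer(d)
    v[1L] <- sample(0:1, 1L)
    if (d > 1L) v[2:d] <- parent[1:(d - 1L)]
    v
  })
}

#' Merge protein copies into one offspring by uniform crossover
#'
#' A single protein is returned unchanged.  With several, the list is folded
#' left to right by uniform crossover: at every position the surviving bit is
#' drawn from either operand with probability 1/2.
#'
#' @param proteins Non-empty list of equal-length integer 0/1 vectors.
#' @return One integer 0/1 vector, the new virion.
#' @export
combine_proteins <- function(proteins) {
  if (!is.list(proteins) || length(proteins) == 0L)
    stop("'proteins' must be a non-empty list")
  proteins <- lapply(proteins, assert_mask)
  d <- length(proteins[[1L]])
  if (any(vapply(proteins, length, 1L) != d))
    stop("proteins differ in length")
  out <- proteins[[1L]]
  for (i in seq_along(proteins)[-1L]) {
    take <- stats::runif(d) < 0.5
    out <- ifelse(take, out, proteins[[i]])
  }
  as.integer(out)
}

#' Per-position bit mutation
#'
#' Each position is independently replaced by a fresh random bit with
#' probability `mr` and kept otherwise.  Because the replacement is itself a
#' random bit, the probability that a mutated position actually changes value
#' is `mr / 2`.
#'
#' @param mask Integer 0/1 vector.
#' @param mr Mutation rate in \[0, 1\].
#' @return Mutated integer 0/1 vector.
#' @export
mutate_bits <- function(mask, mr) {
  mask <- assert_mask(mask)
  stopifnot(is.numeric(mr), length(mr) == 1L, mr >= 0, mr <= 1)
  hit <- stats::runif(length(mask)) < mr
  n_hit <- sum(hit)
  if (n_hit > 0L) mask[hit] <- sample(0:1, n_hit, replace = TRUE)
  mask
}

# Evaluate one mask into an "individual" record.
eval_individual <- function(mask, fitness_fn) {
  fb <- fitness_fn(mask)
  list(bits = mask, fitness = fb$fitness, epsilon = fb$epsilon,
       s_size = fb$s_size)
}

#' Run the COVIDOA population stage
#'
#' Seeds `n_pop` real-valued vectors uniformly in `[lb, ub]`, binarizes them
#' through the S-shaped transfer function, repairs any empty mask, and then
#' iterates for `max_iter` generations.  Each generation builds `n_pop`
#' offspring — roulette-selected parent, frameshift replication into `nop`
#' proteins, uniform crossover, bit mutation, repair — and keeps the best
#' `n_pop` of parents and offspring pooled together (elitist update), so the
#' best-so-far fitness trace is non-increasing by construction.
#'
#' @param params A [covidoa_params()] object.
#' @param fitness_fn Function taking an integer 0/1 mask and returning a list
#'   with at least elements `fitness`, `epsilon` and `s_size` (see
#'   [make_fitness()]).
#' @return A list with elements `best` (the best individual: `bits`,
#'   `fitness`, `epsilon`, `s_size`), `trace` (best fitness after each
#'   generation, length `max_iter`), and `population` (final bit matrix).
#' @export
covidoa <- function(params, fitness_fn) {
  stopifnot(inherits(params, "covidoa_params"), is.function(fitness_fn))
  d <- params$d
  n <- params$n_pop

  pop <- matrix(0L, nrow = n, ncol = d)
  for (i in seq_len(n)) {
    seed_vec <- stats::runif(d, params$lb, params$ub)
    pop[i, ] <- repair_mask(binarize(seed_vec))
  }
  fit <- numeric(n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    meta[[i]] <- eval_individual(pop[i, ], fitness_fn)
    fit[i] <- meta[[i]]$fitness
  }

  trace <- numeric(params$max_iter)
  for (iter in seq_len(params$max_iter)) {
    child_bits <- matrix(0L, nrow = n, ncol = d)
    child_fit <- numeric(n)
    child_meta <- vector("list", n)
    for (j in seq_len(n)) {
      parent <- pop[roulette_select(fit), ]
      proteins <- frameshift_replicate(parent, params$nop)
      child <- combine_proteins(proteins)
      child <- repair_mask(mutate_bits(child, params$mr))
      child_bits[j, ] <- child
      child_meta[[j]] <- eval_individual(child, fitness_fn)
      child_fit[j] <- child_meta[[j]]$fitness
    }
    all_fit <- c(fit, child_fit)
    keep <- order(all_fit)[seq_len(n)]   # stable: parents win ties
    all_bits <- rbind(pop, child_bits)
    all_meta <- c(meta, child_meta)
    pop <- all_bits[keep, , drop = FALSE]
    fit <- all_fit[keep]
    meta <- all_meta[keep]
    trace[iter] <- min(fit)
  }

  best_i <- which.min(fit)
  list(best = meta[[best_i]], trace = trace, population = pop)
}
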