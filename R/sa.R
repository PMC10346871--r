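#' Geometric cooling step
#'
#' @param t Current temperature (> 0).
#' @param cooling Cooling rate in (0, 1).
#' @return `t * cooling`, strictly smaller than `t`.
#' @export
cool_temperature <- function(t, cooling) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0)
  if (!is.numeric(cooling) || length(cooling) != 1L ||
      cooling <= 0 || cooling >= 1)
    stop("'cooling' must lie strictly between 0 and 1")
  t * cooling
}

#' Metropolis acceptance rule for minimization
#'
#' A move that does not worsen the objective (`delta_f <= 0`) is always
#' accepted; a worsening move is accepted with probability
#' `exp(-delta_f / t)`, so acceptance of bad moves dies off as the
#' temperature falls.
#'
#' @param delta_f Fitness difference `f_new - f_current`.
#' @param t Current temperature (> 0).
#' @return Logical: accept the move?
#' @export
sa_accept <- function(delta_f, t) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("'t' must be a positive number")
  stopifnot(is.numeric(delta_f), length(delta_f) == 1L, is.finite(delta_f))
  if (delta_f <= 0) return(TRUE)
  stats::runif(1L) < exp(-delta_f / t)
}

#' Neighbouring mask: single uniform bit flip
#'
#' Flips one uniformly chosen bit, then repairs the mask if the flip emptied
#' it (see [repair_mask()]).
#'
#' @param mask Integer 0/1 vector.
#' @return A neighbouring integer 0/1 vector with at least one set bit.
#' @export
sa_neighbor <- function(mask) {
  mask <- assert_mask(mask)
  i <- sample.int(length(mask), 1L)
  mask[i] <- 1L - mask[i]
  repair_mask(mask)
}

#' Simulated-annealing refinement of a feature mask
#'
#' Starting from an already evaluated individual (in the hybrid, the optimum
#' of the population stage), repeatedly proposes a single-bit-flip neighbour,
#' accepts it by the Metropolis rule, and cools the temperature geometrically
#' until it reaches `t_end` or below.  The current solution may wander uphill;
#' the best-so-far solution is tracked separately and returned, so the result
#' is never worse than the initial individual.
#'
#' @param initial An individual (list with `bits`, `fitness`, `epsilon`,
#'   `s_size`), e.g. the `best` element of [covidoa()].
#' @param params A [sa_params()] object.
#' @param fitness_fn As in [covidoa()].
#' @return A list with `best` (individual) and `trace` (best-so-far fitness
#'   after each temperature step; length 0 when `t0 <= t_end`).
#' @export
sa_refine <- function(initial, params, fitness_fn) {
  stopifnot(inherits(params, "sa_params"), is.function(fitness_fn),
            is.list(initial), !is.null(initial$bits),
            is.numeric(initial$fitness))
  current <- initial
  best <- initial
  t <- params$t0
  trace <- numeric(0)
  while (t > params$t_end) {
    cand <- eval_individual(sa_neighbor(current$bits), fitness_fn)
    if (sa_accept(cand$fitness - current$fitness, t)) current <- cand
    if (current$fitness < best$fitness) best <- current
    trace <- c(trace, best$fitness)
    t <- cool_temperature(t, params$cooling)
  }
  list(best = best, trace = trace)
}

#' Run the full hybrid: population stage, then annealing refinement
#'
#' Runs [covidoa()], records its stage optimum, hands that optimum to
#' [sa_refine()] as the initial solution, and returns the combined record.
#' The final best fitness can never exceed the population-stage best.
#'
#' @param covidoa_params A [covidoa_params()] object.
#' @param sa_params A [sa_params()] object.
#' @param fitness_fn As in [covidoa()].
#' @return A list of class `"hybrid_result"`: `best` (individual),
#'   `covidoa_trace`, `sa_trace`, `covidoa_stage_best` (fitness before
#'   refinement).
#' @export
hybrid_run <- function(covidoa_params, sa_params, fitness_fn) {
  stage1 <- covidoa(covidoa_params, fitness_fn)
  stage2 <- sa_refine(stage1$best, sa_params, fitness_fn)
  structure(list(best = stage2$best,
                 covidoa_trace = stage1$trace,
                 sa_trace = stage2$trace,
                 covidoa_stage_best = stage1$best$fitness),
            class = "hybrid_result")
}
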