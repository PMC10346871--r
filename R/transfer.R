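#' S-shaped transfer function
#'
#' The logistic map `1 / (1 + exp(-x))` used to turn a real-valued candidate
#' vector into per-position bit probabilities before binarization.  Strictly
#' increasing, symmetric about (0, 0.5).
#'
#' @param x Numeric vector; all entries must be finite.
#' @return Values in (0, 1), same length as `x`.
#' @export
#' @examples
#' sigmoid_transfer(c(-10, 0, 10))
sigmoid_transfer <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric")
  1 / (1 + exp(-x))
}

#' Stochastic binarization of a real-valued vector
#'
#' Maps each entry through [sigmoid_transfer()] and draws a bit.  The default
#' rule sets the bit when a fresh uniform draw is at least `S(x)`, so
#' `P(bit = 1) = 1 - S(x)`; this inverts the conventional transfer-function
#' rule, under which `P(bit = 1) = S(x)` (available as
#' `direction = "conventional"`).  Used only to create the initial binary
#' population from uniform seeding vectors; after initialization the search
#' operates purely in bit space.
#'
#' @param x Numeric vector of finite reals.
#' @param direction `"inverted"` (bit = 1 when `runif() >= S(x)`, the default)
#'   or `"conventional"` (bit = 1 when `runif() < S(x)`).
#' @return Integer 0/1 vector of the same length.
#' @export
binarize <- function(x, direction = c("inverted", "conventional")) {
  direction <- match.arg(direction)
  s <- sigmoid_transfer(x)
  u <- stats::runif(length(x))
  if (direction == "inverted") as.integer(u >= s) else as.integer(u < s)
}
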