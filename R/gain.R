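#' Sigmoidal population gain
#'
#' The firing-rate gain used throughout: `F(u) = F0 / (1 + exp(-gamma * u))`,
#' a logistic sigmoid with maximum rate `F0` and steepness `gamma`.  Any
#' activation threshold is absorbed into the external drive, so `F` takes the
#' summed synaptic input directly.  Evaluation goes through [stats::plogis()]
#' and is overflow-safe for arbitrarily large `|u|`.
#'
#' @param gamma Dimensionless gain (steepness); must be positive.
#' @param F0 Maximum firing rate, in units of the membrane rate constant
#'   (time is measured in membrane time constants throughout); must be
#'   positive.
#'
#' @return `gain_params()` returns a `gain_params` object (a validated list
#'   with elements `gamma` and `F0`).
#' @examples
#' p <- gain_params(gamma = 1, F0 = 1)
#' sigmoid_gain(0, p) # F0/2
#' @export
gain_params <- function(gamma = 1, F0 = 1) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, is.finite(gamma),
            gamma > 0, is.numeric(F0), length(F0) == 1, is.finite(F0),
            F0 > 0)
  structure(list(gamma = gamma, F0 = F0), class = "gain_params")
}

#' @rdname gain_params
#' @param u Summed synaptic input (any real vector).
#' @param p A [gain_params()] object.
#' @return `sigmoid_gain()` returns `F(u)`, strictly increasing and bounded
#'   in `(0, F0)`.
#' @export
sigmoid_gain <- function(u, p = gain_params()) {
  p$F0 * stats::plogis(p$gamma * u)
}

#' @rdname gain_params
#' @return `sigmoid_gain_deriv()` returns `F'(u) = gamma F (1 - F/F0)`;
#'   `sigmoid_gain_deriv2()` the second derivative
#'   `gamma F' (1 - 2 F/F0)`.
#' @export
sigmoid_gain_deriv <- function(u, p = gain_params()) {
  f <- sigmoid_gain(u, p)
  p$gamma * f * (1 - f / p$F0)
}

#' @rdname gain_params
#' @export
sigmoid_gain_deriv2 <- function(u, p = gain_params()) {
  f <- sigmoid_gain(u, p)
  p$gamma * sigmoid_gain_deriv(u, p) * (1 - 2 * f / p$F0)
}

#' @export
print.gain_params <- function(x, ...) {
  cat("<gain_params> gamma =", x$gamma, ", F0 =", x$F0, "\n")
  invisible(x)
}
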