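#' Model specifications for stochastic neuronal population networks
#'
#' A `network_spec` describes an M-population stochastic Wilson-Cowan model:
#' each population holds `N` neurons whose active count follows a birth-death
#' master equation with birth intensity `F(sum_l w_kl x_l + h_k)` and death
#' intensity `alpha_k x_k` per neuron slot (`x_k = n_k / N`).  The
#' thermodynamic limit `N -> Inf` recovers the deterministic Wilson-Cowan
#' rate equations.  Finite `N` contributes intrinsic multiplicative noise of
#' strength `epsilon = N^(-1/2)`; a common white-noise component of the
#' drive, strength `sigma` split across populations by weights `chi_k`,
#' supplies extrinsic noise shared by every oscillator in an ensemble.
#'
#' @param weights M x M matrix `w_kl`: synaptic weight from population `l`
#'   onto population `k`.
#' @param drive Length-M vector of constant external inputs `h_k`.
#' @param decay Length-M vector of rate constants `alpha_k` (default 1; time
#'   is in units of the membrane time constant, about 10 ms).
#' @param gain A [gain_params()] object.
#' @param N Neurons per population (positive integer); `epsilon = N^(-1/2)`
#'   is always derived from `N`, never stored.
#' @param chi Length-M vector of nonnegative common-noise weights `chi_k`.
#' @param sigma Extrinsic (common) noise strength, `>= 0`.
#'
#' @return An object of class `network_spec`.
#' @seealso [depression_spec()], [preset_spec()], [transition_rates()],
#'   [meanfield_rhs()]
#' @examples
#' spec <- preset_spec("ei")
#' spec$weights
#' @export
network_spec <- function(weights, drive, decay = rep(1, nrow(weights)),
                         gain = gain_params(), N = 1e5,
                         chi = rep(1 / nrow(weights), nrow(weights)),
                         sigma = 0) {
  weights <- as.matrix(weights)
  M <- nrow(weights)
  stopifnot(ncol(weights) == M, M >= 1, length(drive) == M,
            length(decay) == M, all(decay > 0), inherits(gain, "gain_params"),
            length(N) == 1, is.finite(N), N >= 1, N == round(N),
            length(chi) == M, all(chi >= 0), length(sigma) == 1, sigma >= 0)
  structure(
    list(M = M, N = as.numeric(N), weights = unname(weights),
         drive = as.numeric(drive), decay = as.numeric(decay), gain = gain,
         chi = as.numeric(chi), sigma = sigma),
    class = "network_spec")
}

#' @rdname network_spec
#' @param k_plus Recovery rate of the synaptic resource variable `q`.
#' @param k_minus Depletion rate (resources are consumed at rate
#'   `k_minus * x * q`).
#' @param w_self Recurrent excitatory weight multiplying `q * x` inside the
#'   gain; the preset uses 1, with the coupling scale carried by the gain
#'   steepness.
#' @param h Constant external drive (scalar, depression model).
#'
#' @details A `depression_spec` describes the one-population recurrent
#' excitatory network with synaptic depression: activity `x` follows the
#' same birth-death process with `q`-dependent birth intensity
#' `F(w_self * q * x + h)`, while the depression variable
#' `dq/dt = k_plus (1 - q) - k_minus x q` flows deterministically between
#' jumps, making the stochastic model a piecewise-deterministic Markov
#' process.
#' @return `depression_spec()` returns an object of class `depression_spec`.
#' @export
depression_spec <- function(k_plus, k_minus, h, w_self = 1,
                            gain = gain_params(), decay = 1, N = 1e4,
                            sigma = 0) {
  stopifnot(k_plus > 0, k_minus >= 0, inherits(gain, "gain_params"),
            length(N) == 1, N >= 1, N == round(N), decay > 0, sigma >= 0)
  structure(
    list(M = 1L, N = as.numeric(N), k_plus = k_plus, k_minus = k_minus,
         w_self = w_self, drive = h, decay = decay, gain = gain,
         chi = 1, sigma = sigma),
    class = "depression_spec")
}

#' Canonical model presets
#'
#' Two presets ship with the package.  `"ei"` is the mutually coupled
#' excitatory-inhibitory pair operating in its limit-cycle regime:
#' `w_EE = 11.5`, `w_IE = 10`, `w_EI = -10`, `w_II = -2`, `h_E = 0`,
#' `h_I = -4`, unit gain and maximum rate.  `"depression"` is the recurrent
#' excitatory network with synaptic depression in its oscillatory regime:
#' `k_plus = 0.02`, `k_minus = 0.1`, `h = -0.15`, gain steepness 20, unit
#' maximum rate.
#'
#' @param name `"ei"` or `"depression"`.
#' @param N System size override.
#' @param sigma Common-noise strength override.
#' @param chi Common-noise weights override (`"ei"` only; default symmetric
#'   `c(1/2, 1/2)`).
#' @return A [network_spec()] or [depression_spec()].
#' @export
preset_spec <- function(name = c("ei", "depression"), N = NULL, sigma = NULL,
                        chi = NULL) {
  name <- match.arg(name)
  if (name == "ei") {
    spec <- network_spec(
      weights = matrix(c(11.5, -10, 10, -2), 2, 2, byrow = TRUE),
      drive = c(0, -4), decay = c(1, 1), gain = gain_params(1, 1),
      N = if (is.null(N)) 1e5 else N,
      chi = if (is.null(chi)) c(0.5, 0.5) else chi,
      sigma = if (is.null(sigma)) 0.08 else sigma)
  } else {
    if (!is.null(chi)) stop("`chi` applies only to the \"ei\" preset")
    spec <- depression_spec(
      k_plus = 0.02, k_minus = 0.1, h = -0.15, w_self = 1,
      gain = gain_params(20, 1),
      N = if (is.null(N)) 1e4 else N,
      sigma = if (is.null(sigma)) 0.004 else sigma)
  }
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", x$M, "population(s), N =", x$N,
      sprintf("(epsilon = %.4g)", 1 / sqrt(x$N)), "\n")
  cat("  weights:\n")
  print(x$weights)
  cat("  drive:", x$drive, " decay:", x$decay, "\n")
  cat("  gain: gamma =", x$gain$gamma, ", F0 =", x$gain$F0, "\n")
  cat("  common noise: sigma =", x$sigma, ", chi =", x$chi, "\n")
  invisible(x)
}

#' @export
print.depression_spec <- function(x, ...) {
  cat("<depression_spec> N =", x$N,
      sprintf("(epsilon = %.4g)", 1 / sqrt(x$N)), "\n")
  cat("  k_plus =", x$k_plus, ", k_minus =", x$k_minus,
      ", h =", x$drive, ", w_self =", x$w_self, "\n")
  cat("  gain: gamma =", x$gain$gamma, ", F0 =", x$gain$F0,
      "  sigma =", x$sigma, "\n")
  invisible(x)
}

# epsilon is always derived from N
spec_epsilon <- function(spec) 1 / sqrt(spec$N)

# dimension of the deterministic state (activities, plus q for depression)
spec_dim <- function(spec) {
  if (inherits(spec, "depression_spec")) 2L else spec$M
}

# names of the state components, used for tibble columns
spec_state_names <- function(spec) {
  if (inherits(spec, "depression_spec")) return(c("x", "q"))
  if (spec$M == 2) c("x_E", "x_I") else paste0("x_", seq_len(spec$M))
}
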