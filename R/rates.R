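#' Master-equation transition rates
#'
#' Birth and death rates of the M-population birth-death process.  For
#' population `k` with occupation `n_k` out of `N`:
#' death `T_k- = alpha_k n_k`, birth
#' `T_k+ = N F(sum_l w_kl n_l / N + h_k)`.  The rescaled intensities
#' `Omega_k+- = T_k+- / N` drive the mean-field and Langevin reductions.
#' Occupations may not leave `[0, N]`: the master equation assigns zero
#' probability outside the lattice, which the simulators enforce by giving
#' boundary-violating transitions zero rate.
#'
#' @param n Integer occupation vector (length M), each entry in `[0, N]`.
#' @param spec A [network_spec()].
#' @param rescaled If `TRUE` return intensities `Omega = T / N`.
#' @return A tibble with columns `population`, `birth`, `death`.
#' @examples
#' spec <- network_spec(weights = matrix(0), drive = 0, N = 100)
#' transition_rates(50, spec) # birth = death = 50
#' @export
transition_rates <- function(n, spec, rescaled = FALSE) {
  stopifnot(inherits(spec, "network_spec"), length(n) == spec$M)
  if (any(n < 0 | n > spec$N)) {
    stop("occupation out of [0, N]")
  }
  x <- n / spec$N
  u <- as.numeric(spec$weights %*% x) + spec$drive
  birth <- spec$N * sigmoid_gain(u, spec$gain)
  death <- spec$decay * n
  scale <- if (rescaled) spec$N else 1
  tibble::tibble(population = seq_len(spec$M),
                 birth = birth / scale, death = death / scale)
}

#' Mean-field (Wilson-Cowan) vector field
#'
#' The deterministic rate equations recovered from the master equation in
#' the thermodynamic limit.  For a [network_spec()]:
#' `dx_k/dt = -alpha_k x_k + F(sum_l w_kl x_l + h_k)`, identically the
#' difference of rescaled birth and death intensities.  For a
#' [depression_spec()] the state is `c(x, q)`:
#' `dx/dt = -x + F(w_self q x + h)`,
#' `dq/dt = k_plus (1 - q) - k_minus x q`.
#'
#' @param x Numeric state vector (activities; `c(x, q)` for the depression
#'   model).
#' @param spec A [network_spec()] or [depression_spec()].
#' @return Numeric vector `dx/dt` of the same length as `x`.
#' @export
meanfield_rhs <- function(x, spec) UseMethod("meanfield_rhs", spec)

#' @export
meanfield_rhs.network_spec <- function(x, spec) {
  u <- as.numeric(spec$weights %*% x) + spec$drive
  -spec$decay * x + sigmoid_gain(u, spec$gain)
}

#' @export
meanfield_rhs.depression_spec <- function(x, spec) {
  u <- spec$w_self * x[2] * x[1] + spec$drive
  c(-spec$decay * x[1] + sigmoid_gain(u, spec$gain),
    spec$k_plus * (1 - x[2]) - spec$k_minus * x[1] * x[2])
}

#' Jacobian of the mean-field flow
#'
#' Analytic Jacobian using `F' = gamma F (1 - F/F0)` (which reduces to the
#' logistic identity `F' = F(1-F)` at unit gain), with a centred
#' finite-difference fallback available for cross-checks.
#'
#' @inheritParams meanfield_rhs
#' @param method `"analytic"` (default) or `"numeric"` (centred differences,
#'   step `1e-6`).
#' @return Square matrix `d(dx/dt)/dx`.
#' @export
jacobian_matrix <- function(x, spec, method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (method == "numeric") {
    d <- length(x)
    eps <- 1e-6
    J <- matrix(0, d, d)
    for (j in seq_len(d)) {
      e <- replace(numeric(d), j, eps)
      J[, j] <- (meanfield_rhs(x + e, spec) - meanfield_rhs(x - e, spec)) /
        (2 * eps)
    }
    return(J)
  }
  if (inherits(spec, "depression_spec")) {
    u <- spec$w_self * x[2] * x[1] + spec$drive
    fp <- sigmoid_gain_deriv(u, spec$gain)
    matrix(c(-spec$decay + fp * spec$w_self * x[2], fp * spec$w_self * x[1],
             -spec$k_minus * x[2], -spec$k_plus - spec$k_minus * x[1]),
           2, 2, byrow = TRUE)
  } else {
    u <- as.numeric(spec$weights %*% x) + spec$drive
    diag(-spec$decay, spec$M) +
      diag(sigmoid_gain_deriv(u, spec$gain), spec$M) %*% spec$weights
  }
}

#' Langevin drift and noise amplitudes
#'
#' Coefficients of the chemical-Langevin approximation evaluated at a state.
#' Drift `A_k = Omega_k+ - Omega_k-`; intrinsic (finite-size) amplitude
#' `b_k = sqrt(Omega_k+ + Omega_k-)`, entering with prefactor
#' `epsilon = N^(-1/2)` as independent Ito noise; common-noise amplitude
#' `a_k = chi_k F'(u_k)` (for the depression model `a = F'(w_self q x + h)`
#' and noise enters the activity equation only), entering with prefactor
#' `sigma` as shared Stratonovich noise.
#'
#' @inheritParams meanfield_rhs
#' @return A tibble with columns `component`, `drift`, `intrinsic`
#'   (`b_k`), `common` (`a_k`).  For the depression model the `q` row has
#'   zero noise amplitudes.
#' @export
langevin_drift_diffusion <- function(x, spec) {
  UseMethod("langevin_drift_diffusion", spec)
}

#' @export
langevin_drift_diffusion.network_spec <- function(x, spec) {
  u <- as.numeric(spec$weights %*% x) + spec$drive
  om_plus <- sigmoid_gain(u, spec$gain)
  om_minus <- spec$decay * x
  s <- om_plus + om_minus
  if (any(s < 0)) stop("negative total intensity: state outside model domain")
  tibble::tibble(
    component = spec_state_names(spec),
    drift = om_plus - om_minus,
    intrinsic = sqrt(s),
    common = spec$chi * sigmoid_gain_deriv(u, spec$gain))
}

#' @export
langevin_drift_diffusion.depression_spec <- function(x, spec) {
  u <- spec$w_self * x[2] * x[1] + spec$drive
  om_plus <- sigmoid_gain(u, spec$gain)
  om_minus <- spec$decay * x[1]
  s <- om_plus + om_minus
  if (any(s < 0)) stop("negative total intensity: state outside model domain")
  tibble::tibble(
    component = c("x", "q"),
    drift = meanfield_rhs(x, spec),
    intrinsic = c(sqrt(s), 0),
    common = c(sigmoid_gain_deriv(u, spec$gain), 0))
}

# derivative of b_k with respect to x_k on the diagonal, needed for the
# Ito -> Stratonovich conversion of the intrinsic noise:
# b_k^2 = F(u_k) + alpha_k x_k  =>  b_k db_k/dx_k = (F'(u_k) w_kk + alpha_k)/2
intrinsic_bdb <- function(x, spec) {
  if (inherits(spec, "depression_spec")) {
    u <- spec$w_self * x[2] * x[1] + spec$drive
    c((sigmoid_gain_deriv(u, spec$gain) * spec$w_self * x[2] + spec$decay) / 2,
      0)
  } else {
    u <- as.numeric(spec$weights %*% x) + spec$drive
    (sigmoid_gain_deriv(u, spec$gain) * diag(spec$weights) + spec$decay) / 2
  }
}
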