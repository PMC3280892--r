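#' Assemble the stochastic phase equation on the limit cycle
#'
#' Projects the Langevin noise structure onto the phase variable.  With all
#' coefficients evaluated on the deterministic orbit, the Stratonovich phase
#' equation reads
#' `dTheta = (omega + eps^2 nu(Theta)) dt + sigma alpha(Theta) o dW
#'  + eps sum_k beta_k(Theta) o dW_k`,
#' where `alpha = sum_k Z_k a_k` (common channel),
#' `beta_k = Z_k b_k` (independent channels) and
#' `nu = -(1/2) sum_k Z_k b_k db_k/dx_k` is the drift inherited from
#' converting the intrinsic Ito noise to Stratonovich form before phase
#' reduction.  Converting the phase equation itself to Ito form adds
#' `(sigma^2/4) d(alpha^2)/dtheta + (eps^2/4) d(sum_k beta_k^2)/dtheta`,
#' computed here by spectral differentiation of the tabulated coefficients.
#' When `eps = sigma = 0` the drift is identically `omega` and all noise
#' coefficients vanish.
#'
#' @param lc A [find_limit_cycle()] result.
#' @param prc The matching [compute_prc()] result (same grid).
#' @param sigma,N,chi Optional overrides of the spec's common-noise
#'   strength, system size and noise weights.
#' @return A `phase_law`: tibble with columns `theta`, `common`, one
#'   `beta_*` per component, `indep_total` (root-sum-square of the
#'   independent amplitudes), `strat`, `drift` (full Ito drift at the law's
#'   `epsilon`, `sigma`); attributes `omega`, `period`, `epsilon`, `sigma`,
#'   `spec`, `n_grid`.
#' @export
build_phase_law <- function(lc, prc, sigma = NULL, N = NULL, chi = NULL) {
  stopifnot(inherits(lc, "limit_cycle"), inherits(prc, "prc"))
  if (attr(lc, "n_grid") != attr(prc, "n_grid")) {
    stop("limit cycle and PRC are tabulated on different grids")
  }
  spec <- attr(lc, "spec")
  if (!is.null(sigma)) spec$sigma <- sigma
  if (!is.null(N)) spec$N <- as.numeric(N)
  if (!is.null(chi)) {
    if (inherits(spec, "depression_spec")) stop("chi applies to networks")
    stopifnot(length(chi) == spec$M, all(chi >= 0))
    spec$chi <- chi
  }
  n <- attr(lc, "n_grid")
  omega <- attr(lc, "omega")
  st <- lc_states(lc)
  Z <- prc_components(prc)
  d <- ncol(st)
  ab <- t(apply(st, 1, function(x) {
    co <- langevin_drift_diffusion(x, spec)
    c(co$common, co$intrinsic)
  }))
  a <- ab[, seq_len(d), drop = FALSE]
  b <- ab[, d + seq_len(d), drop = FALSE]
  bdb <- t(apply(st, 1, intrinsic_bdb, spec = spec))
  if (inherits(spec, "depression_spec")) {
    # noise enters the activity equation only
    a[, 2] <- 0
    b[, 2] <- 0
  }
  common <- rowSums(Z * a)
  beta <- Z * b
  strat <- -0.5 * rowSums(Z * bdb)
  eps <- spec_epsilon(spec)
  sum_beta2 <- rowSums(beta^2)
  drift <- omega + eps^2 * strat +
    (spec$sigma^2 / 4) * spectral_deriv(common^2) +
    (eps^2 / 4) * spectral_deriv(sum_beta2)
  out <- tibble::as_tibble(as.data.frame(beta))
  names(out) <- paste0("beta_", sub("^Z_", "", colnames(Z)))
  out <- tibble::add_column(out, theta = lc$theta, common = common,
                            .before = 1)
  out$indep_total <- sqrt(sum_beta2)
  out$strat <- strat
  out$drift <- drift
  structure(out, class = c("phase_law", class(out)),
            omega = omega, period = attr(lc, "period"),
            epsilon = eps, sigma = spec$sigma, spec = spec, n_grid = n)
}

#' @export
print.phase_law <- function(x, ...) {
  cat(sprintf(
    "<phase_law> omega %.6g, epsilon %.4g, sigma %.4g, %d grid points\n",
    attr(x, "omega"), attr(x, "epsilon"), attr(x, "sigma"),
    attr(x, "n_grid")))
  NextMethod()
}

#' Simulate an ensemble of phase oscillators under the law
#'
#' Euler-Maruyama on the Ito phase equation.  Every oscillator receives the
#' same common Wiener increment, scaled by its own `common(Theta)`; the
#' independent channels are drawn per oscillator with the root-sum-square
#' amplitude `indep_total(Theta)` (equivalent in law to the per-population
#' channels).  Phases are reported wrapped to `[-pi, pi)`.
#'
#' @param law A [build_phase_law()] result.
#' @param n_osc Number of oscillators (`>= 2`).
#' @param horizon Total simulated time (membrane time constants).
#' @param dt Step size; refused if `>= period/100`.
#' @param seed Optional RNG seed (`set.seed`) for reproducible paths.
#' @param sample_every Interval between recorded snapshots (default
#'   `horizon/100`).
#' @param init `"spread"` (phases uniformly spaced around the cycle),
#'   `"equal"` (all at 0), or a numeric vector of initial phases.
#' @return A `phase_trajectory` tibble with columns `time`, `oscillator`,
#'   `theta`; attributes carry the law parameters and seed.
#' @export
simulate_phase_ensemble <- function(law, n_osc, horizon, dt = 1e-3,
                                    seed = NULL, sample_every = NULL,
                                    init = "spread") {
  stopifnot(inherits(law, "phase_law"), n_osc >= 2, dt > 0, horizon > dt)
  if (dt >= attr(law, "period") / 100) {
    stop("dt too coarse: must resolve the period (dt < period/100)")
  }
  if (!is.null(seed)) set.seed(seed)
  theta0 <- if (is.numeric(init)) {
    stopifnot(length(init) == n_osc)
    init
  } else if (identical(init, "equal")) {
    rep(0, n_osc)
  } else {
    phase_grid(n_osc)
  }
  if (is.null(sample_every)) sample_every <- horizon / 100
  sample_times <- seq(sample_every, horizon, by = sample_every)
  ph <- em_phase_cpp(law$drift, law$common, law$indep_total,
                     attr(law, "sigma"), attr(law, "epsilon"),
                     theta0, dt, sample_times)
  out <- tibble::tibble(
    time = rep(sample_times, times = n_osc),
    oscillator = rep(seq_len(n_osc), each = length(sample_times)),
    theta = as.numeric(ph))
  structure(out, class = c("phase_trajectory", class(out)),
            kind = "diffusion", seed = seed, dt = dt,
            omega = attr(law, "omega"), period = attr(law, "period"),
            epsilon = attr(law, "epsilon"), sigma = attr(law, "sigma"))
}
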