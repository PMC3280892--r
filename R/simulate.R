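#' Exact stochastic simulation of the master equation
#'
#' Gillespie's direct method over the `2M` birth/death channels, with rates
#' from [transition_rates()].  Occupations never leave `[0, N]`: transitions
#' that would cross the boundary carry zero rate, matching the master
#' equation's absorbing boundary convention.  States are recorded by exact
#' piecewise-constant sampling at `sample_times` (the default is 200 evenly
#' spaced snapshots); set `record = "events"` to keep every jump (small
#' fixtures only, capped at `max_events`).
#'
#' @param spec A [network_spec()].
#' @param n0 Integer occupation vector (defaults to `N/2` per population).
#' @param horizon Total simulated time.
#' @param seed Optional RNG seed.
#' @param sample_times Snapshot times (record = "sample").
#' @param record `"sample"` or `"events"`.
#' @param max_events Cap on recorded jumps for `record = "events"`.
#' @return A `jump_trajectory` tibble: columns `time`, one fractional
#'   activity column per population (`x_* = n/N`); attribute `absorbed`
#'   flags an absorbing state reached before the horizon.
#' @export
ssa_run <- function(spec, n0 = NULL, horizon = 10, seed = NULL,
                    sample_times = NULL, record = c("sample", "events"),
                    max_events = 1e6) {
  stopifnot(inherits(spec, "network_spec"))
  record <- match.arg(record)
  if (is.null(n0)) n0 <- rep(round(spec$N / 2), spec$M)
  stopifnot(length(n0) == spec$M, all(n0 >= 0), all(n0 <= spec$N))
  if (!is.null(seed)) set.seed(seed)
  if (record == "sample") {
    if (is.null(sample_times)) sample_times <- seq(0, horizon,
                                                   length.out = 201)
    st <- ssa_sample_cpp(spec$weights, spec$drive, spec$decay,
                         spec$gain$gamma, spec$gain$F0, spec$N,
                         as.integer(n0), sample_times)
    out <- tibble::as_tibble(as.data.frame(st / spec$N))
    names(out) <- spec_state_names(spec)
    out <- tibble::add_column(out, time = sample_times, .before = 1)
    absorbed <- FALSE
  } else {
    ev <- ssa_events_cpp(spec$weights, spec$drive, spec$decay,
                         spec$gain$gamma, spec$gain$F0, spec$N,
                         as.integer(n0), horizon, max_events)
    out <- tibble::as_tibble(as.data.frame(ev$states / spec$N))
    names(out) <- spec_state_names(spec)
    out <- tibble::add_column(out, time = ev$times, .before = 1)
    absorbed <- ev$absorbed
  }
  structure(out, class = c("jump_trajectory", class(out)),
            kind = "jump", seed = seed, spec = spec, absorbed = absorbed)
}

#' Piecewise-deterministic simulation of the depression hybrid model
#'
#' Exact simulation of the one-population birth-death process with
#' `q`-dependent birth rate.  Between jumps the depression variable follows
#' its deterministic (linear-in-`q`) flow exactly; jump times are sampled by
#' thinning against the global rate bound `N F0 + N alpha`, accepting with
#' the instantaneous rates at the candidate time.
#'
#' @param spec A [depression_spec()].
#' @param n0 Initial active count (default `N/2`).
#' @param q0 Initial depression variable in `(0, 1]`.
#' @param horizon Total simulated time.
#' @inheritParams ssa_run
#' @return A `jump_trajectory` tibble with columns `time`, `x`, `q` (or
#'   per-jump records for `record = "events"`).
#' @export
pdmp_run <- function(spec, n0 = NULL, q0 = 1, horizon = 100, seed = NULL,
                     sample_times = NULL, record = c("sample", "events"),
                     max_events = 1e6) {
  stopifnot(inherits(spec, "depression_spec"))
  record <- match.arg(record)
  if (is.null(n0)) n0 <- round(spec$N / 2)
  stopifnot(n0 >= 0, n0 <= spec$N)
  if (!(q0 > 0 && q0 <= 1)) stop("q0 must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (record == "sample") {
    if (is.null(sample_times)) sample_times <- seq(0, horizon,
                                                   length.out = 201)
    st <- pdmp_sample_cpp(spec$N, spec$k_plus, spec$k_minus, spec$w_self,
                          spec$drive, spec$gain$gamma, spec$gain$F0,
                          spec$decay, as.integer(n0), q0, sample_times)
    out <- tibble::tibble(time = sample_times, x = st[, 1], q = st[, 2])
  } else {
    ev <- pdmp_events_cpp(spec$N, spec$k_plus, spec$k_minus, spec$w_self,
                          spec$drive, spec$gain$gamma, spec$gain$F0,
                          spec$decay, as.integer(n0), q0, horizon,
                          max_events)
    out <- tibble::tibble(time = ev$times, x = ev$n / spec$N, q = ev$q)
  }
  structure(out, class = c("jump_trajectory", class(out)),
            kind = "jump", seed = seed, spec = spec, absorbed = FALSE)
}

#' Langevin ensembles of full population oscillators
#'
#' Euler-Maruyama integration of `n_osc` copies of the network (or
#' depression) Langevin equations, all sharing one common Wiener process
#' (handled in Stratonovich form via its Ito drift correction) and each
#' owning independent intrinsic channels.  States are not clipped to
#' `[0, 1]`: the diffusion amplitudes floor the argument of the square root
#' at zero, and the Langevin description is only trusted in the interior.
#'
#' @param spec A [network_spec()] or [depression_spec()] (its `sigma`, `chi`
#'   and `N` set the noise).
#' @param n_osc Number of ensemble members.
#' @param x0 Matrix of initial states (`n_osc` rows); a single state is
#'   recycled.
#' @param horizon,dt,seed,sample_times As in [simulate_phase_ensemble()].
#' @return A `langevin_trajectory` tibble: `time`, `oscillator`, one column
#'   per state component.
#' @export
simulate_langevin_ensemble <- function(spec, n_osc, x0, horizon, dt = 1e-3,
                                       seed = NULL, sample_times = NULL) {
  stopifnot(n_osc >= 1, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  d <- spec_dim(spec)
  x0 <- if (is.matrix(x0)) {
    stopifnot(nrow(x0) == n_osc, ncol(x0) == d)
    x0
  } else {
    stopifnot(length(x0) == d)
    matrix(as.numeric(x0), nrow = n_osc, ncol = d, byrow = TRUE)
  }
  if (is.null(sample_times)) sample_times <- seq(0, horizon,
                                                 length.out = 101)
  eps <- spec_epsilon(spec)
  if (inherits(spec, "depression_spec")) {
    st <- em_depression_cpp(spec$k_plus, spec$k_minus, spec$w_self,
                            spec$drive, spec$gain$gamma, spec$gain$F0,
                            spec$decay, spec$sigma, eps, x0, dt,
                            sample_times)
  } else {
    st <- em_network_cpp(spec$weights, spec$drive, spec$decay,
                         spec$gain$gamma, spec$gain$F0, spec$sigma,
                         spec$chi, eps, x0, dt, sample_times)
  }
  ns <- length(sample_times)
  # columns are oscillator-major blocks of d components
  comp <- spec_state_names(spec)
  long <- lapply(seq_len(d), function(k) {
    as.numeric(st[, (seq_len(n_osc) - 1) * d + k])
  })
  names(long) <- comp
  out <- tibble::tibble(
    time = rep(sample_times, times = n_osc),
    oscillator = rep(seq_len(n_osc), each = ns), !!!long)
  structure(out, class = c("langevin_trajectory", class(out)),
            kind = "diffusion", seed = seed, dt = dt, spec = spec)
}

#' Project Langevin states onto the phase of the limit cycle
#'
#' Nearest-orbit-point projection: each state is assigned the phase of the
#' closest tabulated orbit point.  Adequate for stationary histograms when
#' fluctuations stay near the cycle.
#'
#' @param traj A [simulate_langevin_ensemble()] result.
#' @param lc The deterministic [find_limit_cycle()] of the same model.
#' @return The trajectory tibble with a `theta` column added, classed as
#'   `phase_trajectory`.
#' @export
project_phase <- function(traj, lc) {
  comp <- setdiff(names(traj), c("time", "oscillator"))
  theta <- project_phase_cpp(as.matrix(traj[, comp]), lc_states(lc))
  out <- traj
  out$theta <- theta
  class(out) <- unique(c("phase_trajectory", class(traj)))
  attr(out, "period") <- attr(lc, "period")
  attr(out, "omega") <- attr(lc, "omega")
  out
}

#' Noise channel layout for the generic Euler-Maruyama integrator
#'
#' @param n_independent Number of independent channels per oscillator.
#' @param has_common Whether a single shared channel is present.
#' @param interpretation `"ito"` or `"stratonovich"` for the common channel;
#'   independent (intrinsic) channels are always Ito.
#' @return A `noise_layout` list.
#' @export
noise_layout <- function(n_independent = 0, has_common = FALSE,
                         interpretation = c("stratonovich", "ito")) {
  interpretation <- match.arg(interpretation)
  structure(list(n_independent = n_independent, has_common = has_common,
                 interpretation = interpretation), class = "noise_layout")
}

#' Generic Euler-Maruyama integrator
#'
#' A flexible (pure R) integrator for small systems and validation runs:
#' `d`-dimensional oscillators, an optional shared common channel and
#' `n_independent` per-oscillator channels.  A Stratonovich common channel
#' is converted internally to Ito drift-corrected form using a
#' finite-difference Jacobian of its amplitude.  With all amplitudes zero it
#' reduces to explicit Euler.  For production ensembles use the dedicated
#' compiled paths ([simulate_langevin_ensemble()],
#' [simulate_phase_ensemble()]).
#'
#' @param drift Function `x -> d-vector` (applied per oscillator).
#' @param common Function `x -> d-vector` amplitude of the shared channel,
#'   or `NULL`.
#' @param independent Function `x -> d x n_independent matrix` of
#'   amplitudes, or `NULL`.
#' @param layout A [noise_layout()].
#' @param x0 Initial state, `n_osc x d` matrix (or a vector for one
#'   oscillator).
#' @param horizon,dt Integration horizon and step.
#' @param seed Optional RNG seed.
#' @param keep_every Record every `keep_every`-th step (default: 1).
#' @return A tibble `time`, `oscillator`, state columns `x_1..x_d`.
#' @export
euler_maruyama <- function(drift, common = NULL, independent = NULL,
                           layout = noise_layout(), x0, horizon, dt,
                           seed = NULL, keep_every = 1L) {
  stopifnot(dt > 0, horizon > 0)
  if (!is.null(seed)) set.seed(seed)
  x <- if (is.matrix(x0)) x0 else matrix(x0, nrow = 1)
  n_osc <- nrow(x)
  d <- ncol(x)
  nstep <- floor(horizon / dt)
  if (d == 1L) {
    # scalar systems: vectorised across oscillators (drift/amplitude
    # functions are applied to the whole state vector at once)
    return(em_scalar(drift, common, independent, layout, as.numeric(x),
                     nstep, dt, keep_every))
  }
  eff_drift <- drift
  if (!is.null(common) && layout$interpretation == "stratonovich") {
    # Ito correction (1/2) (Da) a with Da the Jacobian of the amplitude
    eff_drift <- function(x1) {
      a <- common(x1)
      J <- matrix(0, d, d)
      h <- 1e-6
      for (j in seq_len(d)) {
        e <- replace(numeric(d), j, h)
        J[, j] <- (common(x1 + e) - common(x1 - e)) / (2 * h)
      }
      drift(x1) + 0.5 * as.numeric(J %*% a)
    }
  }
  keep <- seq(keep_every, nstep, by = keep_every)
  out <- vector("list", length(keep))
  ki <- 1L
  sq <- sqrt(dt)
  for (s in seq_len(nstep)) {
    dW <- stats::rnorm(1) * sq
    for (m in seq_len(n_osc)) {
      xm <- x[m, ]
      incr <- eff_drift(xm) * dt
      if (!is.null(common) && layout$has_common) {
        incr <- incr + common(xm) * dW
      }
      if (!is.null(independent) && layout$n_independent > 0) {
        B <- independent(xm)
        incr <- incr + as.numeric(B %*% stats::rnorm(layout$n_independent)) *
          sq
      }
      x[m, ] <- xm + incr
      if (any(!is.finite(x[m, ]))) {
        stop(sprintf("non-finite state at step %d, oscillator %d", s, m))
      }
    }
    if (ki <= length(keep) && s == keep[ki]) {
      out[[ki]] <- cbind(time = s * dt, oscillator = seq_len(n_osc), x)
      ki <- ki + 1L
    }
  }
  res <- tibble::as_tibble(as.data.frame(do.call(rbind, out)))
  names(res) <- c("time", "oscillator", paste0("x_", seq_len(d)))
  res
}

# vectorised scalar-system Euler-Maruyama backing euler_maruyama()
em_scalar <- function(drift, common, independent, layout, x, nstep, dt,
                      keep_every) {
  n_osc <- length(x)
  eff_drift <- drift
  if (!is.null(common) && layout$interpretation == "stratonovich") {
    h <- 1e-6
    eff_drift <- function(x1) {
      drift(x1) + 0.5 * common(x1) *
        (common(x1 + h) - common(x1 - h)) / (2 * h)
    }
  }
  keep <- seq(keep_every, nstep, by = keep_every)
  out <- vector("list", length(keep))
  ki <- 1L
  sq <- sqrt(dt)
  for (s in seq_len(nstep)) {
    incr <- eff_drift(x) * dt
    if (!is.null(common) && layout$has_common) {
      incr <- incr + common(x) * (stats::rnorm(1) * sq)
    }
    if (!is.null(independent) && layout$n_independent > 0) {
      incr <- incr + independent(x) * stats::rnorm(n_osc) * sq
    }
    x <- x + incr
    if (any(!is.finite(x))) stop(sprintf("non-finite state at step %d", s))
    if (ki <= length(keep) && s == keep[ki]) {
      out[[ki]] <- cbind(time = s * dt, oscillator = seq_len(n_osc), x)
      ki <- ki + 1L
    }
  }
  res <- tibble::as_tibble(as.data.frame(do.call(rbind, out)))
  names(res) <- c("time", "oscillator", "x_1")
  res
}
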