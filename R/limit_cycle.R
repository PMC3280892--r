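#' Locate the deterministic limit cycle and parameterize it by phase
#'
#' Integrates the mean-field flow past transients, detects the cycle with a
#' Poincare section (first state coordinate crossing the midpoint of its
#' range, upward), refines successive return times by root-finding on a
#' spline of the section coordinate, and resamples the orbit at `n_grid`
#' uniform phases (uniform time, since the asymptotic phase advances at the
#' constant rate `omega = 2*pi/T`).  The phase origin convention is
#' `theta = 0` at the global maximum of the first activity coordinate.
#'
#' @param spec A [network_spec()] or [depression_spec()] in an oscillatory
#'   regime.
#' @param x0 Starting state (default: centre of the state space).
#' @param n_grid Number of uniform phase-grid points (a power of two; the
#'   spectral utilities assume an even count).
#' @param transient_periods Multiples of the linearised period integrated
#'   and discarded before cycle detection.
#' @param tol Relative tolerance on the period estimate across successive
#'   returns.
#' @return A `limit_cycle`: a tibble with column `theta` (grid over
#'   `[-pi, pi)`) and one column per state component, with attributes
#'   `period`, `omega`, `spec`, `n_grid`.
#' @examples
#' \donttest{
#' lc <- find_limit_cycle(preset_spec("ei"))
#' attr(lc, "period")
#' }
#' @export
find_limit_cycle <- function(spec, x0 = NULL, n_grid = 1024,
                             transient_periods = 50, tol = 1e-8) {
  d <- spec_dim(spec)
  if (is.null(x0)) x0 <- rep(0.5, d)
  rhs <- function(t, x, p) list(meanfield_rhs(x, spec))

  # linearised period estimate sets the time scales
  T_lin <- linearised_period(spec)
  xs <- quiet_ode(x0, c(0, transient_periods * T_lin), rhs)
  xs <- as.numeric(xs[nrow(xs), -1])

  # observation window: enough returns to average the period; the window
  # grows geometrically if the linearised estimate undershoots the true
  # period (e.g. relaxation oscillations born far from the focus frequency)
  window <- 12 * T_lin
  for (try in 1:6) {
    tt <- seq(0, window, window / 7200)
    o <- quiet_ode(xs, tt, rhs)
    w <- o[, 2]
    if (diff(range(w)) < 1e-5) {
      stop("trajectory converged to a fixed point; no limit cycle")
    }
    sec <- mean(range(w))
    up <- which(diff(sign(w - sec)) == 2)
    up <- up[up > 3 & up < length(tt) - 4]
    if (length(up) >= 4) break
    xs <- as.numeric(o[nrow(o), -1])
    window <- window * 4
  }
  if (length(up) < 3) stop("no limit cycle found within the horizon")
  cross <- vapply(up, function(i) {
    f <- stats::splinefun(tt[(i - 3):(i + 4)], w[(i - 3):(i + 4)])
    stats::uniroot(function(s) f(s) - sec, c(tt[i], tt[i + 1]),
                   tol = 1e-13)$root
  }, numeric(1))
  periods <- diff(cross)
  # drop the first return (residual transient), average the rest
  if (length(periods) > 2) periods <- periods[-1]
  period <- mean(periods)
  if (stats::sd(periods) / period > tol * 1e4) {
    stop("return times did not settle; no stable limit cycle found")
  }

  # anchor state on the section, then closure-refine the period
  anchor <- as.numeric(o[which.min(abs(tt - cross[length(cross) - 1])), -1])
  o1 <- quiet_ode(anchor, c(0, period), rhs)
  gap <- max(abs(as.numeric(o1[2, -1]) - anchor))
  if (gap > 1e-5) stop("orbit failed to close: not a periodic solution")

  # locate the true (sub-grid) maximum of the first coordinate so the phase
  # origin does not depend on the grid resolution
  o2 <- quiet_ode(anchor, seq(0, period, length.out = 4097), rhs)
  w2 <- o2[-4097, 2]
  im <- which.max(w2)
  tg <- seq(0, period, length.out = 4097)
  sp <- stats::splinefun(tg, c(w2, w2[1]), method = "periodic")
  t_max <- stats::optimize(sp, interval = period * (im + c(-2, 2)) / 4096,
                           maximum = TRUE, tol = 1e-12)$maximum %% period
  x_max <- if (t_max < 1e-12) anchor else
    as.numeric(quiet_ode(anchor, c(0, t_max), rhs)[2, -1])

  # resample n_grid uniform phases starting from the maximum (theta = 0)
  o3 <- quiet_ode(x_max, seq(0, period, length.out = n_grid + 1), rhs)
  orb <- unname(o3[seq_len(n_grid), -1, drop = FALSE])
  orb <- orb[((seq_len(n_grid) - 1 - n_grid / 2) %% n_grid) + 1, ,
             drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(orb))
  names(out) <- spec_state_names(spec)
  out <- tibble::add_column(out, theta = phase_grid(n_grid), .before = 1)
  structure(out, class = c("limit_cycle", class(out)),
            period = period, omega = 2 * pi / period, spec = spec,
            n_grid = n_grid)
}

# period of the linearisation about the (unstable) focus, used only to set
# integration horizons
linearised_period <- function(spec) {
  fp <- tryCatch({
    fps <- find_fixed_points(spec, n_starts = 3)
    if (nrow(fps) == 0) NULL else
      as.numeric(fps[which.max(fps$re_lambda),
                     seq_len(spec_dim(spec)), drop = TRUE])
  }, error = function(e) NULL)
  if (is.null(fp)) return(2 * pi)
  lam <- eigen(jacobian_matrix(fp, spec), only.values = TRUE)$values
  im <- max(abs(Im(lam)))
  if (im < 1e-8) 2 * pi else 2 * pi / im
}

quiet_ode <- function(y, times, func, rtol = 1e-11, atol = 1e-13) {
  suppressWarnings(
    deSolve::ode(y, times, func, parms = NULL, rtol = rtol, atol = atol,
                 maxsteps = 500000)
  )
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("<limit_cycle> period %.6g, omega %.6g, %d grid points\n",
              attr(x, "period"), attr(x, "omega"), attr(x, "n_grid")))
  NextMethod()
}

# matrix of orbit states (rows = grid points), without the theta column
lc_states <- function(lc) {
  as.matrix(lc[, setdiff(names(lc), "theta"), drop = FALSE])
}

# vector field evaluated along the orbit
lc_flow <- function(lc) {
  spec <- attr(lc, "spec")
  t(apply(lc_states(lc), 1, meanfield_rhs, spec = spec))
}

# periodic spline interpolants of the orbit components as functions of
# time measured from theta = -pi
lc_interpolants <- function(lc) {
  Tper <- attr(lc, "period")
  n <- attr(lc, "n_grid")
  st <- lc_states(lc)
  tgrid <- seq(0, Tper, length.out = n + 1)
  lapply(seq_len(ncol(st)), function(k) {
    stats::splinefun(tgrid, c(st[, k], st[1, k]), method = "periodic")
  })
}
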