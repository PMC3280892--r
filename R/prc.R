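#' Infinitesimal phase-resetting curve by the adjoint method
#'
#' The PRC `Z(theta)` is the gradient of asymptotic phase along the limit
#' cycle: the phase shift per unit infinitesimal state perturbation.  It is
#' the unique 2*pi-periodic solution of the adjoint linear equation
#' `dZ/dt = -J(x*(t))^T Z`, normalised by
#' `sum_k Z_k(theta) dx*_k/dt(theta) = omega` (the convention consistent
#' with `dtheta/dt = omega` on the cycle).  Because every non-zero Floquet
#' exponent of adjoint solutions is positive, backward integration contracts
#' onto the periodic solution; the iteration renormalises once per period
#' and stops when the per-period change falls below `tol`.
#'
#' @param lc A [find_limit_cycle()] result.
#' @param tol Per-period sup-norm change declaring convergence.
#' @param max_periods Maximum backward periods before giving up.
#' @return A `prc`: tibble with `theta` and one `Z_*` column per state
#'   component, attributes `period`, `omega`, `n_grid`, `spec`.
#' @examples
#' \donttest{
#' lc <- find_limit_cycle(preset_spec("ei"))
#' prc <- compute_prc(lc)
#' }
#' @export
compute_prc <- function(lc, tol = 1e-10, max_periods = 200) {
  stopifnot(inherits(lc, "limit_cycle"))
  spec <- attr(lc, "spec")
  Tper <- attr(lc, "period")
  omega <- attr(lc, "omega")
  n <- attr(lc, "n_grid")
  d <- spec_dim(spec)
  interp <- lc_interpolants(lc)
  orbit_at <- function(tm) vapply(interp, function(f) f(tm), numeric(1))
  adj <- function(s, Z, p) {
    x <- orbit_at((-s) %% Tper)
    list(as.numeric(t(jacobian_matrix(x, spec)) %*% Z))
  }
  st <- lc_states(lc)
  f0 <- meanfield_rhs(st[1, ], spec)
  Z <- rep(1, d)
  Z <- Z * omega / sum(Z * f0)
  converged <- FALSE
  for (r in seq_len(max_periods)) {
    Zprev <- Z
    Z <- as.numeric(quiet_ode(Z, c(0, Tper), adj)[2, -1])
    Z <- Z * omega / sum(Z * f0)
    if (max(abs(Z - Zprev)) < tol * max(1, max(abs(Z)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("adjoint iteration did not converge after ", max_periods,
         " periods; residual Floquet contraction too slow")
  }
  oZ <- quiet_ode(Z, seq(0, Tper, length.out = n + 1), adj)
  Zg <- unname(oZ[seq_len(n), -1, drop = FALSE])
  Zg <- Zg[c(1, seq(n, 2)), , drop = FALSE] # backward time -> forward phase
  out <- tibble::as_tibble(as.data.frame(Zg))
  names(out) <- paste0("Z_", sub("^x_?", "", spec_state_names(spec)))
  if (inherits(spec, "depression_spec")) names(out) <- c("Z_x", "Z_q")
  out <- tibble::add_column(out, theta = phase_grid(n), .before = 1)
  structure(out, class = c("prc", class(out)),
            period = Tper, omega = omega, spec = spec, n_grid = n)
}

#' @export
print.prc <- function(x, ...) {
  cat(sprintf("<prc> %d grid points, omega %.6g\n",
              attr(x, "n_grid"), attr(x, "omega")))
  NextMethod()
}

# matrix of PRC components aligned with the limit-cycle grid
prc_components <- function(prc) {
  as.matrix(prc[, setdiff(names(prc), "theta"), drop = FALSE])
}

#' Direct (perturbation) measurement of the PRC
#'
#' Brute-force oracle for [compute_prc()]: kick one state coordinate by a
#' small pulse at a given phase, integrate perturbed and unperturbed copies
#' for many periods, and read the asymptotic phase shift off the difference
#' in section-crossing times.  Slow; intended for validation at a handful of
#' phases.
#'
#' @param lc A [find_limit_cycle()] result.
#' @param theta Phase at which the pulse is applied.
#' @param component State coordinate index receiving the pulse.
#' @param delta Pulse amplitude.
#' @param settle_periods Periods integrated before reading the shift.
#' @return Estimated `Z_component(theta)` (shift divided by `delta`).
#' @export
prc_direct <- function(lc, theta, component = 1, delta = 1e-4,
                       settle_periods = 20) {
  spec <- attr(lc, "spec")
  Tper <- attr(lc, "period")
  omega <- attr(lc, "omega")
  rhs <- function(t, x, p) list(meanfield_rhs(x, spec))
  st <- lc_states(lc)
  j <- which.min(abs(circ_diff(lc$theta, theta)))
  x0 <- st[j, ]
  sec <- mean(range(st[, 1]))
  crossing_time <- function(x) {
    horizon <- (settle_periods + 2) * Tper
    tt <- seq(settle_periods * Tper, horizon, Tper / 2000)
    o <- quiet_ode(x, c(0, tt), rhs)
    w <- o[-1, 2]
    tt2 <- tt
    up <- which(diff(sign(w - sec)) == 2)
    i <- up[1]
    f <- stats::splinefun(tt2[(i - 3):(i + 4)], w[(i - 3):(i + 4)])
    stats::uniroot(function(s) f(s) - sec, c(tt2[i], tt2[i + 1]),
                   tol = 1e-13)$root
  }
  t_ref <- crossing_time(x0)
  xp <- x0
  xp[component] <- xp[component] + delta
  t_pert <- crossing_time(xp)
  shift <- circ_diff(omega * (t_ref - t_pert), 0)
  shift / delta
}
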