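#' Bifurcation curves of the two-population network
#'
#' For the E-I pair at unit gain the logistic identity `F' = F(1-F)` makes
#' the Jacobian at an equilibrium `(x_E*, x_I*)` a function of
#' `f_k = x_k*(1 - x_k*)` alone, so bifurcation loci can be traced in
#' fixed-point coordinates and mapped to the drive plane through the
#' equilibrium conditions `h_k = logit(x_k*) - sum_l w_kl x_l*`.
#'
#' `hopf_curves()` traces the Hopf locus `Tr J = 0`, `Det J > 0`.  Because
#' the trace is quadratic in the fixed-point coordinate there are two
#' branches of admissible `x_I*` for each `x_E*`.  `fold_curves()` traces
#' the fold (saddle-node) locus `Det J = 0`, `Tr J < 0`, solving the
#' determinant condition for `f_I` at each `x_E*`.
#'
#' @param spec A two-population [network_spec()] with unit gain
#'   (`gamma = F0 = 1`); only the weights are used.
#' @param x_E Sweep of excitatory fixed-point values in (0, 1).
#' @return A tibble with columns `branch`, `x_E`, `x_I`, `h_E`, `h_I`,
#'   `tr`, `det`.  Empty (with a warning) if the sweep contains no
#'   admissible points.
#' @export
hopf_curves <- function(spec, x_E = seq(0.01, 0.99, length.out = 400)) {
  stopifnot(inherits(spec, "network_spec"), spec$M == 2)
  if (spec$gain$gamma != 1 || spec$gain$F0 != 1) {
    stop("closed-form bifurcation curves require gamma = F0 = 1")
  }
  if (length(x_E) == 0) {
    warning("empty sweep range")
    return(tibble::tibble())
  }
  W <- spec$weights
  rows <- list()
  for (xe in x_E) {
    fE <- xe * (1 - xe)
    fI <- (sum(spec$decay) - W[1, 1] * fE) / W[2, 2]
    if (!is.finite(fI) || fI <= 0 || fI > 0.25) next
    for (branch in 1:2) {
      xi <- (1 + c(-1, 1)[branch] * sqrt(1 - 4 * fI)) / 2
      J <- matrix(c(-spec$decay[1] + W[1, 1] * fE, W[1, 2] * fE,
                    W[2, 1] * fI, -spec$decay[2] + W[2, 2] * fI),
                  2, 2, byrow = TRUE)
      dt <- det(J)
      if (dt <= 0) next
      rows[[length(rows) + 1]] <- c(branch, xe, xi,
                                    stats::qlogis(xe) - W[1, 1] * xe - W[1, 2] * xi,
                                    stats::qlogis(xi) - W[2, 1] * xe - W[2, 2] * xi,
                                    sum(diag(J)), dt)
    }
  }
  if (length(rows) == 0) {
    warning("no admissible Hopf points in sweep range")
    return(tibble::tibble())
  }
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  names(out) <- c("branch", "x_E", "x_I", "h_E", "h_I", "tr", "det")
  out
}

#' @rdname hopf_curves
#' @export
fold_curves <- function(spec, x_E = seq(0.01, 0.99, length.out = 400)) {
  stopifnot(inherits(spec, "network_spec"), spec$M == 2)
  if (spec$gain$gamma != 1 || spec$gain$F0 != 1) {
    stop("closed-form bifurcation curves require gamma = F0 = 1")
  }
  if (length(x_E) == 0) {
    warning("empty sweep range")
    return(tibble::tibble())
  }
  W <- spec$weights
  aE <- spec$decay[1]; aI <- spec$decay[2]
  rows <- list()
  for (xe in x_E) {
    fE <- xe * (1 - xe)
    # det = (-aE + wEE fE)(-aI + wII fI) - wEI wIE fE fI = 0, linear in fI
    num <- aI * (-aE + W[1, 1] * fE)
    den <- (-aE + W[1, 1] * fE) * W[2, 2] - W[1, 2] * W[2, 1] * fE
    fI <- num / den
    if (!is.finite(fI) || fI <= 0 || fI > 0.25) next
    for (branch in 1:2) {
      xi <- (1 + c(-1, 1)[branch] * sqrt(1 - 4 * fI)) / 2
      J <- matrix(c(-aE + W[1, 1] * fE, W[1, 2] * fE,
                    W[2, 1] * fI, -aI + W[2, 2] * fI), 2, 2, byrow = TRUE)
      tr <- sum(diag(J))
      if (tr >= 0) next
      rows[[length(rows) + 1]] <- c(branch, xe, xi,
                                    stats::qlogis(xe) - W[1, 1] * xe - W[1, 2] * xi,
                                    stats::qlogis(xi) - W[2, 1] * xe - W[2, 2] * xi,
                                    tr, det(J))
    }
  }
  if (length(rows) == 0) {
    warning("no admissible fold points in sweep range")
    return(tibble::tibble())
  }
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  names(out) <- c("branch", "x_E", "x_I", "h_E", "h_I", "tr", "det")
  out
}

#' Hopf points of the depression model along the depletion rate
#'
#' Follows the unique fixed-point branch of the depression model as the
#' depletion rate `k_minus` sweeps, computing
#' `q* = k_plus / (k_plus + k_minus x*)` and the Jacobian eigenvalues, and
#' refines every sign change of the leading real part by bisection.
#'
#' @param spec A [depression_spec()]; its own `k_minus` is ignored during
#'   the sweep.
#' @param k_minus Sweep of depletion rates.
#' @return A list with `branch` (tibble `k_minus`, `x`, `q`, `re_lambda`,
#'   `im_lambda`) and `hopf` (numeric vector of bifurcation points).
#' @export
hopf_points_depression <- function(spec,
                                   k_minus = seq(0.01, 1, length.out = 200)) {
  stopifnot(inherits(spec, "depression_spec"))
  if (length(k_minus) == 0) {
    warning("empty sweep range")
    return(list(branch = tibble::tibble(), hopf = numeric(0)))
  }
  lead_re <- function(km) {
    sp <- spec
    sp$k_minus <- km
    fp <- depression_fixed_point(sp)
    lam <- eigen(jacobian_matrix(fp, sp), only.values = TRUE)$values
    i <- which.max(Re(lam))
    c(fp, Re(lam[i]), abs(Im(lam[i])))
  }
  br <- t(vapply(k_minus, lead_re, numeric(4)))
  branch <- tibble::tibble(k_minus = k_minus, x = br[, 1], q = br[, 2],
                           re_lambda = br[, 3], im_lambda = br[, 4])
  flips <- which(diff(sign(branch$re_lambda)) != 0)
  hopf <- vapply(flips, function(i) {
    stats::uniroot(function(km) lead_re(km)[3],
                   c(k_minus[i], k_minus[i + 1]), tol = 1e-10)$root
  }, numeric(1))
  list(branch = branch, hopf = hopf)
}

# unique fixed point of the depression model: solve the scalar equation
# x = F(w q(x) x + h) with q(x) = k+ / (k+ + k- x) by bisection + refinement
depression_fixed_point <- function(spec) {
  gfun <- function(x) {
    q <- spec$k_plus / (spec$k_plus + spec$k_minus * x)
    sigmoid_gain(spec$w_self * q * x + spec$drive, spec$gain) / spec$decay - x
  }
  lo <- 1e-12; hi <- spec$gain$F0 / spec$decay
  xs <- seq(lo, hi, length.out = 400)
  gv <- vapply(xs, gfun, numeric(1))
  i <- which(diff(sign(gv)) != 0)[1]
  if (is.na(i)) stop("no fixed point found on the branch")
  x <- stats::uniroot(gfun, c(xs[i], xs[i + 1]), tol = 1e-14)$root
  q <- spec$k_plus / (spec$k_plus + spec$k_minus * x)
  c(x = x, q = q)
}
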