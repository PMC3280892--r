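#' Cycle-averaged noise correlation functions
#'
#' Averaging the ensemble Fokker-Planck equation over one cycle leaves the
#' slow phase-difference dynamics governed by two circular correlation
#' functions of the phase sensitivities:
#' `g(phi) = (2*pi)^-1 \oint alpha(theta) alpha(theta + phi) dtheta`
#' (common channel) and
#' `h(phi) = (2*pi)^-1 \oint sum_k beta_k(theta) beta_k(theta + phi) dtheta`
#' (independent channels).  Both are computed by circular convolution on the
#' grid (spectral method, exact for band-limited tabulations); both are even
#' in `phi`, and `g(0) >= g(phi)` everywhere (Cauchy-Schwarz).
#'
#' @param law A [build_phase_law()] result.
#' @return A `phase_correlation` tibble with columns `phi`, `g`, `h`;
#'   attributes `omega`, `epsilon`, `sigma`, `spec`.
#' @export
correlation_functions <- function(law) {
  stopifnot(inherits(law, "phase_law"))
  g <- circ_xcorr(law$common, law$common)
  beta_cols <- grep("^beta_", names(law), value = TRUE)
  h <- Reduce(`+`, lapply(beta_cols, function(cn) {
    circ_xcorr(law[[cn]], law[[cn]])
  }))
  out <- tibble::tibble(phi = law$theta, g = g, h = h)
  structure(out, class = c("phase_correlation", class(out)),
            omega = attr(law, "omega"), epsilon = attr(law, "epsilon"),
            sigma = attr(law, "sigma"), spec = attr(law, "spec"),
            n_grid = attr(law, "n_grid"))
}

#' Stationary distribution of the pairwise phase difference
#'
#' The averaged Fokker-Planck equation for the phase difference of two
#' oscillators has the stationary density
#' `Phi0(phi) = Gamma0 / (sigma^2 (g(0) - g(phi)) + eps^2 h(0))`,
#' normalised to unit circular integral.  Limits: with `sigma = 0` and
#' `eps > 0` the density is exactly uniform (complete desynchronization);
#' as `eps -> 0` at fixed `sigma > 0` the density diverges at `phi = 0`
#' (complete synchronization by the common noise); intrinsic noise broadens
#' the peak through the term `eps^2 h(0) = h(0)/N`.
#'
#' @param corr A [correlation_functions()] result.
#' @param epsilon Intrinsic noise strength `N^(-1/2)` (default: from the
#'   law's spec).
#' @param sigma Common noise strength (default: from the law's spec).
#' @return A `phase_dist` tibble with columns `phi`, `g`, `h`, `phi0`;
#'   attributes `gamma0`, `epsilon`, `sigma`, and `peaks` (from
#'   [find_peaks()] with the default prominence).
#' @export
stationary_distribution <- function(corr, epsilon = NULL, sigma = NULL) {
  stopifnot(inherits(corr, "phase_correlation"))
  if (is.null(epsilon)) epsilon <- attr(corr, "epsilon")
  if (is.null(sigma)) sigma <- attr(corr, "sigma")
  stopifnot(epsilon >= 0, sigma >= 0)
  if (epsilon == 0 && sigma == 0) {
    stop("at least one noise source must be present")
  }
  n <- nrow(corr)
  i0 <- which.min(abs(corr$phi))
  g0 <- corr$g[i0]
  h0 <- corr$h[i0]
  if (sigma == 0) {
    phi0 <- rep(1 / (2 * pi), n)
    gamma0 <- epsilon^2 * h0 / (2 * pi)
  } else {
    denom <- sigma^2 * (g0 - corr$g) + epsilon^2 * h0
    if (any(denom <= 0)) {
      if (epsilon == 0) {
        stop("degenerate density: g(0) - g(phi) vanishes with epsilon = 0")
      }
      stop("non-positive denominator in stationary density")
    }
    raw <- 1 / denom
    z <- sum(raw) * 2 * pi / n
    phi0 <- raw / z
    gamma0 <- 1 / z
  }
  out <- tibble::tibble(phi = corr$phi, g = corr$g, h = corr$h, phi0 = phi0)
  out <- structure(out, class = c("phase_dist", class(out)),
                   gamma0 = gamma0, epsilon = epsilon, sigma = sigma,
                   g0 = g0, h0 = h0, omega = attr(corr, "omega"),
                   spec = attr(corr, "spec"))
  attr(out, "peaks") <- find_peaks(out)
  out
}

#' Circular peak (cluster) detection
#'
#' Local maxima of the stationary density on the circle, filtered by
#' topographic prominence: a peak is kept when its height stands at least
#' `prominence` times the density range above the highest saddle separating
#' it from any higher peak.  The number of retained peaks is the predicted
#' number of phase clusters in the ensemble.
#'
#' @param dist A [stationary_distribution()] result (or any tibble with
#'   `phi` and `phi0` columns).
#' @param prominence Minimum prominence as a fraction of the density range
#'   (default 0.02, low enough to keep faint secondary peaks).
#' @return A tibble `location`, `height`, `prominence` sorted by height.
#' @export
find_peaks <- function(dist, prominence = 0.02) {
  p <- dist$phi0
  phi <- dist$phi
  n <- length(p)
  rng <- diff(range(p))
  if (rng == 0) {
    return(tibble::tibble(location = numeric(0), height = numeric(0),
                          prominence = numeric(0)))
  }
  left <- p[((seq_len(n) - 2) %% n) + 1]
  right <- p[(seq_len(n) %% n) + 1]
  cand <- which(p > left & p >= right)
  if (length(cand) == 0) return(tibble::tibble(location = numeric(0),
                                               height = numeric(0),
                                               prominence = numeric(0)))
  prom <- vapply(cand, function(j) {
    higher <- cand[p[cand] > p[j]]
    if (length(higher) == 0) return(rng) # global maximum
    # walk both ways to the nearest higher peak, track the minimum en route
    saddle <- -Inf
    for (dir in c(1L, -1L)) {
      i <- j
      lo <- p[j]
      repeat {
        i <- ((i - 1 + dir) %% n) + 1
        lo <- min(lo, p[i])
        if (p[i] > p[j]) break
        if (i == j) break
      }
      saddle <- max(saddle, lo)
    }
    p[j] - saddle
  }, numeric(1))
  keep <- prom >= prominence * rng
  out <- tibble::tibble(location = phi[cand[keep]], height = p[cand[keep]],
                        prominence = prom[keep])
  out[order(-out$height), ]
}

#' Cauchy (Lorentzian) approximation near the synchronized peak
#'
#' Expanding `g` to second order about `phi = 0` turns the stationary
#' density into a Lorentzian with squared half-width
#' `w^2 = 2 eps^2 h(0) / (sigma^2 |g''(0)|)` -- the half-width grows
#' linearly in `eps` at fixed `sigma`.  `g''(0)` is obtained by spectral
#' differentiation.
#'
#' @param dist A [stationary_distribution()] result with its maximum at 0.
#' @return A list: `half_width`, `gpp0` (`g''(0)`), and `approx`, a tibble
#'   `phi`, `phi0_cauchy` normalised to unit circular integral.
#' @export
cauchy_approximation <- function(dist) {
  n <- nrow(dist)
  i0 <- which.min(abs(dist$phi))
  if (which.max(dist$phi0) != i0) {
    stop("density maximum is not at phi = 0; Cauchy approximation invalid")
  }
  gpp <- spectral_deriv(spectral_deriv(dist$g))
  gpp0 <- gpp[i0]
  if (gpp0 >= 0) stop("g''(0) >= 0: no local quadratic decay at phi = 0")
  eps <- attr(dist, "epsilon")
  sigma <- attr(dist, "sigma")
  w2 <- 2 * eps^2 * attr(dist, "h0") / (sigma^2 * abs(gpp0))
  raw <- 1 / (dist$phi^2 + w2)
  z <- sum(raw) * 2 * pi / n
  list(half_width = sqrt(w2), gpp0 = gpp0,
       approx = tibble::tibble(phi = dist$phi, phi0_cauchy = raw / z))
}

#' Histogram of pairwise phase differences
#'
#' Pools the circular differences of all unordered oscillator pairs across
#' the retained snapshots of a phase trajectory, after discarding a burn-in
#' fraction, and bins them on `[-pi, pi)`.  The density is normalised so
#' that bin sums times the bin width integrate to one.
#'
#' @param traj A `phase_trajectory` (from [simulate_phase_ensemble()] or
#'   [project_phase()]), or a list of them (pooled).
#' @param n_bins Number of bins (default 50).
#' @param burn_in Fraction of early snapshot times discarded (default 0.5).
#' @return A `phase_histogram` tibble: `phi` (bin midpoints), `density`;
#'   attribute `n_samples`.
#' @export
histogram_phase_differences <- function(traj, n_bins = 50, burn_in = 0.5) {
  trajs <- if (inherits(traj, "phase_trajectory")) list(traj) else traj
  diffs <- unlist(lapply(trajs, function(tr) {
    stopifnot("theta" %in% names(tr))
    if (length(unique(tr$oscillator)) < 2) {
      stop("need at least two oscillators for pairwise differences")
    }
    tcut <- stats::quantile(unique(tr$time), burn_in)
    keep <- tr[tr$time >= tcut, ]
    unlist(lapply(split(keep$theta, keep$time), function(ph) {
      dd <- outer(ph, ph, `-`)
      wrap_phase(dd[upper.tri(dd)])
    }), use.names = FALSE)
  }), use.names = FALSE)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  counts <- graphics::hist(diffs, breaks = breaks, plot = FALSE)$counts
  width <- 2 * pi / n_bins
  out <- tibble::tibble(phi = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                        density = counts / (sum(counts) * width))
  structure(out, class = c("phase_histogram", class(out)),
            n_samples = length(diffs))
}

#' L1 distance between a histogram and the analytic density
#'
#' Bin-averages the analytic stationary density over the histogram's bins
#' (so both sides are piecewise-constant on the same partition) and returns
#' the integrated absolute difference.
#'
#' @param hist A [histogram_phase_differences()] result.
#' @param dist A [stationary_distribution()] result.
#' @return Scalar L1 distance (0 = identical; 2 = disjoint).
#' @export
l1_distance <- function(hist, dist) {
  n_bins <- nrow(hist)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(dist$phi, breaks, rightmost.closed = TRUE)
  ana <- vapply(seq_len(n_bins), function(b) mean(dist$phi0[bin == b]),
                numeric(1))
  ana <- ana / (sum(ana) * 2 * pi / n_bins)
  sum(abs(hist$density - ana)) * 2 * pi / n_bins
}
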