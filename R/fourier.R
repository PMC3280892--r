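# Circular-grid utilities.  All tabulated phase functions live on the
# uniform grid theta_j = -pi + 2*pi*j/n, j = 0..n-1.

#' Uniform circular phase grid
#'
#' @param n Number of grid points.
#' @return Numeric vector of phases in `[-pi, pi)`.
#' @export
phase_grid <- function(n) -pi + 2 * pi * seq(0, n - 1) / n

# circular cross-correlation via FFT:
# (1/2pi) \oint f(theta) g(theta + phi) dtheta  on the grid, exact for
# band-limited tabulations.  Returns values on the same [-pi, pi) grid.
circ_xcorr <- function(f, g) {
  n <- length(f)
  lagged <- Re(stats::fft(Conj(stats::fft(f)) * stats::fft(g),
                          inverse = TRUE)) / n^2
  # lagged[m+1] corresponds to offset phi = 2*pi*m/n, m = 0..n-1;
  # remap so that index j corresponds to phi_j = -pi + 2*pi*j/n
  shift_half(lagged)
}

# direct O(n^2) quadrature of the same quantity (test oracle)
circ_xcorr_direct <- function(f, g) {
  n <- length(f)
  out <- vapply(seq(0, n - 1), function(m) {
    mean(f * g[((seq(0, n - 1) + m) %% n) + 1])
  }, numeric(1))
  shift_half(out)
}

# move the phi = 0 origin from index 1 to index n/2 + 1 ([-pi,pi) layout)
shift_half <- function(v) {
  n <- length(v)
  h <- n / 2
  c(v[(h + 1):n], v[1:h])
}

# inverse of shift_half: index 1 <-> phi = 0 layout
unshift_half <- function(v) {
  n <- length(v)
  h <- n / 2
  c(v[(h + 1):n], v[1:h])
}

# spectral derivative of a periodic tabulation on the [-pi,pi) grid
spectral_deriv <- function(f) {
  n <- length(f)
  k <- c(0:(n / 2 - 1), 0, (-n / 2 + 1):-1)
  Re(stats::fft(1i * k * stats::fft(f), inverse = TRUE)) / n
}

# trigonometric (Fourier) interpolation of a tabulation on the [-pi,pi)
# grid; returns a function of theta (vectorised), exactly 2*pi-periodic.
trig_interp <- function(f) {
  n <- length(f)
  co <- stats::fft(f) / n
  k <- c(0:(n / 2 - 1), -n / 2, (-n / 2 + 1):-1)
  function(theta) {
    # grid index 1 corresponds to theta = -pi
    th <- theta + pi
    vapply(th, function(t1) Re(sum(co * exp(1i * k * t1))), numeric(1))
  }
}

# wrap angles to [-pi, pi)
wrap_phase <- function(theta) {
  w <- (theta + pi) %% (2 * pi)
  w - pi
}

# minimal signed circular difference a - b
circ_diff <- function(a, b) wrap_phase(a - b)
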