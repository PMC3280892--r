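ei_corr <- correlation_functions(ei_law)
dep_corr <- correlation_functions(dep_law)

test_that("g and h are even with the global maximum of g at zero", {
  for (corr in list(ei_corr, dep_corr)) {
    n <- nrow(corr)
    i0 <- which.min(abs(corr$phi))
    # evenness: value at phi equals value at -phi (-pi maps to itself)
    flip <- c(1, n:2)
    expect_lt(max(abs(corr$g - corr$g[flip])), 1e-10)
    expect_lt(max(abs(corr$h - corr$h[flip])), 1e-10)
    expect_true(all(corr$g[i0] >= corr$g - 1e-12))
  }
})

test_that("spectral and direct quadrature of g, h agree to 1e-10", {
  lc <- find_limit_cycle(preset_spec("ei"), n_grid = 256)
  law <- build_phase_law(lc, compute_prc(lc))
  g_fft <- popsync:::circ_xcorr(law$common, law$common)
  g_dir <- popsync:::circ_xcorr_direct(law$common, law$common)
  expect_lt(max(abs(g_fft - g_dir)), 1e-10)
  h_fft <- popsync:::circ_xcorr(law$beta_E, law$beta_E) +
    popsync:::circ_xcorr(law$beta_I, law$beta_I)
  h_dir <- popsync:::circ_xcorr_direct(law$beta_E, law$beta_E) +
    popsync:::circ_xcorr_direct(law$beta_I, law$beta_I)
  expect_lt(max(abs(h_fft - h_dir)), 1e-10)
})

test_that("the stationary density is a normalized even density", {
  for (corr in list(ei_corr, dep_corr)) {
    d <- stationary_distribution(corr)
    n <- nrow(d)
    expect_true(all(d$phi0 >= 0))
    expect_equal(sum(d$phi0) * 2 * pi / n, 1, tolerance = 1e-8)
    flip <- c(1, n:2)
    expect_lt(max(abs(d$phi0 - d$phi0[flip])), 1e-10)
  }
})

test_that("without common noise the phase difference is exactly uniform", {
  d <- stationary_distribution(ei_corr, sigma = 0)
  expect_true(all(d$phi0 == 1 / (2 * pi)))
  expect_error(stationary_distribution(ei_corr, epsilon = 0, sigma = 0),
               "noise")
})

test_that("vanishing intrinsic noise sharpens the peak without bound", {
  i0 <- which.min(abs(ei_corr$phi))
  heights <- vapply(10^seq(-2, -6, by = -1), function(eps) {
    stationary_distribution(ei_corr, epsilon = eps)$phi0[i0]
  }, numeric(1))
  expect_true(all(diff(heights) > 0))
  expect_gt(heights[5] / heights[1], 100)
})

test_that("the peak height grows with system size at fixed drive noise", {
  i0 <- which.min(abs(ei_corr$phi))
  heights <- vapply(c(1e3, 1e4, 1e5), function(N) {
    stationary_distribution(ei_corr, epsilon = 1 / sqrt(N))$phi0[i0]
  }, numeric(1))
  expect_true(all(diff(heights) > 0))
})

test_that("symmetric drive gives a single cluster at zero difference", {
  for (corr in list(ei_corr, dep_corr)) {
    pk <- attr(stationary_distribution(corr), "peaks")
    expect_equal(nrow(pk), 1)
    expect_equal(pk$location, 0, tolerance = 2 * pi / 1024 + 1e-12)
  }
})

test_that("peak detection honours circular topology and prominence", {
  phi <- phase_grid(512)
  # a dominant peak at zero plus two shallow satellites near +-2pi/3
  dens <- 1 + cos(phi) + 0.45 * cos(3 * phi)
  dens <- dens - min(dens) + 0.01
  dens <- dens / (sum(dens) * 2 * pi / 512)
  d <- tibble::tibble(phi = phi, phi0 = dens)
  pk_all <- find_peaks(d, prominence = 0.001)
  pk_main <- find_peaks(d, prominence = 0.9)
  expect_equal(nrow(pk_all), 3)
  expect_equal(nrow(pk_main), 1)
  expect_equal(pk_main$location, 0, tolerance = 0.05)
  # constant density: no peaks rather than everything
  flat <- tibble::tibble(phi = phi, phi0 = rep(1 / (2 * pi), 512))
  expect_equal(nrow(find_peaks(flat)), 0)
})

test_that("Cauchy approximation matches the density near its peak", {
  d <- stationary_distribution(ei_corr) # sigma = 0.08, N = 1e5
  ca <- cauchy_approximation(d)
  win <- abs(d$phi) < ca$half_width
  # compare shapes with matched normalisation over the window
  scale <- d$phi0[which.min(abs(d$phi))] /
    ca$approx$phi0_cauchy[which.min(abs(d$phi))]
  rel <- abs(d$phi0[win] - scale * ca$approx$phi0_cauchy[win]) / d$phi0[win]
  expect_lt(max(rel), 0.1)
})

test_that("Cauchy half-width scales linearly in the intrinsic noise", {
  eps <- 10^seq(-4, -2, length.out = 7)
  w <- vapply(eps, function(e) {
    cauchy_approximation(stationary_distribution(ei_corr,
                                                 epsilon = e))$half_width
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(w) ~ log(eps)))[2]
  expect_equal(unname(slope), 1, tolerance = 0.05)
})

test_that("histogram utility handles degenerate and uniform inputs", {
  mk_traj <- function(theta_mat) {
    n_osc <- ncol(theta_mat)
    tb <- tibble::tibble(
      time = rep(seq_len(nrow(theta_mat)), times = n_osc),
      oscillator = rep(seq_len(n_osc), each = nrow(theta_mat)),
      theta = as.numeric(theta_mat))
    structure(tb, class = c("phase_trajectory", class(tb)))
  }
  # identical phases: all mass in the bin containing zero
  h1 <- histogram_phase_differences(mk_traj(matrix(1.3, 10, 8)),
                                    burn_in = 0)
  expect_equal(sum(h1$density > 0), 1)
  expect_lt(abs(h1$phi[h1$density > 0]), 2 * pi / 50)
  # independent uniform phases: flat (chi-square at 1%)
  set.seed(77)
  # one independent pair per snapshot keeps the chi-square test valid
  h2 <- histogram_phase_differences(
    mk_traj(matrix(stats::runif(2 * 2000, -pi, pi), 2000, 2)), burn_in = 0)
  counts <- h2$density * (2 * pi / 50) * attr(h2, "n_samples")
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
  expect_error(histogram_phase_differences(mk_traj(matrix(0, 5, 1))),
               "two oscillators")
})
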