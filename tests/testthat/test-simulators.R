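# one-population spec with the gain silenced: pure death process
death_spec <- function(N) {
  network_spec(weights = matrix(0, 1, 1), drive = -40, decay = 1,
               gain = gain_params(1, 1), N = N)
}

test_that("SSA reproduces the pure death process", {
  spec <- death_spec(20)
  tsamp <- c(0.5, 1, 2)
  set.seed(101)
  runs <- replicate(2000, {
    ssa_run(spec, n0 = 20, sample_times = tsamp)$x_1 * 20
  })
  for (i in seq_along(tsamp)) {
    p <- exp(-tsamp[i])
    se <- sqrt(20 * p * (1 - p)) / sqrt(2000)
    expect_lt(abs(mean(runs[i, ]) - 20 * p), 3 * se + 1e-9)
  }
})

test_that("occupations never leave the lattice and absorbing states flag", {
  spec <- network_spec(weights = matrix(c(5, -3, 4, -1), 2, 2, byrow = TRUE),
                       drive = c(1, -1), N = 30)
  set.seed(3)
  for (r in 1:100) {
    tr <- ssa_run(spec, n0 = c(0, 30), horizon = 3,
                  sample_times = seq(0, 3, 0.1))
    expect_true(all(tr$x_E >= 0 & tr$x_E <= 1))
    expect_true(all(tr$x_I >= 0 & tr$x_I <= 1))
  }
  # with the gain fully silenced and no active neurons, the total rate is
  # exactly zero: an absorbing state
  silent <- network_spec(weights = matrix(0, 1, 1), drive = -Inf, N = 10)
  dead <- ssa_run(silent, n0 = 0, horizon = 5, record = "events")
  expect_true(attr(dead, "absorbed"))
})

test_that("identical seeds reproduce identical trajectories everywhere", {
  spec <- preset_spec("ei", N = 200)
  a <- ssa_run(spec, horizon = 2, seed = 42)
  b <- ssa_run(spec, horizon = 2, seed = 42)
  expect_identical(a, b)
  expect_false(identical(ssa_run(spec, horizon = 2, seed = 43)$x_E, a$x_E))
  dspec <- preset_spec("depression", N = 200)
  expect_identical(pdmp_run(dspec, horizon = 20, seed = 7),
                   pdmp_run(dspec, horizon = 20, seed = 7))
  expect_identical(
    simulate_phase_ensemble(ei_law, 5, horizon = 10, seed = 9),
    simulate_phase_ensemble(ei_law, 5, horizon = 10, seed = 9))
  expect_identical(
    simulate_langevin_ensemble(ei_spec, 3, c(0.5, 0.5), horizon = 2,
                               seed = 5),
    simulate_langevin_ensemble(ei_spec, 3, c(0.5, 0.5), horizon = 2,
                               seed = 5))
})

test_that("SSA ensemble mean tracks the mean-field cycle at large N", {
  spec <- preset_spec("ei", N = 1e4)
  st <- popsync:::lc_states(ei_lc)
  Tper <- attr(ei_lc, "period")
  n0 <- round(st[1, ] * spec$N)
  tsamp <- seq(0, Tper, length.out = 21)
  ref <- popsync:::quiet_ode(n0 / spec$N, tsamp,
                             function(t, x, p) list(meanfield_rhs(x, spec)))
  set.seed(11)
  runs <- replicate(200,
                    as.matrix(ssa_run(spec, n0 = n0,
                                      sample_times = tsamp)[, -1]),
                    simplify = "array")
  mn <- apply(runs, c(1, 2), mean)
  expect_lt(max(abs(mn - ref[, -1])), 5 / sqrt(spec$N))
})

test_that("depression variable follows its closed-form recovery", {
  # births silenced (very negative drive), deaths impossible (n0 = 0):
  # q(t) = 1 - (1 - q0) exp(-k+ t)
  spec <- depression_spec(k_plus = 0.05, k_minus = 0, h = -10,
                          gain = gain_params(20, 1), N = 50)
  tsamp <- seq(0, 40, 1)
  tr <- pdmp_run(spec, n0 = 0, q0 = 0.3, sample_times = tsamp, seed = 1)
  expect_equal(tr$q, 1 - 0.7 * exp(-0.05 * tsamp), tolerance = 1e-10)
  expect_true(all(tr$x == 0))
  expect_error(pdmp_run(spec, q0 = 0), "q0")
  expect_error(pdmp_run(spec, q0 = 1.2), "q0")
})

test_that("thinning matches the direct method when q is frozen", {
  # q0 = 1 with k- = 0 freezes q; the hybrid model is then the plain
  # one-population birth-death process, so inter-event times must agree in
  # distribution with the direct-method SSA
  N <- 50
  dspec <- depression_spec(k_plus = 0.5, k_minus = 0, h = -0.15,
                           gain = gain_params(20, 1), N = N)
  nspec <- network_spec(weights = matrix(1, 1, 1), drive = -0.15,
                        gain = gain_params(20, 1), N = N)
  set.seed(21)
  ev_p <- pdmp_run(dspec, n0 = 25, q0 = 1, horizon = 1e5,
                   record = "events", max_events = 10000)
  ev_s <- ssa_run(nspec, n0 = 25, horizon = 1e5, record = "events",
                  max_events = 10000)
  ks <- stats::ks.test(diff(ev_p$time), diff(ev_s$time))
  expect_gt(ks$p.value, 0.01)
  # and the visited-state averages agree (lattice values: no KS here)
  expect_lt(abs(mean(ev_p$x) - mean(ev_s$x_1)), 0.02)
})

test_that("PDMP ensemble mean tracks the mean-field oscillation", {
  spec <- preset_spec("depression", N = 1e4)
  st <- popsync:::lc_states(dep_lc)
  Tper <- attr(dep_lc, "period")
  n0 <- round(st[1, 1] * spec$N)
  q0 <- st[1, 2]
  tsamp <- seq(0, 2 * Tper, length.out = 41)
  ref <- popsync:::quiet_ode(c(n0 / spec$N, q0), tsamp,
                             function(t, x, p) list(meanfield_rhs(x, spec)))
  set.seed(12)
  runs <- replicate(200,
                    as.matrix(pdmp_run(spec, n0 = n0, q0 = q0,
                                       sample_times = tsamp)[, -1]),
                    simplify = "array")
  mn <- apply(runs, c(1, 2), mean)
  expect_lt(max(abs(mn - ref[, -1])), 5 / sqrt(spec$N))
})

test_that("with zero diffusion the integrator is explicit Euler", {
  spec <- preset_spec("ei")
  drift <- function(x) meanfield_rhs(x, spec)
  ref <- popsync:::quiet_ode(c(0.5, 0.5), c(0, 1), function(t, x, p)
    list(meanfield_rhs(x, spec)))
  err <- vapply(c(2e-3, 1e-3), function(dt) {
    tr <- euler_maruyama(drift, x0 = c(0.5, 0.5), horizon = 1, dt = dt,
                         keep_every = round(1 / dt))
    max(abs(as.numeric(tr[nrow(tr), 3:4]) - ref[2, -1]))
  }, numeric(1))
  expect_lt(err[2], 5e-3)
  expect_equal(err[1] / err[2], 2, tolerance = 0.3) # first-order convergence
})

test_that("Ornstein-Uhlenbeck stationary variance is recovered", {
  cc <- 0.8
  set.seed(31)
  x0 <- stats::rnorm(1000, 0, cc / sqrt(2)) # start in stationarity
  tr <- euler_maruyama(drift = function(x) -x,
                       independent = function(x) rep(cc, length(x)),
                       layout = noise_layout(n_independent = 1),
                       x0 = matrix(x0, ncol = 1), horizon = 1, dt = 1e-3)
  v <- stats::var(tr$x_1) # 1e6 pooled samples
  # paths decorrelate over ~1 time unit: ~3000 effective samples
  se <- (cc^2 / 2) * sqrt(2 / 3000)
  expect_lt(abs(v - cc^2 / 2), 3 * se)
})

test_that("common noise alone keeps identical oscillators identical", {
  law0 <- build_phase_law(ei_lc, ei_prc, sigma = 0.1)
  attr(law0, "epsilon") <- 0 # exactly no intrinsic channel
  tr <- simulate_phase_ensemble(law0, 6, horizon = 20, seed = 4,
                                init = "equal")
  spread <- tapply(tr$theta, tr$time, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-9)
})

test_that("Stratonovich stepping agrees with its explicit Ito form", {
  # dx = -x dt + a(x) o dW with a(x) = 1 + 0.5 sin x; the Stratonovich
  # route (internal correction) and the hand-converted Ito route
  # dx = (-x + a a'/2) dt + a(x) dW must agree in distribution
  a <- function(x) 1 + 0.5 * sin(x)
  ap <- function(x) 0.5 * cos(x)
  strat <- euler_maruyama(
    drift = function(x) -x, common = a,
    layout = noise_layout(has_common = TRUE,
                          interpretation = "stratonovich"),
    x0 = matrix(0), horizon = 1200, dt = 1e-3, seed = 51,
    keep_every = 1000)
  ito <- euler_maruyama(
    drift = function(x) -x + 0.5 * a(x) * ap(x), common = a,
    layout = noise_layout(has_common = TRUE, interpretation = "ito"),
    x0 = matrix(0), horizon = 1200, dt = 1e-3, seed = 52,
    keep_every = 1000)
  # samples one relaxation time apart are effectively independent
  ks <- suppressWarnings(stats::ks.test(strat$x_1[-(1:5)], ito$x_1[-(1:5)]))
  expect_gt(ks$p.value, 0.01)
})

test_that("diverging states abort with a diagnostic", {
  expect_error(
    euler_maruyama(drift = function(x) x^3, x0 = matrix(2), horizon = 5,
                   dt = 0.1),
    "non-finite")
})
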