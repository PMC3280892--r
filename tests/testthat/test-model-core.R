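test_that("sigmoid gain has the right value, bounds and derivatives", {
  p <- gain_params(1, 1)
  expect_equal(sigmoid_gain(0, p), 0.5)
  expect_equal(sigmoid_gain(0, gain_params(3, 7)), 3.5)
  # logistic derivative identity F' = F(1 - F) at unit gain
  for (u in c(-2, 0, 3)) {
    f <- sigmoid_gain(u, p)
    expect_equal(sigmoid_gain_deriv(u, p), f * (1 - f), tolerance = 1e-15)
  }
  expect_equal(sigmoid_gain(40, p), 1, tolerance = 1e-12)
  # saturation without overflow at extreme inputs
  expect_equal(sigmoid_gain(c(-1e4, 1e4), p), c(0, 1))
  u <- seq(-5, 5, 0.25)
  expect_true(all(diff(sigmoid_gain(u, p)) > 0))
})

test_that("transition rates match their closed forms and reject bad input", {
  spec <- one_pop_spec(N = 100)
  r <- transition_rates(50, spec)
  expect_equal(r$birth, 50) # N * F(0) = 100/2
  expect_equal(r$death, 50)
  r0 <- transition_rates(0, spec)
  expect_equal(r0$death, 0)
  expect_error(transition_rates(101, spec), "out of")
  expect_error(transition_rates(-1, spec), "out of")
  # rescaled intensities are rates / N
  rr <- transition_rates(50, spec, rescaled = TRUE)
  expect_equal(rr$birth, r$birth / 100)
})

test_that("transition rates balance at the deterministic fixed point", {
  spec <- preset_spec("ei", N = 1000)
  fps <- find_fixed_points(spec)
  expect_equal(nrow(fps), 1) # unique equilibrium at this drive point
  x <- as.numeric(fps[1, c("x_E", "x_I")])
  r <- transition_rates(round(x * spec$N), spec, rescaled = TRUE)
  # n is rounded to the lattice, so balance holds to O(|w|/N)
  expect_lt(max(abs(r$birth - r$death)), 10 / spec$N)
})

test_that("mean-field rhs equals the difference of intensities everywhere", {
  spec <- preset_spec("ei")
  set.seed(11)
  for (i in 1:20) {
    x <- runif(2)
    co <- langevin_drift_diffusion(x, spec)
    u <- as.numeric(spec$weights %*% x) + spec$drive
    om_plus <- sigmoid_gain(u, spec$gain)
    om_minus <- spec$decay * x
    expect_equal(meanfield_rhs(x, spec), om_plus - om_minus)
    expect_equal(co$drift, om_plus - om_minus)
    # b^2 is the sum and A the difference of nonnegative intensities
    expect_true(all(co$intrinsic^2 >= abs(co$drift) - 1e-12))
  }
})

test_that("single decoupled population has the textbook coefficients", {
  spec <- one_pop_spec()
  co <- langevin_drift_diffusion(0.5, spec)
  expect_equal(co$drift, 0)
  expect_equal(co$intrinsic, 1)
  co2 <- langevin_drift_diffusion(0.2, spec)
  expect_equal(co2$drift, -0.2 + 0.5)
  expect_equal(co2$intrinsic, sqrt(0.2 + 0.5))
})

test_that("depression mean field vanishes at its analytic fixed point", {
  spec <- preset_spec("depression")
  fp <- popsync:::depression_fixed_point(spec)
  # q* = k+ / (k+ + k- x*)
  expect_equal(fp[["q"]],
               spec$k_plus / (spec$k_plus + spec$k_minus * fp[["x"]]))
  expect_equal(unname(meanfield_rhs(fp, spec)), c(0, 0), tolerance = 1e-10)
})

test_that("analytic Jacobian matches centred finite differences", {
  set.seed(7)
  for (spec in list(preset_spec("ei"), preset_spec("depression"))) {
    for (i in 1:10) {
      x <- runif(popsync:::spec_dim(spec), 0.1, 0.9)
      expect_equal(jacobian_matrix(x, spec),
                   jacobian_matrix(x, spec, method = "numeric"),
                   tolerance = 1e-6)
    }
  }
  # decoupled decay: J = -identity
  spec0 <- network_spec(weights = matrix(0, 2, 2), drive = c(0, 0),
                        decay = c(1, 1))
  expect_equal(jacobian_matrix(c(0.3, 0.7), spec0), -diag(2))
})

test_that("depression preset sits in the oscillatory regime", {
  spec <- preset_spec("depression")
  fp <- popsync:::depression_fixed_point(spec)
  lam <- eigen(jacobian_matrix(fp, spec), only.values = TRUE)$values
  expect_true(all(Re(lam) > 0)) # unstable equilibrium inside the cycle
})
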