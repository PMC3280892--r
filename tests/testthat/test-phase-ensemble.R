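test_that("noise-free phases advance rigidly at the natural frequency", {
  law <- build_phase_law(ei_lc, ei_prc, sigma = 0, N = 1e12)
  attr(law, "epsilon") <- 0
  omega <- attr(law, "omega")
  tr <- simulate_phase_ensemble(law, 3, horizon = 20, dt = 1e-3, seed = 1,
                                sample_every = 5, init = "equal")
  # sampling resolves time to one step, hence the omega*dt slack
  err <- abs(popsync:::circ_diff(tr$theta, omega * tr$time))
  expect_lt(max(err), 2 * omega * 1e-3)
  # and all oscillators stay exactly coincident
  expect_equal(as.numeric(tapply(tr$theta, tr$time,
                                 function(v) diff(range(v)))),
               rep(0, 4))
})

test_that("with zero noise the drift is identically omega", {
  law <- build_phase_law(ei_lc, ei_prc, sigma = 0, N = 1e12)
  # eps^2 = 1e-12: drift corrections are numerically negligible
  expect_equal(law$drift, rep(attr(law, "omega"), nrow(law)),
               tolerance = 1e-9)
  expect_equal(law$indep_total * attr(law, "epsilon"),
               rep(0, nrow(law)), tolerance = 1e-4)
  # zero common-noise weights kill the common coefficient at any sigma
  law2 <- build_phase_law(ei_lc, ei_prc, sigma = 0.5, chi = c(0, 0))
  expect_true(all(law2$common == 0))
})

test_that("pure common noise contracts the ensemble toward synchrony", {
  law <- build_phase_law(ei_lc, ei_prc, sigma = 0.08)
  attr(law, "epsilon") <- 0
  resultant <- function(th) Mod(mean(exp(1i * th)))
  checkpoints <- matrix(NA_real_, 50, 3)
  for (s in 1:50) {
    tr <- simulate_phase_ensemble(law, 10, horizon = 1250, dt = 2e-3,
                                  seed = 1000 + s, sample_every = 50)
    r <- tapply(tr$theta, tr$time, resultant)
    checkpoints[s, ] <- r[c("50", "250", "1250")]
  }
  m <- colMeans(checkpoints)
  expect_true(all(diff(m) > 0)) # synchrony grows across the checkpoints
  expect_gt(m[3], 0.8) # and ends strongly locked
})

test_that("pure intrinsic noise spreads the ensemble toward uniformity", {
  law <- build_phase_law(ei_lc, ei_prc, sigma = 0, N = 400)
  tr <- simulate_phase_ensemble(law, 20, horizon = 400, dt = 2e-3,
                                seed = 5, sample_every = 40,
                                init = "equal")
  late <- tr[tr$time > 200, ]
  # circular spread of pairwise differences near the uniform value
  h <- histogram_phase_differences(tr, burn_in = 0.5)
  expect_lt(max(h$density), 4 / (2 * pi)) # no residual synchrony spike
  r_late <- tapply(late$theta, late$time, function(v) Mod(mean(exp(1i * v))))
  expect_lt(mean(r_late), 0.5)
})

test_that("the ensemble mean frequency stays within second-order terms", {
  law <- build_phase_law(ei_lc, ei_prc) # sigma = 0.08, N = 1e5
  omega <- attr(law, "omega")
  tr <- simulate_phase_ensemble(law, 10, horizon = 100, dt = 1e-3,
                                seed = 8, sample_every = 0.5)
  # unwrap each oscillator's sampled phase
  freq <- vapply(split(tr$theta, tr$oscillator), function(th) {
    un <- th + 2 * pi * cumsum(c(0, diff(th) < -pi)) -
      2 * pi * cumsum(c(0, diff(th) > pi))
    (un[length(un)] - un[1]) / (100 - 0.5)
  }, numeric(1))
  expect_lt(abs(mean(freq) - omega) / omega, 0.05)
})

test_that("frozen coefficients give exact rotational equivariance", {
  law <- build_phase_law(ei_lc, ei_prc, sigma = 0.05)
  # freeze the tabulated functions at constants: the law is then
  # rotation-invariant and equal seeds must give rigidly shifted paths
  law$drift <- rep(attr(law, "omega"), nrow(law))
  law$common <- rep(1, nrow(law))
  law$indep_total <- rep(0.7, nrow(law))
  base <- simulate_phase_ensemble(law, 4, horizon = 5, seed = 3,
                                  init = rep(0, 4))
  shifted <- simulate_phase_ensemble(law, 4, horizon = 5, seed = 3,
                                     init = rep(1, 4))
  expect_equal(popsync:::wrap_phase(shifted$theta - base$theta),
               rep(1, nrow(base)), tolerance = 1e-12)
})

test_that("equal-time increment correlations have the common/independent split", {
  law <- build_phase_law(ei_lc, ei_prc, sigma = 0.3, N = 100)
  sig <- attr(law, "sigma")
  eps <- attr(law, "epsilon")
  theta0 <- c(-2, 0.5, 2.5)
  dt <- 1e-3
  nrep <- 4000
  set.seed(9)
  incr <- t(replicate(nrep, {
    popsync:::em_phase_cpp(law$drift, law$common, law$indep_total, sig, eps,
                           theta0, dt, dt)[1, ] - theta0
  }))
  emp <- stats::cov(incr) / dt
  itp <- function(col, th) stats::approx(law$theta, col, xout = th)$y
  al <- itp(law$common, theta0)
  b2 <- itp(law$indep_total, theta0)^2
  pred <- sig^2 * outer(al, al) + diag(eps^2 * b2)
  # Monte-Carlo error on a covariance of nrep samples
  tol <- 4 * max(abs(pred)) / sqrt(nrep)
  expect_lt(max(abs(emp - pred)), tol)
})

test_that("a too-coarse step is refused", {
  expect_error(simulate_phase_ensemble(ei_law, 4, horizon = 10, dt = 1),
               "dt")
})
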