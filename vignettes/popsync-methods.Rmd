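---
title: "Methods: stochastic phase reduction of neuronal population oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic phase reduction of neuronal population oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popsync)
```

This vignette records the model, the assumptions behind each reduction
step, the numerical choices, and the limits of what the package's tests
establish.

## The model chain

**Master equation.** Each population oscillator consists of M homogeneous
populations of N neurons; the number of active neurons `n_k` follows a
one-step jump Markov process with birth rate
`T_k+ = N F(sum_l w_kl n_l/N + h_k)` and death rate `T_k- = alpha_k n_k`,
where `F(u) = F0/(1 + exp(-gamma u))`. The state space is the lattice
`[0, N]^M`; transitions that would leave it carry zero rate, so no
probability flux escapes. In the thermodynamic limit the rescaled
activities `x_k = n_k/N` obey the Wilson-Cowan equations. `ssa_run()`
samples this process exactly (direct method over the 2M channels).

**Synaptic-depression hybrid model.** The one-population variant couples
the jump process to a deterministic resource variable:
`dq/dt = k_plus (1 - q) - k_minus x q` between jumps, with the birth rate
depending on `q` through `F(w_self q x + h)`. Because `q` enters the rates,
the joint process is a piecewise-deterministic Markov process. `pdmp_run()`
simulates it exactly: between candidate jump times the `q`-flow is linear
in `q` and solved in closed form, and jumps are thinned against the global
bound `N F0 + N alpha`. The gain argument is taken as `q x + h` with
`w_self = 1`; the coupling scale is carried by the gain steepness
(`gamma = 20` in the preset), and with the preset parameters this places
the model in a relaxation-oscillation regime bracketed by two Hopf points
in `k_minus`, which `hopf_points_depression()` locates.

**Langevin approximation.** A second-order Kramers-Moyal expansion gives
the chemical-Langevin equation with drift `A_k = F(u_k) - alpha_k x_k` and
intrinsic (Ito) noise amplitude `b_k = sqrt(F(u_k) + alpha_k x_k)` scaled
by `eps = N^(-1/2)`. A common white-noise component of the drive,
`h_k -> h_k + sigma chi_k xi(t)`, is the zero-correlation-time limit of a
colored process and therefore Stratonovich; expanding to first order in
`sigma` gives the shared multiplicative amplitude `a_k = chi_k F'(u_k)`.
Both noise sources are multiplicative — this is what makes clustering
possible at all. Langevin paths are not clipped to `[0, 1]`; the argument
of the square root is floored at zero and the approximation is only
trusted in the interior.

**Phase reduction.** When the mean-field system has a stable limit cycle,
`find_limit_cycle()` parameterizes it by a phase advancing uniformly in
time, and `compute_prc()` obtains the phase-resetting curve as the
2*pi-periodic solution of the adjoint equation `dZ/dt = -J(x*(t))^T Z`,
integrated backwards (all non-trivial Floquet exponents of adjoint
solutions are positive, so backward integration contracts). The
normalization `sum_k Z_k dx*_k/dt = omega` is adopted — the convention
under which the deterministic phase obeys `dtheta/dt = omega` exactly —
and is verified pointwise on the grid after convergence. The adjoint PRC
is cross-checked against a brute-force oracle (`prc_direct()`): kick one
coordinate by `1e-4` and measure the asymptotic shift in section-crossing
times twenty periods later.

**Stochastic phase equation.** With coefficients evaluated on the orbit,
the Stratonovich phase equation has common coefficient
`alpha(theta) = sum_k Z_k a_k`, independent coefficients
`beta_k(theta) = Z_k b_k`, and an extra drift
`-(eps^2/2) sum_k Z_k b_k db_k/dx_k` inherited from converting the
intrinsic Ito noise to Stratonovich before applying the chain rule.
Converting the scalar phase equation back to Ito form adds
`(sigma^2/4) d(alpha^2)/dtheta + (eps^2/4) d(sum_k beta_k^2)/dtheta`
(spectral differentiation of the tabulated squares). For simulation the M
independent channels are folded into one with the root-sum-square
amplitude, which is equivalent in law for a scalar SDE.

**Averaging and the stationary density.** For weak noise the phase
differences evolve slowly; averaging the ensemble Fokker-Planck equation
over one cycle leaves the circular autocorrelations

    g(phi) = (2 pi)^-1 \oint alpha(theta) alpha(theta + phi) dtheta,
    h(phi) = (2 pi)^-1 \oint sum_k beta_k(theta) beta_k(theta + phi) dtheta,

and the pairwise phase difference has stationary density
`Phi0(phi) = Gamma0 / (sigma^2 (g(0) - g(phi)) + eps^2 h(0))`. This
composition is fixed by its three limits: `sigma = 0` gives the exact
uniform density; `eps -> 0` gives a divergence at `phi = 0` (positivity
guaranteed by `g(0) >= g`); and the broadening of the peak is governed by
`h(0)/N`. Near the peak, expanding `g` to second order yields a Cauchy
(Lorentzian) profile with half-width `sqrt(2 eps^2 h(0) / (sigma^2
|g''(0)|))`, linear in `eps` at fixed `sigma`.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `N` | neurons per population | 1e5 (E-I), 1e4 (depression) | sets `eps = N^(-1/2)`; never stored separately |
| `sigma` | common-noise strength | 0.08 (E-I), 0.004 (depression) | dimensionless; see below for the depression choice |
| `chi_k` | split of the common drive | (1/2, 1/2) | asymmetric splits change the harmonic content of `g` |
| `n_grid` | phase-grid resolution | 1024 | doubling changes the PRC by < 1e-4 sup-norm |
| `dt` | Euler-Maruyama step | 1e-3 time units | refused above period/100; halving does not change test outcomes |
| `prominence` | peak filter | 2% of density range | low enough to keep faint secondary peaks |
| burn-in | discarded fraction of each run | 1/2 | pairwise differences must reach stationarity |

Time is measured in membrane time constants (1 unit = 10 ms), so the E-I
cycle period 4.295 corresponds to about 23 Hz.

The E-I preset noise levels are the regimes studied throughout:
`sigma = 0.08` with `N in {1e3, 1e4, 1e5}` for the sharpening analysis and
`sigma = 0.01` for the weak-drive and asymmetric-drive regimes. For the
depression preset no canonical noise pairing exists, so the package fixes
`N = 1e4`, `sigma = 0.004` once, chosen so that the synchrony ratio
`sigma^2 (g(0) - g_min) / (eps^2 h(0))` (about 4.5) matches the clearly
peaked E-I reference regime; this choice was made from the analytic `g`,
`h` magnitudes alone, before any theory-versus-simulation comparison was
run.

## What the simulators emulate — and what they do not

The stochastic simulators are the package's synthetic-data generators:
they produce exactly the processes the theory approximates, under the
stated study conditions. The SSA and PDMP samplers are statistically exact
for the master equation and the hybrid model; the Langevin and phase
integrators introduce `O(dt)` weak error. Passing tests therefore show
internal consistency of the reduction chain (master equation -> Langevin
-> phase -> averaging) at the preset parameters. They do not show that
real cortical populations follow Wilson-Cowan rate dynamics, that
population-level depression is a single scalar resource, or that
extrinsic noise is white; those are modelling assumptions inherited by
every downstream statement.

## Numerical choices

- **ODE integration**: `deSolve::lsoda`, `rtol 1e-11`, `atol 1e-13`
  everywhere (orbit, adjoint, oracles).
- **Cycle detection**: transient of 50 linearised periods, then a Poincare
  section at the midrange of the first coordinate with spline-refined
  crossing times; the observation window grows geometrically when the
  linearised frequency underestimates the true period (relaxation
  oscillators whose unstable equilibrium is a node, as in the depression
  preset). The phase origin (`theta = 0` at the maximum of the first
  coordinate) is located to sub-grid accuracy so that refining the grid
  does not move it.
- **Adjoint iteration**: per-period renormalization at the anchor point;
  convergence when the per-period change is below `1e-10` relative;
  typically ~25 backward periods for the E-I preset (weakly contracting)
  and ~3 for the depression preset.
- **Spectral operations**: circular correlations and derivatives via FFT
  on the uniform grid; exact for band-limited tabulations and verified
  against direct O(n^2) quadrature to 1e-10.
- **Degenerate inputs**: `sigma = eps = 0` is rejected for the stationary
  density (no stationary distribution of a deterministic difference);
  `sigma = 0` returns the exact uniform branch rather than a 0/0 limit;
  absorbing SSA states return early with a flag.
- **Chi-square flatness testing**: pooled pairwise differences are heavily
  dependent (all pairs share oscillators, and the ensemble fluctuates
  coherently), which invalidates a naive chi-square test. The
  desynchronization check therefore pools one difference per disjoint
  oscillator pair per widely spaced snapshot, spacing chosen beyond the
  phase-diffusion mixing time.
- **Histogram comparisons**: the analytic density is bin-averaged before
  the L1 distance is taken, and simulated histograms pool several
  independent replicate ensembles — a single run's pairwise differences
  fluctuate coherently and leave an O(0.2) L1 residue no matter how long
  it runs.
- **Problem sizes**: tests use 1024-point grids, ensembles of 10-200
  oscillators, horizons of a few hundred to ten thousand time units, and
  200-2000 stochastic replicates per moment comparison; these sizes give
  Monte-Carlo errors comfortably inside the asserted tolerances on a
  single core.

## Design decisions on genuinely open points

- **Depression gain argument.** The resource variable multiplies the
  recurrent input as `F(q x + h)` with unit recurrent weight; the
  effective coupling scale is carried by `gamma = 20`. With the preset
  parameters this produces a large relaxation cycle (activity swinging
  between 0.08 and 0.98 with period ~44.8) whose equilibrium loses
  stability between two Hopf points in `k_minus` — the qualitative
  structure required of this model — so the convention is kept.
- **PRC normalization.** `sum_k Z_k dx*_k/dt = omega` (rather than unit
  normalization); downstream densities are invariant to this scale choice,
  but the convention makes the deterministic phase advance exactly at
  `omega` and gives the drift statements above their clean form.
- **Phase interval.** `[-pi, pi)` half-open, uniform grids of size a power
  of two; the origin convention is immaterial downstream (verified: the
  stationary density is invariant under rotating the cycle and PRC
  together).
- **Prominence threshold.** 2% of the density range keeps genuinely faint
  secondary peaks (the excitatory-dominant regime is expected to produce
  an antiphase peak that "does not contribute significantly") while
  suppressing grid-level wiggles; it is exposed as an argument.

## A structural finding at the E-I preset, and known limitations

Clustering — a multimodal stationary density — requires the common-noise
phase sensitivity `alpha(theta) = chi_E Z_E F'(u_E) + chi_I Z_I F'(u_I)`
to be dominated by a harmonic above the fundamental, since the peaks of
`Phi0` are exactly the local maxima of `g` and `g`'s Fourier mass is
`|alpha_m|^2`. At the E-I preset with unit gain this cannot happen: the
first harmonics of the two products `Z_k F'(u_k)` sit about 124 degrees
apart in phase, so no nonnegative split `(chi_E, chi_I)` cancels the
fundamental (the minimum attainable fundamental magnitude, 0.59, is an
order of magnitude above the third harmonic). The package's `g` is
therefore provably unimodal for every `chi` at this operating point, for
any noise strengths, and the same conclusion held at every oscillatory
drive point we scanned in the `(h_E, h_I)` plane at unit gain. This is
not a numerical artifact: the adjoint PRC agrees with the brute-force
perturbation oracle to 0.1%, and a full planar Langevin ensemble —
simulated with no phase reduction at all — reproduces the flat analytic
density in the weak-drive asymmetric regime. Steepening the gain changes
the picture qualitatively: at `gamma` near 2.2 (all else at the preset
values) the orbit acquires strong gain-derivative modulation, the product
harmonics mix, and `g` develops the three-peak structure at 0 and near
+-2*pi/3 under inhibitory-dominant drive. Users exploring clustering
should treat the gain steepness as the controlling parameter.

Other limitations: the Langevin and phase reductions are accurate only
for large N and weak `sigma` (errors grow near the boundaries of
`[0, 1]^M` and near bifurcations); the nearest-orbit-point projection used
to compare planar simulations with phase theory is not the isochron map
and contributes a small bias at finite noise; the averaging step assumes
the phase differences evolve slowly compared to the cycle, which fails
when `sigma^2 g` becomes comparable to `omega`; heterogeneous ensembles
and coupled oscillators are out of scope.
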