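# popsync

Noise-induced synchronization of stochastic neuronal population
oscillators.

## The problem

Uncoupled oscillators can synchronize when they are driven by a *common*
fluctuating input. For neuronal populations the picture is complicated by a
second, unavoidable noise source: finite-size (demographic) fluctuations of
the population activity itself, which are *independent* across oscillators
and work against synchrony. `popsync` quantifies the balance between the
two for rate-based population oscillators.

Each oscillator is an M-population network whose active-neuron counts
follow a birth-death master equation with rates

    T_k+ (n) = N F( sum_l w_kl n_l / N + h_k ),   T_k- (n) = alpha_k n_k,
    F(u) = F0 / (1 + exp(-gamma u)),

so that the mean-field limit `N -> Inf` is the Wilson-Cowan system
`dx_k/dt = -alpha_k x_k + F(sum_l w_kl x_l + h_k)`. A Kramers-Moyal
expansion gives the chemical-Langevin approximation

    dX_k = A_k dt + sigma a_k o dW (common, Stratonovich)
                 + eps b_k dW_k   (intrinsic, Ito),

with `A_k = F(u_k) - alpha_k x_k`, `b_k = sqrt(F(u_k) + alpha_k x_k)`,
`a_k = chi_k F'(u_k)`, `eps = N^(-1/2)`. When the deterministic system has
a stable limit cycle `x*(theta)` with frequency `omega = 2 pi / T`, phase
reduction with the adjoint phase-resetting curve `Z(theta)` turns the
ensemble into scalar phase oscillators; averaging over the cycle leaves the
stationary density of the pairwise phase difference

    Phi0(phi) = Gamma0 / ( sigma^2 (g(0) - g(phi)) + eps^2 h(0) ),

where `g` and `h` are the circular autocorrelations of the common-noise and
independent-noise phase sensitivities `sum_k Z_k a_k` and `Z_k b_k` on the
cycle. `Phi0` is uniform with no common noise, diverges at 0 as
`N -> Inf`, and can be multimodal (clustering) when `g` carries strong
higher harmonics.

Two presets ship with the package: an excitatory-inhibitory pair
(`preset_spec("ei")`: `w_EE = 11.5`, `w_IE = -w_EI = 10`, `w_II = -2`,
`h_E = 0`, `h_I = -4`, unit gain) and a recurrent excitatory network with
synaptic depression (`preset_spec("depression")`: `k+ = 0.02`,
`k- = 0.1`, `h = -0.15`, gain steepness 20), both in their oscillatory
regimes. Time is measured in membrane time constants (1 unit = 10 ms).

Everything in the chain is also checkable by direct stochastic simulation:
an exact Gillespie sampler of the master equation, an exact
piecewise-deterministic (thinning) sampler for the depression hybrid model,
and Euler-Maruyama integrators for the planar and phase-reduced Langevin
ensembles with a shared common-noise stream.

## Worked example

```r
library(popsync)

lc  <- find_limit_cycle(preset_spec("ei"))
prc <- compute_prc(lc)
law <- build_phase_law(lc, prc)            # sigma = 0.08, N = 1e5
dist <- stationary_distribution(correlation_functions(law))

runs <- lapply(1:8, function(s)
  simulate_phase_ensemble(law, n_osc = 100, horizon = 1300, dt = 1e-3,
                          seed = s, sample_every = 25))
hist <- histogram_phase_differences(runs)

cat("pooled pairwise samples:", attr(hist, "n_samples"), "\n")
cat("L1(theory, simulation):", round(l1_distance(hist, dist), 3), "\n")
cat("peak height Phi0(0):", round(glance(dist)$phi0_at_zero, 3), "\n")
```

prints

```
pooled pairwise samples: 1029600
L1(theory, simulation): 0.044
peak height Phi0(0): 0.332
```

The E-I cycle has period 4.295 (23.3 Hz). At `sigma = 0.08`, `N = 1e5`
the analytic density is unimodal with `Phi0(0) = 0.332` (about twice the
uniform level `1/2pi = 0.159`): the common drive synchronizes the
ensemble, and the pooled pairwise-difference histogram from the simulated
phase ensemble matches the analytic curve to an L1 distance of 0.04.
Single short runs fluctuate coherently (the whole ensemble wanders
together), so pooling independent replicates is essential for a clean
histogram.

`autoplot()` methods give quick views of every stage
(`autoplot(lc)`, `autoplot(prc)`, `autoplot(dist)`,
`autoplot(hist, dist = dist)`), and `run_pipeline("ei", out_dir = "out")`
runs the whole chain and writes TSV/JSON artifacts with a reproducible
manifest.

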