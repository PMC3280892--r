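# Shared fixtures: the two preset chains, computed once per test run.
# Everything downstream (phase laws, distributions, simulations) derives
# from these.

ei_spec <- preset_spec("ei")
ei_lc <- find_limit_cycle(ei_spec)
ei_prc <- compute_prc(ei_lc)
ei_law <- build_phase_law(ei_lc, ei_prc) # sigma = 0.08, N = 1e5, chi = 1/2

dep_spec <- preset_spec("depression")
dep_lc <- find_limit_cycle(dep_spec)
dep_prc <- compute_prc(dep_lc)
dep_law <- build_phase_law(dep_lc, dep_prc) # sigma = 0.004, N = 1e4

# single decoupled population, handy for closed-form checks
one_pop_spec <- function(N = 100, drive = 0, sigma = 0, chi = 1) {
  network_spec(weights = matrix(0, 1, 1), drive = drive, decay = 1,
               gain = gain_params(1, 1), N = N, chi = chi, sigma = sigma)
}
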