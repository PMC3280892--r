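# Two-population excitatory-inhibitory preset with overridden noise levels.
preset: ei
model:
  N: 10000
  sigma: 0.05
run:
  n_oscillators: 50
  horizon: 1000
  dt: 0.001
  seed: 1
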