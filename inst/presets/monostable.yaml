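# q = 0.5 (b > c): single noisy attractor at the symmetric progenitor state
analysis: simulate
seed: 1
generic:
  a: 1.0
  f: 1.0
  b: 0.5
  c: 0.25
  d: 0.5
simulation:
  sigma: 0.05
  dt: 0.01
  n_steps: 250000
  ensemble: true
  burn_in_fraction: 0.1
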