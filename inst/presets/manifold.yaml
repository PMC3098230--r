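# degenerate manifold, reference parameter set (x ranges over [0, 2])
analysis: manifold
seed: 1
generic:
  a: 1.0
  f: 1.0
  b: 0.5
  c: 0.5
  d: 0.5
manifold:
  n_points: 200
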