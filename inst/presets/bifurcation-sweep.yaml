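# full sweep of q = c/b for the reference symmetric circuit
analysis: bifurcate
seed: 1
generic:
  a: 1.0
  f: 1.0
  b: 0.5
  c: 0.5
  d: 0.5
bifurcation:
  q_min: 0.2
  q_max: 5.0
  n_q: 101
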