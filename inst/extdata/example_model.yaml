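# One neuron driven by an excitatory and an inhibitory pool with weak
# within-pool synchrony (rho = 0.03) and no cross-type synchrony.
neuron:
  tau: 0.015
  Ve: 60
  Vi: -10
  Irest: 0
pools:
  - {kind: e, K: 1000, w: 0.001, r: 10}
  - {kind: i, K: 250, w: 0.004, r: 10}
correlation:
  rho:
    - [0.03, 0.0]
    - [0.0, 0.03]
duration: 20
dt: 1.0e-4
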