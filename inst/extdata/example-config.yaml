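# Example run configuration: the published free-running parameter set,
# constant darkness, default likelihood and sampler settings.
params:
  vs: 1.6
  kI: 1.0
  vm: 0.505
  km: 0.5
  ks: 0.5
  vd: 1.4
  kd: 0.13
  k1: 0.5
  k2: 0.6
  "N": 4
  omega: 500
protocol:
  mode: DD
likelihood:
  epsilon: 0.1
  bridge_length: 20
sampler:
  "n": 25
  window: 50
  tol: 0.005
  margin: 10
prior:
  lower: [0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05]
  upper: [2.5, 2.5, 2.5, 2.5, 2.5, 2.5, 2.5, 2.5, 2.5]
seed: 1
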