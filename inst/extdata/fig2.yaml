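# Gradient scenario: 25 studies whose treatment effect varies linearly with
# ambient temperature (degrees Celsius); fitted by the conditional-effect
# regression. Effects cross zero across the probed range.
seed: 20260925
run: gradient
fixture:
  n_studies: 25
  x_range: [18, 30]
  delta0: -4.8
  delta1: 0.2
  se_per_study: 0.3
  n_per_arm: 10
criteria:
  z: 1.96
output:
  dir: fig2-out
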