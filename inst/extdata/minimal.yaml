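# Minimal multi-lab simulation: two genotypes with crossing linear norms
# (a GxE configuration), heterogenized across 6 labs.
seed: 11
run: simulate
norms:
  - genotype: g1
    shape: linear
    params: {intercept: 0, slope: 2}
  - genotype: g2
    shape: linear
    params: {intercept: 4, slope: -2}
environment:
  family: gaussian
  params: {mean: 1, sd: 0.5}
design:
  n_labs: 6
  n_per_arm: 5
  genotypes: [g1, g2]
  within_noise_sd: 1
  small_effect_sd: 0.5
  delta0: 1
output:
  dir: minimal-out
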