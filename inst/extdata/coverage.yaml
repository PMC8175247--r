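# Coverage experiment: single-lab studies with an environment-dependent
# treatment effect (delta1 = 1 per unit of the dominating factor). The
# classical interval under-covers the population-average effect; the
# random-lab-model interval with the oracle GxE variance restores coverage.
seed: 20260925
run: coverage
norms:
  - genotype: g1
    shape: flat
    params: {m: 10}
environment:
  family: gaussian
  params: {mean: 0, sd: 1}
design:
  n_per_arm: 10
  genotypes: [g1]
  standardization: heterogenized
  within_noise_sd: 0.5
  delta0: 1
  delta1: 1
simulation:
  n_replicates: 200
criteria:
  confidence: 0.95
output:
  dir: coverage-out
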