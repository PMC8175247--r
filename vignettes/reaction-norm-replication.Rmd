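---
title: "Reaction norms, replication criteria and the random lab model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction norms, replication criteria and the random lab model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactnorm)
```

## The model

A reaction norm is a genotype-specific deterministic mapping $h(\cdot)$ from
the value $x$ of an environmental parameter to the expected value of a
phenotypic trait, $E(y \mid x) = h(x)$, valid over a stated environmental
range. If environments are distributed with density $g(x)$, the distribution
$f$ of *expected* trait values is the composition $f = g(h(x))$. The package
represents norms (`reaction_norm` with constructors for flat, linear,
quadratic, logistic and tabulated shapes), environment distributions
(`environment_dist`: Gaussian, uniform, tabulated) and the induced trait
distribution (`trait_dist`: Gaussian, point mass, or empirical sample), with
`compose_distribution()` carrying one into the other.

Two modelling commitments deserve emphasis:

* **$f$ is the distribution of expected values.** The composed distribution
  describes $E(y \mid X)$, not individual observations; measurement error and
  individual biological variation are added downstream by the simulator as
  within-lab noise. The two readings are sometimes conflated in informal
  discussion; keeping them apart is what lets the tail-product criterion ask
  a clean question ("could both study means be ordinary draws of the
  environment?") without double-counting sampling error.
* **Norms are range-limited.** A tabulated norm refuses evaluation outside
  its tabulated range (an error, not clamping), and every norm carries a
  domain; a norm is an empirical object that should not be trusted where it
  was never measured.

Residual environmental influences — the many parameters that are neither
controlled nor dominant — are modelled as independent zero-mean factors of
small effect. Their sum is, by the central limit theorem, approximately
$N(0, \sum_k v_k)$; `clt_aggregate()` draws the finite-$K$ aggregate and
reports the limiting parameters, and the simulator absorbs this aggregate
into a per-lab Gaussian offset $u_{lab}$.

## The generative model of a multi-lab experiment

`simulate_multilab()` draws, for lab $j$, a dominating-factor value $x_j$
(fixed at the environment mean under standardization, drawn from $g$ under
heterogenization) and a lab offset $u_j \sim N(0, \sigma_u^2)$, and then per
animal

$$ y = h_g(x_j) + u_j + \mathbb{1}[\text{treatment}]\,(\delta_0 + \delta_1 x_j)
      + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_w^2). $$

The structural point the simulator encodes — rather than an ad-hoc "lab noise
on effects" term — is that *additive* lab offsets cancel in the within-lab
treatment−control contrast. Between-lab variation of the effect arises only
when the effect itself depends on the environment ($\delta_1 \neq 0$) or when
genotype norms differ across the probed range. The test suite asserts this
cancellation exactly (changing $\sigma_u$ leaves per-lab effects bit-for-bit
unchanged) and asserts the induced effect variance $\delta_1^2\,\mathrm{var}(X)$.

We considered additionally letting the small-effect aggregate act on the
treatment effect itself (an opt-in latent effect modifier). We decided
against it: from contrast data alone such a term is indistinguishable from an
enlarged $2 s^2_{G\times E}$, and its mechanistic role is already played by
$\delta_1$, which ties effect heterogeneity to an observable covariate. Users
who want unexplained effect heterogeneity can raise $\delta_1$ or pass a
larger `s2_gxe` to the inference functions directly.

### Seeding

All randomness flows from one integer seed. Each lab gets a substream seed
$(\text{seed} \cdot 48271 + j \cdot 65537) \bmod (2^{31}-1)$, and draws
within a lab happen in a fixed order (dominating factor, lab offset, then
animal noise by genotype and arm). Two consequences: identical inputs give
byte-identical CSV exports, and appending labs does not perturb existing
records. Standard deviations scale standard normal draws (rather than being
passed to `rnorm`) so that setting a variance component to zero does not
consume a different number of deviates and silently desynchronise
comparisons across designs.

## Replication criteria

Let study 1 (original) have mean $\bar y_1$ with standard error
$\mathrm{SE}_1$, and study 2 (replicate) mean $\bar y_2$.

* **Naive**: success iff
  $\bar y_1 - z\,\mathrm{SE}_1 < \bar y_2 < \bar y_1 + z\,\mathrm{SE}_1$.
* **Shifted CI** (environments $x_1, x_2$ and the norm known): the same
  interval shifted by $h(x_2) - h(x_1)$. With a flat norm this reduces
  *exactly* to the naive criterion — a property the suite checks over
  randomized inputs.
* **Tail product** (only the distribution $f$ known): success iff the
  product of the two tail masses of $f$, each taken on the side away from
  the first moment $M_1$, exceeds a critical value $L$.

Conventions, chosen once and tested:

* All interval inequalities are strict; a boundary hit is a failure.
* Only $\mathrm{SE}_1$ enters the shifted/naive interval: the replicate's
  uncertainty does not widen the acceptance region. Consequently, with an
  equally noisy replicate the ideal success rate is
  $P(|N(0, \sqrt2\,\mathrm{SE})| < 1.96\,\mathrm{SE}) \approx 0.834$, not
  0.95 — worth knowing before reading empirical rates.
* Tail sides are chosen independently per mean. A mean exactly at $M_1$
  contributes $0.5$ for the closed-form Gaussian representation (continuity
  of the rule), the empirical upper-tail mass for empirical samples (no
  smoothing), and $1$ for a point mass.
* Default $z = 1.96$ (two-sided 95%). Default $L = 0.05^2 = 0.0025$: each
  study is allowed to sit at its own two-sided 5% tail. $L$ has no canonical
  value; the default is a transparent conventional anchor and is
  configurable everywhere it appears.
* Empirical tails use the raw empirical survival function with a minimum of
  1000 samples (smaller samples error unless explicitly overridden), to
  avoid hidden smoothing bias.
* `reproducibility_rate()` reports Wilson score intervals (good small-$n$
  behaviour, no continuity correction).

When every study carries a measured environmental covariate,
`conditional_effect_regression()` fits inverse-variance weighted least
squares of effect on environment and judges each study against its own
conditional prediction (prediction strictly inside the study's
$z \cdot \mathrm{SE}$ interval). This is the constructive reading of a
25-study gradient scenario: what looks like heterogeneity is largely a
predictable environmental trend.

## The random lab model

The adjusted standard error for a two-group contrast is

$$ \mathrm{SE} = \sqrt{ s^2 \left( \tfrac1{n_1} + \tfrac1{n_2} \right)
   + 2 s^2_{G\times E} }, $$

which reduces to the classical pooled-variance SE at
$s^2_{G\times E} = 0$ and is strictly increasing in it. Choices:

* **Gaussian reference.** Tests and intervals use normal quantiles, not $t$:
  the penalty term carries no degrees of freedom, so no exact $t$ reference
  exists. At small per-arm sizes the classical interval is therefore
  slightly anti-conservative (e.g. true coverage $\approx 93.5\%$ at 10 per
  arm); coverage checks in the suite use large arms where this is the
  quantity under test.
* **Parameterisation.** $2 s^2_{G\times E}$ is the between-lab variance of
  the *contrast* (one interaction variance per arm); the moment estimator
  divides by 2 accordingly.
* **Moment estimator.** With per-lab effects $d_j$ and sampling variances
  $v_j$: $\hat s^2_{G\times E} = \max\!\big(0, (\widehat{\mathrm{var}}(d_j)
  - \bar v)/2\big)$, truncated at zero as variance components are
  nonnegative. With several genotypes, effects are centred within genotype
  and the between-lab variance pooled across genotypes. At least 3 labs are
  required — the component is not identifiable from a single experiment.
  $s^2$ pools within lab across the two arms.
* **Oracle mode.** `coverage_experiment()` can inject the simulator's true
  between-lab effect variance ($\delta_1^2 \mathrm{var}(X)/2$), separating
  procedure error from estimator error.

## What the simulator emulates — and what it does not

Emulated: one dominating environmental factor with a possibly non-linear,
genotype-specific norm; a Gaussian aggregate of small-effect factors at the
lab level; environment-dependent treatment effects (the G×E channel into
effect heterogeneity); balanced two-arm designs; standardized and
heterogenized regimes; effects varying linearly along a gradient of studies.
A non-linear norm pushed through a Gaussian environment also yields *skewed*
lab-level distributions, so the common normality assumption for lab random
effects can be probed, though the package deliberately ships no non-normal
estimator.

Not emulated: nested structure below the lab (cages, batches, racks),
longitudinal or developmental environmental effects, unbalanced allocation,
multi-dimensional norm surfaces, and norm *inference* from data (norms are
inputs here, not estimands). Passing tests therefore demonstrate internal
consistency of this variance structure, not that any real multi-lab dataset
follows it; with real data the environmental covariate is usually unknown,
which is exactly the regime the tail-product criterion and the RLM are for.

## Numerical choices and problem sizes

* Density normalisation is checked by adaptive quadrature to $10^{-6}$;
  unbounded supports are truncated at $\pm 8$ standard deviations for the
  check. Tabulated densities are normalised by trapezoid integration and
  sampled by inverse-CDF interpolation.
* Closed-form composition exists for exactly two cases (flat; linear ×
  Gaussian); requesting it elsewhere is an error, never a silent Monte
  Carlo fallback.
* Monte Carlo composition requires an explicit seed and at least 2 draws;
  accuracy checks in the suite run at $10^5$ draws with 4-standard-error
  bands.
* Environment mass escaping a norm's domain is tolerated only below
  $10^{-9}$.
* The simulation studies in the suite use sizes chosen to make their
  expected sampling error an order of magnitude smaller than the effects
  being asserted: 2000 labs for variance-decomposition checks, 2000
  replicates for coverage, 100 replicates of 50 labs × 20/arm for
  G×E-variance recovery (where the inter-replicate spread of the estimate
  is itself part of the assertion, contrasted against 5-lab replicates).

### The gradient fixture

`make_gradient_fixture()` defaults encode a concrete, reproducible scenario:
25 studies evenly spaced over an ambient-temperature range of 18–30 °C
(even spacing, not random, so the sorted-gradient reading is deterministic),
true effect $\delta_0 + \delta_1 x$ with defaults $\delta_0 = -4.8$,
$\delta_1 = 0.2$ — chosen so effects cross zero inside the range, the
configuration in which ignoring the environment is most misleading — and
observation noise equal to each study's standard error (default 0.3).

## Limitations

* Eq.-style intervals use only the original study's SE; users comparing
  empirical success rates to a nominal 95% should use the $0.834$ benchmark
  above.
* The RLM's Gaussian reference is anti-conservative for very small arms.
* The moment estimator of $s^2_{G\times E}$ is unbiased before truncation
  but the zero-truncation introduces upward bias near zero truth; the suite
  quantifies the median behaviour rather than the mean.
* The tail-product threshold $L$ has no principled default; sensitivity to
  $L$ should be reported alongside any rate computed with it.
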