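---
title: "Methods: small-area modelling of mortality and service delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area modelling of mortality and service delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
`servmort`, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The scientific problem

Sub-district ("local municipality") areal data link all-cause mortality to
the delivery of basic municipal services — water, sanitation, refuse
removal, electricity, schooling, housing and health facilities. Death
counts in small areas are noisy and spatially correlated: neighbouring
municipalities resemble each other, and crude standardized mortality
ratios (SMRs) in low-population units are unstable. The package therefore
follows the standard disease-mapping approach: a composite deprivation
index summarizes service (non-)delivery, a Bayesian convolution
conditional-autoregressive (CAR) Poisson model smooths the risk surface
and estimates covariate effects, exceedance probabilities flag hotspots,
and attributable fractions translate fitted relative risks into a
projected mortality-reduction index.

## Composite service (non-)delivery index

Seven components are observed per unit: the proportions with no water
service provider, no toilet facilities, no refuse disposal, no
electricity, no schooling, the proportion in informal housing, and the
population-to-health-facility ratio. Components live on different scales,
so each is normalized to a z-score with the sample (n−1) standard
deviation and the z-scores are summed with equal weight. Higher composite
scores mean poorer delivery. Equal weighting is deliberate: it is
replicable across study areas and avoids arbitrary importance judgements;
`composite_index(weights =)` allows per-component reweighting or sign
flips.

Two open points and how they are resolved here:

* **Informal housing.** In typical data this component correlates
  *negatively* with the other deprivation components (informal settlement
  concentrates where networked services exist). It enters the composite
  with the sign it is stored with — deliberately not flipped — and the
  weight override exists for analysts who prefer the opposite convention.
* **Non-negativity of the score.** A sum of z-scores is negative for
  roughly half the units, while a square-root transform needs a
  non-negative argument. The composite is therefore shifted by its
  minimum before the square root: `sqrt(score − min(score))`. The
  transform is exactly rank-preserving and anchored at zero for the
  best-served unit.

The square-root transform itself exists because the raw composite is
convex against log-mortality in data of this shape; the transformed score
is the covariate used in all model fits.

The Gini coefficient of household income per unit is computed as the
standard relative mean absolute pairwise difference,
`G = mean |x_i − x_j| / (2 mean x)` over ordered pairs, implemented in
O(n log n) via the sorted-vector identity and tested for exact agreement
with the O(n²) oracle. (Descriptions of the Gini as "based on the standard
deviation of income" appear in applied work; the pairwise-difference
definition is the standard one and is what this package computes.) Units
above the upper tertile of the Gini distribution are flagged as
high-inequality; "high" has no canonical cut, so the quantile is a
documented, configurable choice.

## The BYM convolution model

For unit *i* with death count `O_i` and expected count
`E_i = (ΣO / Σpop) × pop_i` (internal standardization, so `ΣE = ΣO`
exactly):

```
O_i ~ Poisson(E_i λ_i)
log λ_i = α + X_i β + ε_i + φ_i
```

`ε_i ~ N(0, σ²_ε)` is unstructured heterogeneity; `φ` is an intrinsic CAR
field: `φ_i | φ_−i ~ N(mean of neighbours, σ²_φ / n_i)` on a symmetric
binary contiguity graph. The intrinsic prior is improper and only
differences are identified, so the field is constrained to sum to zero
and `α` carries the overall level. The null model (no covariates) drives
the risk maps; the multivariable model adds the transformed service
score, the high-inequality flag, HIV seroprevalence in percentage points
(linear), and a three-level density/metro class with low/medium density
as reference.

**Priors.** `α` and each `β` get vague Normal(0, 10⁶) priors. Both
precisions get Gamma(0.5, 0.0005), the conventional weakly-informative
disease-mapping choice; all are configurable via `model_spec()`.

**Sampler.** A compiled Metropolis-within-Gibbs kernel: random-walk
updates for `α`, each `β_k`, and the two fields, with conjugate gamma
Gibbs draws for the precisions. Proposal scales adapt toward 44%
acceptance during burn-in only and are frozen afterwards, so retained
samples come from a fixed, valid kernel. Two further exact moves address
the well-known confounding in this model:

* only `ε_i + φ_i` enters the likelihood, so the split between the two
  fields is resampled per unit from its exact Gaussian full conditional
  given the sum (the linear predictor is untouched);
* the intercept and coefficients are confounded with the mean (and
  covariate projections) of the heterogeneity field; a Gibbs draw along
  each likelihood-invariant direction (`α ← α + d`, `ε ← ε − d`, and the
  analogue for each `β_k`) removes the slow random-walk drift these
  directions otherwise exhibit.

The sum-to-zero constraint is imposed each sweep by recentring `φ` and
absorbing the mean into `α` (and, for isolated zero-neighbour units whose
`φ` is pinned at 0, into `ε`), leaving the linear predictor exactly
unchanged. Covariates are mean-centered internally for sampling and the
intercept is mapped back, so reported coefficients are on the natural
covariate scale. Isolated units keep `φ_i = 0` and are carried by the
heterogeneity term.

**Chains, stopping and diagnostics.** Two chains by default, burn-in
5,000 and 5,000 retained per chain (10,000 pooled). After the initial
run, the batch-means (30 batches) Monte-Carlo error of every monitored
scalar must be below 5% of its posterior standard deviation; otherwise
sampling extends in blocks up to a hard cap of 200,000 pooled samples,
after which the fit is returned with an explicit failure flag. Chain `c`
seeds R's RNG with `seed + c − 1`, making fits bitwise reproducible.
Convergence is summarized by the between/within-chain potential scale
reduction factor with a threshold of 1.1 (cross-checked against the coda
reference implementation in the test suite). Model comparison uses
`DIC = Dbar + pD` with `pD = Dbar − D(posterior means of the log relative
risks)`; lower is better.

The sampler is validated against a 1-D quadrature oracle (single unit,
random effects disabled: posterior mean within 0.02, sd within 10%) and
by parameter-recovery simulations (95% credible intervals cover the
generative log relative risks at the nominal rate across seeded
replicates).

## Hotspots and reporting

A unit is a hotspot when `P(λ_i > 1 | data) > 0.9`, the stringent variant
of Richardson's criterion (the standard value is 0.8); the threshold is
an argument and is recorded in the output. Covariates are declared
significant when `P(β > 0)` or `P(β < 0)` exceeds 0.95, the analogous
covariate criterion.

The service-delivery analogue ("standardized poor service ratio") needs
counts, but the composite index is continuous; the construction of such a
ratio is not canonical. The package makes the device explicit: the
shifted composite score is discretized to a pseudo-count
(`round(shifted_score × 25)` by default, configurable), every unit gets
the same size measure so the expected count is the table-wide mean, and
the identical BYM machinery produces exceedance probabilities. Only the
internal consistency of this mapping (monotonicity, determinism) is
meaningful — the absolute count scale is not.

Provincial summaries aggregate crude rates per 1000 with
normal-approximation binomial CIs and population-weighted mean composite
scores with across-unit-variance CIs. Ranks are assigned in descending
order with a CI-overlap tie rule: a province whose 95% CI overlaps the
current rank-group leader's CI shares the leader's rank. This reproduces
the familiar pattern where several statistically indistinguishable
provinces share rank 1.

## Attributable fractions and the reduction index

For a determinant with prevalence `p_e` and relative risk `RR`,
`AF = p_e(RR−1) / (1 + p_e(RR−1))`. Determinant RRs come from a
component-level multivariable fit (each basic-service component as its own
covariate, so prevalence is the component proportion itself); the
composite-index fit cannot be decomposed by component. The exponentiated
coefficients are interpreted as rate ratios (the model is Poisson; "odds
ratio" is sometimes used loosely for these in applied work).

Per unit, the per-determinant reduction is `observed rate × AF_k`.
Combining determinants is ambiguous in principle; the package emits both
conventions and uses the multiplicative one as the headline: the residual
rate is `observed × Π_k(1 − AF_k)`, which is order-invariant and cannot
go negative, while the additive per-determinant table supports
decomposition statements ("about half the avertable deaths attach to
schooling"). The national figure is the population-weighted mean
reduction; its 95% interval recomputes the whole pipeline per posterior
RR draw (the additive decomposition shares are reported from point
estimates). The reduction curve orders units by observed rate and pairs
each with its projected residual rate.

## The synthetic-data generator

No microdata ship with the package; every analysis runs on synthetic
areal data whose defaults emulate the study structure: 248 units on an
8 × 31 rook lattice partitioned into 9 contiguous pseudo-provinces,
populations uniform on 5,000–50,000 (survey-scale person counts), a
baseline rate of 15 deaths per 1000, covariate effects RR 1.84 per unit
of transformed service score, 1.14 for high inequality, 1.02 per HIV
percentage point, 0.97 / 0.73 for the high-density non-metro / metro
classes, heterogeneity sd 0.1 and spatial conditional sd 0.3, and a
latent equicorrelation of 0.5 among the seven service components.

Mechanics worth knowing:

* the CAR field is drawn exactly from the intrinsic prior restricted to
  the sum-to-zero subspace (eigendecomposition of the graph Laplacian per
  connected component, zero mode excluded), so generated fields match the
  prior the model assumes;
* service components come from a Gaussian copula (probit transform of a
  correlated latent normal), keeping every proportion in (0, 1) while
  hitting the target correlation to within sampling error; the
  health-facility component is generated on the same normalized scale,
  which is immaterial downstream because z-scoring removes scale;
* household incomes are lognormal (the within-municipality income
  distribution is a modelling choice — nothing in the source data
  constrains it), giving a closed-form check `G = 2Φ(σ/√2) − 1`;
* deaths are `Poisson(E_i λ_i)` with the design matrix built by the same
  `prepare_covariates()` used at fit time, so recovery tests exercise the
  identical covariate pathway. If configured effects would push
  `E_i λ_i` past the population, the generator refuses (or caps `λ` with
  a warning, configurable) — note that because `E_i` is proportional to
  population, resampling the population cannot repair this condition.

What the generator does **not** emulate: real municipal geography and
contiguity irregularity, spatially structured covariates (components are
drawn independently across units, so spatial confounding between `φ` and
`X` is absent), survey sampling error in the death counts, and missing
data. Passing recovery tests on these data therefore demonstrates
correctness of the machinery under the model's own assumptions, not
robustness to the ways real data violate them.

## Problem sizes and numerical choices

The test suite and acceptance script scale simulations to what a laptop
core handles comfortably while keeping the statistical checks meaningful:
recovery uses 20 replicates of a 10 × 10 lattice with 1,500 burn-in /
2,500 retained per chain, hotspot detection 10 replicates of a 12 × 12
lattice with an embedded 3 × 3 doubled-risk cluster, and DIC model
selection 20 replicate pairs on 7 × 7 lattices; the analysis scripts run
the full 248-unit configuration with 2,000 / 5,000 per chain. Degenerate
inputs are handled explicitly: constant vectors z-score to zeros with a
warning, a constant component yields undefined correlations reported as
missing, an all-equal composite yields an empty service map with a
warning, zero total deaths make expected counts zero and the model is
declared unfittable, and quantile ties in the inequality flag resolve by
the strict-inequality rule. Equality comparisons against oracles use
1e-12 tolerances; the CAR eigen-sampler treats eigenvalues below
`max(eig) × 1e-10` as the null space.

## Known limitations

Inference is conditional on the contiguity graph supplied; the package
never derives adjacency from geometry. The intrinsic CAR model
oversimplifies neighbour dynamics (households use services across
boundaries); multiple-membership extensions are out of scope. The
ecological design warns against individual-level causal readings of the
fitted RRs, and the attributable-fraction projections inherit that
caveat: they quantify "what the fitted model implies if exposure were
removed", not an intervention forecast.
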