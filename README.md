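# servmort

Small-area spatial modelling of the mortality impact of municipal service
delivery.

`servmort` is an R package plus analysis workflow for epidemiologists and
health-policy analysts working with areal ("lattice") data: one row per
local municipality with a death count, a population, service-delivery
indicators, household income data, HIV seroprevalence and a density/metro
class, together with a neighbour-contiguity structure. It answers three
questions:

1. **Where** are the mortality and service non-delivery hotspots?
2. **How strongly** is poor service delivery associated with mortality,
   after adjusting for income inequality, density and HIV?
3. **How much** mortality could the provision of basic services avert,
   per municipality and nationally?

## The models

**Composite service (non-)delivery index.** Seven components — the
proportions with no water service, no toilet, no refuse disposal, no
electricity, no schooling, the proportion in informal housing and the
population-to-health-facility ratio — are z-scored across units
(`(x − mean) / sd`, sample sd) and summed with equal weight; higher =
poorer delivery. The model covariate is the rank-preserving transform
`sqrt(score − min(score))`. Income inequality per unit is the standard
pairwise-difference Gini, `G = mean|x_i − x_j| / (2 mean x)`, with the
upper tertile flagged "high inequality".

**BYM convolution CAR Poisson model.** For unit *i* with deaths `O_i` and
internally standardized expected counts `E_i` (`ΣE = ΣO`):

    O_i ~ Poisson(E_i λ_i),   log λ_i = α + X_i β + ε_i + φ_i

with iid heterogeneity `ε_i ~ N(0, σ²_ε)` and an intrinsic CAR
(conditional autoregressive) spatial field
`φ_i | φ_−i ~ N(mean of neighbours, σ²_φ/n_i)` under a sum-to-zero
constraint. Fitting is two-chain Metropolis-within-Gibbs MCMC (compiled
core) with vague Normal(0, 10⁶) priors on `α`, `β`, Gamma(0.5, 0.0005) on
both precisions, adaptive burn-in, a 5% Monte-Carlo-error stopping rule,
Gelman–Rubin convergence checks and DIC model comparison. A unit is a
hotspot when `P(λ_i > 1 | data) > 0.9` (stringent Richardson criterion);
a covariate is significant when `P(β > 0)` or `P(β < 0)` exceeds 0.95.

**Attributable fractions.** For a determinant with prevalence `p_e` and
relative risk `RR`, `AF = p_e(RR−1)/(1 + p_e(RR−1))`; per-unit projected
reductions are `observed rate × AF`, combined across determinants
multiplicatively on the residual, aggregated nationally by population
weight with a posterior uncertainty interval.

No survey microdata ship with the package. A first-class synthetic-data
generator emulates the study structure (248 municipalities on an 8 × 31
lattice in 9 pseudo-provinces, correlated service components, lognormal
incomes, Poisson deaths from a convolution risk field with realistic
effect sizes) so that every stage is testable, with known truth, end to
end. See `vignettes/methods.Rmd` for the full methods account.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
default synthetic study area and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # area table + GAL adjacency + truth
Rscript analysis/02_service_index.R  # composite index, correlations, provinces
Rscript analysis/03_fit_models.R     # null + multivariable BYM fits
Rscript analysis/04_hotspots.R       # exceedance-probability maps
Rscript analysis/05_attributable.R   # reduction index
```

Stage 3 prints the posterior relative risks next to the generative truth
(this exact output, seed 20070101):

```
posterior relative risks (95% BCI):
              covariate    rr rr_lower rr_upper p_rr_gt_1 significant
1          service_sqrt 1.840    1.788    1.894    1.0000        TRUE
2       inequality_high 1.129    1.070    1.191    1.0000        TRUE
3          hiv_centered 1.022    1.019    1.025    1.0000        TRUE
4 density_high_nonmetro 0.959    0.903    1.019    0.0862       FALSE
5    density_high_metro 0.733    0.681    0.788    0.0000        TRUE

recovery check against the generative truth:
             covariate true_rr posterior_rr
          service_sqrt    1.84        1.840
       inequality_high    1.14        1.129
          hiv_centered    1.02        1.022
 density_high_nonmetro    0.97        0.959
    density_high_metro    0.73        0.733
```

Reading: each unit of the transformed service score multiplies the
mortality rate by 1.84 (95% credible interval 1.79–1.89); high-inequality
municipalities carry 13% excess risk; each HIV percentage point adds 2%;
metro residence is protective (RR 0.73). Every interval covers its
generative value, and the multivariable model beats the null by 17.7 DIC
units. Stage 4 then flags 82/248 mortality hotspots and 101/248 service
non-delivery hotspots (72 municipalities on both maps), and stage 5
projects a national mean reduction of 12.9 deaths per 1000 (95% interval
12.3–13.6) if the five basic services were provided, ranging from 0.2 to
65 per 1000 across municipalities.

The same machinery runs from a single configuration file:

```r
library(servmort)
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "servmort"))
run_pipeline(cfg)   # simulate -> index -> fit -> map -> af, with manifest
```

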