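# vbgrowth

Random-effects von Bertalanffy growth models for sparse mark-recapture
size-at-age data, fitted by Laplace-approximated maximum marginal
likelihood with Empirical Bayes individual estimates.

## What it is for

Annual tagging studies of fish and other organisms yield longitudinal
length-at-age records in which most individuals are measured only once or
twice. Two things follow: repeated measures on the same individual are
strongly autocorrelated (size ranks persist), so treating the data as
cross-sectional biases group-level growth estimates; and no single
individual carries enough data to estimate its own growth curve.
`vbgrowth` is for ecologists and fisheries scientists who want to separate
*shared* determinants of growth (year-of-birth cohort, early-life
population density) from *individual* variation, predict unobserved
lengths-at-age of known individuals, and quantify the correlation between
growth rate and asymptotic size at the individual and cohort level.

## The model

Length-at-age follows the von Bertalanffy growth function

    L(t) = L∞ (1 − exp(−k (t − t0)))

with, for individual *i* in cohort *j*, log-linked linear predictors

    log k_ij  = β0 + β1j + β2 x_j + σ_u u_ij
    log L∞_ij = α0 + α1j + α2 x_j + σ_v v_ij

where `u, v ~ N(0,1)` are standardized individual random effects, `x_j` is
cohort density in the first year of life, and `t0` is a shared
population-level parameter. Observations are Gaussian around the individual
curve with residual SD `σ_ε` (mm). The marginal likelihood integrates
`(u, v)` out per individual via a Laplace approximation around the joint
mode (inner damped Newton in C++, analytic derivatives); the outer problem
is bounded quasi-Newton with a max-gradient < 1e-4 convergence criterion.
Individual parameters are Empirical Bayes posterior modes — shrunk toward
the population curve in proportion to data sparsity. Models over the
none/density/cohort predictor grid are ranked by AIC.

## Worked example

Simulate a 200-fish annual mark-recapture study from known truth
(L∞ = 330 mm, k = 0.37 1/y, t0 = −0.38 y, σ_u = σ_v = 0.22, σ_ε = 8 mm),
fit the no-predictor model, and inspect recovery:

```r
library(vbgrowth)

sim <- simulate_growth(sim_config(n_fish = 200, seed = 42))
fit <- fit_vbgf(sim$data)
fit
#> <vbgf_fit: no predictors>
#>   logLik -3782.05 | AIC 7576.1 | 6 parameters | 200 fish, 886 obs
#>   converged: TRUE (max gradient 1.18e-07)
#>   L_inf 329.6 mm | k 0.376 1/y | t0 -0.35 y

population_parameters(fit)
#> # A tibble: 3 × 5
#>   parameter estimate std.error conf.low conf.high
#> 1 L_inf      330.      5.00     320.      340.
#> 2 k            0.376   0.00809    0.360     0.392
#> 3 t0          -0.352   0.0239    -0.399    -0.305
```

The truth lies inside every interval. Per-fish Empirical Bayes estimates
and the individual-level correlation between the two growth parameters
(restricted to fish with ≥ 3 captures, since single-capture fish carry an
artefactual near-perfect correlation):

```r
head(eb_random_effects(fit), 3)
#>   fish_id cohort_id n_captures       u      v     k  linf
#> 1 f0001   2000               4  0.0196 -1.85  0.377  224.
#> 2 f0002   2000               3 -0.740   0.419 0.323  360.
#> 3 f0003   2000               6  0.130   1.33  0.386  435.

empirical_correlation(fit, min_captures = 3)
#>   level           r p.value     n
#> 1 individual 0.0351   0.636   184
```

The data were generated with independent effects, and the recovered
correlation is near zero as it should be. Model selection, hold-out
validation and per-cohort least-squares comparisons follow the same
data-frame-in/tibble-out style: `select_growth_models()`,
`validate_growth_model()`, `compare_cohort_fits()`; each result has
`tidy()`/`glance()`/`autoplot()` methods. A thin command-line front end
over the same functions lives in `inst/cli/vbgrowth.R`
(`simulate` / `fit` / `select` / `validate`).

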