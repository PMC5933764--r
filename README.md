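# otolithIPM

Temperature-dependent fish growth from otolith increments, projected
across ages with a cohort integral projection model (cIPM).

## What it is for

Fish otoliths record a fish's whole growth history as annual rings
(annuli), so a sample of otoliths yields a *longitudinal* panel of
annual growth increments — unlike the usual cross-sectional
size-at-age snapshot, it lets each year's growth be matched to the
water temperature of that year. This package, built around the biology
of gilthead seabream (*Sparus aurata*) in Mediterranean coastal
lagoons but generic in its interfaces, provides the full analysis:

* **Growth models.** The Walford size–size regression
  `Z' = β₁Z + α₀ + ε` of otolith radius at year *t* on radius at year
  *t−1*, its temperature extension `Z' = β₁Z + β₂T + α₀ + ε`, an
  initial-size model `Z = β₁T + α₀ + ε` for the radius at the first
  birthday, an otolith-to-length allometry `L = β₁Z + α₀ + ε`
  (optionally with exponential variance), and linear mixed versions
  with crossed random intercepts for formation year and individual
  fish (fitted by ML via lme4, so AIC is comparable across
  fixed-effects structures).
* **Von Bertalanffy parameters** from the Walford fit:
  `K = −ln β₁`, the otolith asymptote `Z∞ = α₀/(1−β₁)`, `L∞` via the
  allometry, and the growth-performance index
  `φ′ = ln K + 2 ln L∞` (L∞ in cm).
* **The cIPM.** A Gaussian growth kernel advances the otolith-size
  density one age class, `n(Z', t+1) = ∫ g(Z'|Z) n(Z, t) dZ`
  (midpoint rule, 500-node mesh by default, no mortality), and a
  second kernel maps each age's density to total length. Scenarios at
  reference ±1 °C quantify how warming shrinks size-at-age, with
  nonparametric bootstrap CIs (cluster-resampling formation years by
  default) and prediction intervals.
* **A calibrated synthetic-data generator** that simulates the exact
  assumed generating process (crossed year/fish effects included), so
  every stage is testable end to end without field data.

## Worked example

Simulate a 400-fish world at the published coefficients, fit the model
suite, and project under temperature scenarios:

```r
library(otolithIPM)
pop   <- generate_population(truth_config(seed = 1))
pairs <- build_growth_pairs(pop$increments)

lm1  <- fit_walford(pairs)
lm2  <- fit_walford_temp(pairs, pop$temps)
lm4  <- fit_allometry(pop$fish)
mod3 <- fit_mixed_growth(pairs, pop$temps)
compare_models(list(lm1 = lm1, lm2 = lm2, mod3 = mod3))
#> Model comparison (ML fits, same data)
#>   model      aic delta_aic     r2
#> 1  mod3 -1250.44      0.00 0.8934
#> 2   lm2 -1144.64    105.81 0.8958
#> 3   lm1 -1116.25    134.19 0.8906

vb_transform(lm1, lm4)
#> von Bertalanffy parameters (from Walford fit)
#>   K         = 0.3285 / yr
#>   Z_inf     = 2.891 mm
#>   L_inf     = 434.2 mm
#>   phi-prime = 6.429 (L_inf in cm)

res <- bootstrap_projection(pairs, first_increments(pop$increments),
                            pop$fish, pop$temps, B = 500, seed = 1,
                            max_age = 3)
compare_scenarios(res, ages = 2:3)
#>    scenario age percent_change
#> 1    minus1   2      -7.225221
#> 2    minus1   3      -7.153135
#> 3 reference   2       0.000000
#> 4 reference   3       0.000000
#> 5     plus1   2       7.225221
#> 6     plus1   3       7.153135
```

Reading this: the mixed model with temperature (mod3) wins the AIC
comparison; the fitted Walford slope maps to a growth coefficient
K ≈ 0.33/yr and an asymptotic length ≈ 434 mm for this simulated
world; and a +1 °C summer leaves two- and three-year-olds about 7%
shorter on average, with bootstrap CIs in `summary(res)`.

With *published* coefficients instead of fitted ones, the
coefficient-injection constructor reproduces published point
projections exactly:

```r
lm2 <- growth_fit("walford_temp", 2.120, slope_Z = 0.7033,
                  slope_T = -0.0631, sigma = 0.08)
lm3 <- growth_fit("initial_size", 2.937, slope_T = -0.0718, sigma = 0.2)
lm4 <- growth_fit("allometry", -74.62, slope_Z = 176.38, sigma = 20)
summary(project_scenarios(lm3, lm2, lm4, max_age = 3))
```

which gives mean total lengths of 253.3 mm (age 2) and 302.0 mm
(age 3) at the 20.48 °C reference temperature, versus 233.3 mm and
276.8 mm at +1 °C — reductions of 7.9% and 8.4%.

A higher-level pipeline (`pipeline_config()`, `run_simulate()`,
`run_fit()`, `run_project()`, `run_report()`) chains the stages on a
run directory with seed and config-hash provenance in every artifact.

## Documentation

The methods vignette (`vignettes/otolith-growth-cipm.Rmd`) documents
the model suite and its assumptions, the discretization and its
analytic oracle, the bootstrap resampling-unit choice, what the
synthetic generator does and does not emulate, and known limitations.
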