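# opuntiacam

Invasive prickly pear (*Opuntia* spp.) restructures East African savanna
habitats, and large mammals may respond by avoiding or favouring invaded
sites, by changing how often they pass through them, or by shifting their
activity into the night. `opuntiacam` is an end-to-end, fully tested R
implementation of a camera-trap inference pipeline for exactly this kind of
study, aimed at quantitative ecologists who want every stage — from raw
volunteer classification votes to posterior effect summaries — reproducible
and verifiable against synthetic data with known ground truth.

## What it does

* **Synthetic studies** (`simulate_study()`): paired camera sites inside
  500 × 500 m grid squares (high-*Opuntia* site + lower-cover site 50–70 m
  away), two seasons, daily detection / count / night-count observations
  from the same models the package fits (with a spatial Gaussian-process
  field), distance-sampling transect counts, and 12-volunteer vote vectors
  per image with a configurable confusion structure.
* **Consensus classification** (`consensus_classify()`): a species is
  present when ≥ 66% of an image's volunteers voted for it; images with
  vote-distribution Shannon entropy above 1 are discarded; expert labels
  override. Accuracy audits via `classification_accuracy()`.
* **Day/night astronomy** (`sun_times()`, `is_night()`,
  `lunar_fraction()`): NOAA solar-position dawn/dusk at civil twilight and
  a low-precision lunar illuminated fraction.
* **Distance sampling** (`fit_distance_model()`): Poisson-multinomial model
  with half-normal detection `g(x) = exp(-x²/2σ²)` per *Opuntia* size
  class; abundances convert to volumes with hemisphere-based per-stand
  constants (0.260 / 7.070 / 32.725 m³) and to per-metre and whole-square
  volumes.
* **Causal covariate selection** (`habitat_dag()`, `total_effect_sets()`):
  minimal back-door adjustment sets on an editable causal graph, honouring
  latent nodes and leaving mediated paths open so the estimand is the total
  effect.
* **Three Bayesian habitat-use models** (`fit_occupancy()`,
  `fit_daily_counts()`, `fit_night_activity()`): marginalized site
  occupancy (camera-model intercepts and daily temperature in the detection
  sub-model), NB2 daily counts, and binomial night activity with an
  *Opuntia* × lunar-illumination interaction — all with season-specific
  effects, standardized covariates (lunar illumination excluded), and an
  exponentiated-quadratic GP spatial random effect, sampled by the
  package's own MCMC engine (adaptive Metropolis blocks + elliptical slice
  sampling for the GP field) with rank-normalized split-R̂ / bulk-ESS
  diagnostics.
* **Effect reporting** (`p_positive()`, `compatibility_intervals()`,
  `marginal_effect_curve()`, `effect_matrix()`, plus `autoplot()` /
  `plot_effect_matrix()`): P(+ve effect) matrices and nested
  95/89/80/70/60/50% compatibility intervals on the response scale.
* **Orchestration** (`run_pipeline()`, `validate_tables()`): staged runs
  with a manifest, content-hash caching and schema/referential validation
  of every CSV artefact.

## Worked example

```r
library(opuntiacam)

study <- simulate_study(species = "impala", seed = 1,
                        n_squares_s1 = 20, n_squares_s2 = 8, days = 30)
study
#> <synthetic_study: 56 sites, 1 species, 1680 obs rows, 172 images, 2064 vote rows>

table(consensus_classify(study$votes)$status)
#> consensus    expert
#>       149        23

total_effect_sets(habitat_dag())
#> [[1]]
#> [1] "dist_river" "dist_road"  "livestock"
```

All 172 images reach a classification (149 by the 66% volunteer rule, 23 by
expert override), and the causal graph selects distance-to-river,
distance-to-road and livestock use as the unique minimal adjustment set for
the total *Opuntia* effect. Distance sampling recovers the generator's
detection scales (truth 2 / 4 / 6 m for the S / M / L size classes):

```r
fit_ds <- fit_distance_model(study$transects, chains = 2,
                             warmup = 400, iters = 400, seed = 2)
tidy(fit_ds)
#> # A tibble: 6 × 6
#>   size_class parameter estimate std.error    q5   q95
#> 1 L          sigma_m       5.32    0.511   4.63  6.12
#> 2 L          lambda        9.63    0.950   8.22 11.1
#> 3 M          sigma_m       3.97    0.199   3.69  4.30
#> 4 M          lambda       23.7     1.51   21.6  26.1
#> 5 S          sigma_m       1.92    0.0784  1.79  2.03
#> 6 S          lambda       39.8     3.17   34.9  45.5
```

The occupancy model then estimates the seasonal *Opuntia* effect with its
spatial GP, and the effect summaries give the reporting quantities:

```r
obs <- study$observations[study$observations$species == "impala", ]
fit <- fit_occupancy(obs, study$sites, gp = TRUE,
                     chains = 2, warmup = 1000, iters = 1000, seed = 3)
p_positive(fit, "beta_opuntia_s1")
#> [1] 0.6845
compatibility_intervals(fit, "beta_opuntia_s1")
#> # A tibble: 6 × 3
#>   level   lower upper
#> 1    95 -0.440  0.824
#> 2    89 -0.343  0.725
#> 3    80 -0.258  0.626
#> 4    70 -0.190  0.541
#> 5    60 -0.111  0.461
#> 6    50 -0.0614 0.411
```

A sign probability of 0.68 means the data lean positive but the direction
is not settled at this study size (56 sites; the generating slope was
+0.5 per standardized unit of cover); the nested intervals show the same
thing on the logit scale. `autoplot(marginal_effect_curve(fit))` draws the
occupancy-probability curve against raw percent cover, and
`effect_matrix()` assembles the species-by-condition P(+ve effect) table
once several species and model types are fitted.

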