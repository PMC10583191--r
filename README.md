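# phenospan

Season length of perennial herbs from shoot size trajectories.

Perennial plants in seasonal climates rebuild their above-ground shoots
every year, and species differ enormously in how long they keep them: the
growing season of one species may last ten weeks, another's nearly the
whole year. `phenospan` quantifies this from the raw field protocol —
repeated measurements of individual shoots (upper width, lower width,
vegetative length) across a season — and analyses what drives the
interspecific differences.

The pipeline:

1. **Size & splitting** — shoot dimensions become a scalar size, the cube
   root of a conical-frustum volume
   `V = πL(w_u² + w_u w_l + w_l²)/12`; each shoot's trajectory is split
   into growth and decline at the maximum of a cubic smoothing spline.
2. **Spring growth** — per species, a logistic
   `x(t) = A + (K − A)/(1 + e^{−b(t−a)})` is fitted to all shoots jointly
   by nonlinear mixed-model regression (`nlme`), with shoot-level random
   final size `K` and AIC selection among random-effect structures.
   Outputs: day of peak growth `a`, log standardized growth rate `ln b`,
   and season start `a − ln3/b` (the 25% crossing).
3. **Autumn senescence** — per-shoot decline splines (`smooth.spline`,
   `spar = 0.5`) are normalized and averaged into a species profile, from
   which crossing dates give the senescence date (first 50%), pace
   (`1/(t₅% − t₉₅%)`), shape (`log(C/D)`, late vs early half-duration) and
   season end (first 25%). Species never dropping below 25% overwinter and
   get season length 365 d.
4. **Comparative inference** — season length = end − start is analysed by
   all-subsets AICc multimodel averaging of trait and niche effects, PCA
   with season length passively projected, standardized major axis
   regression of start on end, and a layered piecewise structural equation
   model (niche → traits → phenology → season length) with
   directed-separation tests combined by Fisher's `C = −2Σln p`.

A synthetic-data generator with closed-form ground truth (logistic rise
joined to a Richards-type decline, so every fraction crossing is analytic)
backs the whole pipeline with parameter-recovery tests.

## Worked example

```r
library(phenospan)

cfg <- generation_config(n_species = 6, rng_seed = 42)
ds  <- simulate_dataset(cfg)           # truth, covariates, measurements
ex  <- extract_phenology(ds$measurements)
ex$records[, c("species_id", "peak_day", "log_b", "season_start",
               "sen_date", "sen_pace", "season_end", "season_length")]
#>   species_id peak_day  log_b season_start sen_date sen_pace season_end season_length
#> 1      sp001    134.6 -2.116        125.5    240.6 0.009881      261.4         135.9
#> 2      sp002    126.6 -2.311        115.6    240.6 0.011236      259.8         144.2
#> 3      sp003    130.2 -2.267        119.6    277.7 0.010776      296.7         177.1
#> 4      sp004    130.3 -2.043        121.8    255.5 0.011074      274.1         152.3
#> 5      sp005    111.3 -2.056        102.7    278.3 0.009615      299.7         197.0
#> 6      sp006    129.4 -1.918        122.0    283.1 0.011062      302.6         180.6
```

Each row is one species: its growth curve peaks around day 111–135
(spring growth is tightly synchronized), while senescence dates spread
from day 240 to day 283 — so the differences in season length (136–197 d
here) come mostly from autumn, the central empirical pattern this kind of
analysis is after.

How completely do the five phenological variables determine season length?

```r
rec <- truth_phenology(generate_species(generation_config(n_species = 200,
                                                          rng_seed = 42)))
regress_length_on_phenology(rec)
#> Season length ~ phenology (standardized, n = 200, R^2 = 0.997)
#>       term estimate  ci_low ci_high
#>   peak_day  -0.6073 -0.6159 -0.5988
#>      log_b  -0.0961 -0.1047 -0.0875
#>   sen_date   0.9212  0.9122  0.9303
#>   sen_pace  -0.1697 -0.1788 -0.1607
#>  sen_shape   0.0252  0.0157  0.0346
```

A late senescence date lengthens the season almost one-for-one; a late
growth peak and a fast spring or autumn shortens it.

The stage-by-stage pipeline, with CSV artifacts and a JSON manifest, runs
via `run_pipeline("all", pipeline_config(out_dir = "run1", rng_seed = 1))`
or the thin CLI wrapper `inst/scripts/phenospan <simulate|extract|analyze|sem|all>`.

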