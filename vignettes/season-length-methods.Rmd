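---
title: "Deriving species-specific season length from shoot size trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving species-specific season length from shoot size trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenospan)
```

## The problem

Perennial herbs in seasonal climates build their above-ground shoots anew
each year. How long a species keeps photosynthetically active tissue — its
*season length* — is set by two largely independent processes: spring
growth, which is strongly synchronized across species by frost risk, and
autumn senescence, which varies widely. `phenospan` implements a complete
pipeline for quantifying both from repeated measurements of individual
shoots, and for asking how functional traits (height, lateral spread, SLA,
LDMC) and niche positions (Ellenberg-style indicator values, disturbance
regime) shape the resulting season lengths.

The pipeline has four stages: (1) convert raw shoot dimensions to a scalar
size and split each shoot's seasonal trajectory at its smoothed maximum;
(2) fit a logistic growth curve per species by nonlinear mixed-model
regression and extract spring parameters; (3) build an averaged senescence
profile per species from per-shoot smoothing splines and extract autumn
parameters; (4) assemble season length and run the comparative analyses
(multimodel inference, ordination, piecewise structural equation models).
A synthetic-data generator with closed-form ground truth accompanies every
stage, so each estimator has a parameter-recovery test surface.

## Plant size and trajectory splitting

Each measurement is a triplet: upper width, lower width and vegetative
length of a shoot (cm). We summarize it as the cube root of the volume of a
conical frustum,

$$V = \frac{\pi L}{12}\left(w_u^2 + w_u w_l + w_l^2\right),
\qquad \text{size} = V^{1/3},$$

which interpolates smoothly between a cone (one width zero) and a cylinder
(equal widths) and uses all three dimensions symmetrically. The frustum is
a modelling choice — the measurement protocol does not dictate a solid —
so `compute_size()` accepts any volume function with the same signature if,
say, an ellipsoid is preferred. The cube root puts size on a length scale,
so multiplicative measurement errors act proportionally.

Each shoot's seasonal trajectory is split into a growing and a declining
part by fitting a cubic smoothing spline to (day, size) and locating its
maximum on a 0.1-day grid (`split_trajectory()`). The smoothing level for
this split is chosen by generalized cross-validation by default and can be
fixed via `spar`. Ties at the maximum break toward the earliest day.
Measurement points at or before the split day form the growth phase, points
at or after it the decline phase; a point exactly at the maximum belongs to
both. When the spline maximum falls strictly between two measurement days,
the last growth point is also included in the decline phase as an anchor:
without it the decline spline would start below the peak and the 95%
crossing that the senescence pace needs could be undefined. Days are
counted continuously from January 1 (day 1) and simply continue past 365
for observations in the following January.

## Spring growth

Growth-phase points of all shoots of one species are fitted together with
the simplified general logistic

$$x(t) = A + \frac{K - A}{1 + e^{-b\,(t - a)}},$$

where $A$ is the projected initial size, $K$ the projected final size, $a$
the day of peak growth (the inflection) and $b$ the standardized growth
rate: the derivative at the inflection is $b(K-A)/4$, so for $A = 0$ the
familiar identity $b = 4d/K$ holds. Fitting uses `nlme::nlme` with maximum
likelihood. The candidate set crosses $\{A\ \text{free},\ A = 0\}$ with
shoot-level random-effect structures $\{K\ \text{only};\ K$ plus one of
$A, a, b\}$ — $K$ is always random because shoots genuinely differ in final
size, and at most one further parameter is allowed to vary to keep the
variance components identifiable from seven shoots. Random-effect pairs are
uncorrelated (`pdDiag`); allowing a covariance adds a parameter that seven
shoots rarely support. The candidate with the lowest AIC wins.

Nonlinear mixed models are initial-value sensitive. Starting values come
from a pooled logistic self-start; non-converging candidates are restarted
from initial values jittered by up to ±50% (a, shifted by up to ±15 days),
up to `max_restarts` times, and estimates are only accepted inside a
plausibility envelope ($a$ within 60 days of the observed span, $b \in
(10^{-4}, 5)$, $K$ below ten times the largest observed size). If the
residual variance is essentially zero — exactly noiseless data, as in
validation runs — the mixed model degenerates; a fixed-effects logistic
with per-shoot $K$ (fitted with `nls` and a scale offset, which tolerates a
perfect fit) takes over.

Spring outputs per species: `peak_day` ($a$), `log_b` (natural log; the
growth rate arises multiplicatively, so analyses use the log), and
`season_start`, the day the curve reaches 25% of its span, in closed form
$a - \ln 3 / b$. The 25% level is deliberate: smaller fractions sit in the
flat early part of the curve where measurement artefacts dominate. $A$ is
estimated when the data ask for it but excluded from downstream analyses.

## Autumn senescence

The decline phase of each shoot is smoothed with a cubic spline at a fixed
smoothing level, `spar = 0.5` (`fit_decline_spline()`); with fewer than
four decline points the shoot falls back to linear interpolation with a
warning. Each shoot's spline is evaluated on a common daily grid restricted
to its own observation span, normalized by that shoot's own maximum, and
averaged pointwise across shoots (`average_profile()`). Normalizing by the
individual rather than the species maximum makes the profile robust to the
large size differences among shoots; shoots not observed on a grid day are
dropped from the average there rather than extrapolated.

From the averaged fraction-of-maximum curve we take (`crossing_date()`,
with linear interpolation to 0.1 day between grid days):

* **senescence date** — first day at or below 50%;
* **senescence pace** — $1/(t_{5\%} - t_{95\%})$, using the *last* day at
  or above 95% and the *first* day at or below 5%, so non-monotone summer
  dips count from the final departure from the plateau;
* **senescence shape** — $\log(C/D)$ with $C = t_{5\%} - t_{50\%}$ and
  $D = t_{50\%} - t_{95\%}$, positive when the late half of the decline
  takes longer than the early half. The opposite sign convention is one
  flag away (`flip_shape`); the printed formula is the default;
* **season end** — first day at or below 25%.

A species whose profile never falls below 25% *overwinters*: its season
end is undefined and its season length is set to 365 days. Undefined 95% or
5% crossings leave pace and shape missing, and such species are excluded
from the analyses that need them — exclusion reasons are tracked
explicitly in the assembled records.

Season length is season end minus season start (`assemble_pheno_records()`),
capped at 365 days.

## Validation against synthetic ground truth

The generator (`generate_species()`, `render_measurements()`) emulates the
garden protocol: 7 shoots per species, biweekly measurement from early
January (days 7, 21, …), three dimensions per shoot. The true trajectory is
a logistic rise joined piecewise to a Richards-type decline
$K_i\,(1+e^{s (t-m)})^{-\theta}$ at their intersection, so every fraction
crossing of the decline keeps the closed form
$t_q = m + \ln(q^{-1/\theta} - 1)/s$: pace, shape and season end all have
analytic truth. The asymmetry $\theta$ gives nonzero true shape; $\theta$
and decline span are chosen so both signs occur. Shoot-level final sizes
are lognormal around the species $K$ (CV 0.2), and each measured dimension
carries independent mean-one lognormal noise (default CV 5%) — sizes are
strictly positive and errors scale with magnitude, which is how field
measurement error behaves. Baselines ($a = 120$, $b = 0.12$/d, $K = 20$ cm,
$m = 260$, $s = 0.08$/d, $\theta \in [0.3, 3]$) describe a temperate season;
the across-species spreads (e.g. 12 days in $a$, 18 days in $m$) and the
default path matrices linking niche to traits to phenology are conventions
chosen once to resemble realistic interspecific variation, not fitted
values. Species covariates follow a layered linear model — niche scores
(independent normals on the 1–9 indicator scale) → traits → growth and
senescence parameters — with standardized path coefficients, so the
structural analyses also have known truth.

What the generator does *not* emulate: weather forcing, interannual
variation, spatial structure, non-stationary measurement error, and the
truncation of real field campaigns (shoots stop being measured when the
plant is gone). Passing recovery tests therefore demonstrate correctness of
the estimators under the stated error model, not robustness to everything
field data can do.

On this design the suite recovers the day of peak growth to well under a
day (RMSE), $\ln b$ to a few hundredths, the senescence date to about two
days (median), and season length to under five days (median). One
quantity is systematically harder: the senescence **pace**. The fixed
`spar = 0.5` smoothing rounds the shoulders of the decline when points are
14 days apart, moving the 95% crossing earlier and the 5% crossing later,
which widens the span by roughly a fifth at the default decline steepness
— an intrinsic property of that smoothing level at biweekly resolution,
not of the implementation: with daily sampling the same code recovers all
crossings to within about a day. Comparative analyses are unaffected in
rank terms, but absolute pace values should be read with this bias in
mind.

## Comparative analyses

**Multimodel inference** (`all_subsets()`, `average_effects()`): every
subset of a predictor set (traits or niche variables) is fitted by OLS on
z-scored data and ranked by AICc ($-2\ell + 2k + 2k(k+1)/(n-k-1)$, $k$
counting intercept and residual variance). Within the window of models
less than 3 AICc units from the best, Akaike weights are renormalized;
a predictor's *importance* is the summed weight of window models containing
it, and its effect is the weight-averaged coefficient over only those
models (conditional averaging — matching the convention of averaging
"estimates from models that included the term"). Confidence intervals are
weight-averaged per-model interval endpoints; model-averaged standard
errors are a defensible alternative, and the choice is recorded in the
output metadata. Exhaustive enumeration replaces stepwise deletion; with at
most 12 predictors the full set is cheap and removes path dependence.
Lateral spread for non-clonal species is imputed at 0.5 cm/yr before
log-transformation, as is conventional for clonal-trait databases.

**Ordination** (`pca_with_supplementary()`): PCA of the correlation matrix
of the phenological variables, with season length projected passively as
its correlation with each axis' scores — it labels the ordination without
influencing it.

**Start–end allometry** (`sma_regression()`): standardized major axis
regression, slope $\mathrm{sign}(r)\, s_y/s_x$, treats season start and end
symmetrically since neither is an error-free predictor of the other.

## Piecewise structural equation models

The causal hierarchy is layered: niche → traits → phenology → season
length (`default_sem_spec()` starts fully connected between adjacent
layers). Fitting is local (`sem_fit_local()`): each endogenous variable is
regressed on its parents by OLS on z-scored data, so path coefficients are
standardized partial regression slopes. Global fit is assessed by directed
separation: every non-adjacent ordered pair not linked by a correlated
error yields an independence claim, tested by adding the upstream variable
to the downstream variable's parent regression and reading its t-test
p-value — the standard test form for local estimation, since the
likelihood-based alternative is unavailable without a joint model.
Conditioning sets use the parents of the later variable only; causal order
is layer order with alphabetical tie-breaks, which makes the basis set
deterministic. The claims combine into Fisher's
$C = -2\sum \ln p_i \sim \chi^2_{2k}$.

Refinement (`sem_refine()`) mirrors how such models are built in practice:
among significant claims ($p <$ `alpha_add`, default 0.05) the smallest-p
pair gains a directed edge if the variables sit in different layers
(earlier → later) or a correlated error if they share a layer; edges whose
removal lowers the whole-model AIC are pruned; iteration stops when no
claim is significant and the global p exceeds `stop_p` (default 0.2), or at
a cap with a non-convergence flag. Two whole-model AIC variants are
reported because the literature uses both: the sum of component-regression
AICs (with intercept-only components for exogenous nodes, so sums stay
comparable as the graph changes — this variant drives pruning) and the
Fisher's-C-based $C + 2K$. Every addition and removal is logged in an
audit trail.

Calibration is part of the test suite: under the generating DAG the global
p-value is uniform and refinement adds nothing in ~95% of replicates at
$n = 200$; a single omitted path of standardized strength 0.5 is the first
edge recovered essentially always; and path signs recovered from the
generator's own covariate structure agree with the generating signs in
over 95% of cases.

## Numerical choices and degenerate inputs

* Splitting needs ≥ 4 points with ≥ 2 distinct positive sizes; all-zero
  trajectories are an error, not a silent zero.
* Growth fitting needs ≥ 2 shoots with ≥ 4 growth points; per-candidate
  diagnostics ride along on the fit-failure error.
* The profile grid is daily; crossings interpolate linearly to 0.1 day.
  Argmax ties break toward the earliest day.
* Collinear predictors in the season-length regression fall back to a
  pseudo-inverse with a warning (no confidence intervals).
* A claim p-value of exactly 0 makes Fisher's C infinite; this is raised
  as an error naming the claim rather than returned as a number.
* Seeds determine everything: the generator derives its draws from
  `rng_seed`, the measurement rendering from `rng_seed + 1`, and the
  pipeline seeds the (rarely used) restart jitter, so a manifest's seed
  reproduces every artifact byte for byte.

## Problem sizes used in validation

The shipped tests run the full extraction on 20 species × 7 shoots at
biweekly cadence (the reference design), a 3-species noiseless daily run
for exactness checks, 100-replicate simulations at $n = 200$ for the SEM
and multimodel calibration, and 50 replicates for path-sign agreement —
sizes at which each property is informative while the whole suite stays
interactive.

## Known limitations

* The senescence-pace bias at biweekly cadence discussed above.
* Decline splines assume a single senescence episode; repeated cut-back
  and regrowth (mowing, herbivory) will confuse the split.
* The SEM layer for phenology treats the five variables as jointly
  Gaussian after z-scoring; strongly bimodal senescence dates stretch that
  assumption.
* Phylogenetic non-independence is deliberately out of scope; all
  regressions treat species as exchangeable.
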