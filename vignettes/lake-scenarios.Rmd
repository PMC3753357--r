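---
title: "Methods: projecting lake eutrophication under catchment-pressure scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting lake eutrophication under catchment-pressure scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling approach

Cultural eutrophication — nutrient enrichment driving excess phytoplankton
growth — is the dominant water-quality problem of small shallow lakes and
reservoirs in periurban landscapes. Estimating nutrient loads directly
requires per-land-use export coefficients that do not transfer between
regions. This package instead follows a minimal-parameterisation,
space-for-time strategy: chlorophyll *a* (Chla, µg/L), the standard proxy
for phytoplankton biomass and trophic state, is predicted from
catchment-scale descriptors that are cheap to extract from GIS layers, and
management scenarios are expressed as multiplicative changes to two of
those descriptors.

The predictors, in the package's fixed encoding order, are:

| symbol | column | meaning | units |
|---|---|---|---|
| S | `s_ratio` | catchment:lake area ratio, the nutrient-load proxy | — |
| LF | `lf_pct` | forest/semi-natural cover of the catchment | % |
| LA | `la_pct` | agricultural cover | % |
| LI | `li_pct` | impervious (urban) cover, the population-density proxy | % |
| Id | `drainage_density` | waterway length per catchment area | km/km² |
| D | `depth_m` | lake mean depth (buffering capacity) | m |
| — | `altitude_m` | altitude (floodplain/aquifer influence) | m |
| T | `season` | season of the observation, one-hot encoded | — |

Two ensemble-of-trees models are fitted on the lake × season observations:
a regression forest for Chla as a continuous response, and a
classification forest for the binomial state Chla > 25 µg/L, the
"significant eutrophication" boundary of the OECD fixed-boundary system.
Random forests are used because the descriptor–Chla relationships are
non-linear with threshold behaviour and interactions, which defeats
linear-model approaches at this scale. The numeric predictors are z-scored
with training-set statistics (sample standard deviation, n − 1). Tree
ensembles are invariant to monotone per-feature transforms, so this changes
no prediction; it is retained because the original analysis normalised its
inputs and because standardised features make the persisted statistics
useful for diagnostics.

Forest hyperparameters follow the classical conventions (500 unpruned
trees; `mtry` = ⌊p/3⌋ for regression and ⌊√p⌋ for classification; terminal
node sizes 5 and 1) and are configurable via `forest_hyperparams()`. Chla
is modelled on the raw scale: trees are scale-robust, and the raw scale
keeps the grid aggregates in measurement units. Classification ties (vote
fraction exactly 0.5) resolve to "not eutrophic", mirroring the strict
"> 25" rule under which a value exactly at the boundary is not eutrophic.

## Validation protocol

`repeated_holdout()` implements the evaluation protocol: 30 random 80/20
splits; per repeat, normalisation statistics and both models are computed
on the training side only, and the held-out side is scored by R² for the
continuous model and Cohen's kappa for the binomial one; the per-repeat
values are averaged. Two choices deserve notice:

* **R² definition.** R² is the squared Pearson correlation between
  observed and predicted values (the usual reading of "R² between observed
  and predicted"). The `1 − SSE/SST` form, which also penalises bias and
  can be negative, is available as `method = "nse"`.
* **Split unit.** By default whole lakes travel together, so the four
  seasonal observations of a lake never straddle the split — splitting
  observations would leak lake identity through the repeated catchment
  descriptors and flatter the scores. Observation-level splitting is
  available (`split_unit = "observation"`) for fidelity experiments, and a
  pooled-predictions mode (`pooled = TRUE`) complements the per-repeat
  mean, since "averaging the predictions over repeats" can be read either
  way.

Repeats whose test split is degenerate (a single truth class for kappa,
zero variance for R²) record a missing value and are excluded from the
mean with a warning rather than failing the run.

## The scenario engine

Management scenarios scale the two actionable pressures: `m_S` multiplies
the load proxy S (water-treatment investment reduces it; intensification
raises it) and `m_LI` multiplies the impervious cover (demographic
change). Both axes run from 0 (zero impact) to 2 (doubling) in 2% steps —
a 101 × 101 grid. When LI is scaled, the freed or consumed cover is
rebalanced across LA and LF *keeping their ratio constant* (regional
housing economics make conversion between agriculture and forest
unlikely); `m_LI·LI` is capped at 100%, at which point LA = LF = 0. The
physical areas, depth, drainage density and altitude are left unchanged:
the S multiplier models a change of load per unit catchment, not of
geography.

Per grid cell and stratum (all lakes / drainage / seepage — lakes on and
off the stream network respond very differently), the engine aggregates
the mean predicted Chla and the eutrophic frequency (% of lake × season
predictions > 25 µg/L). The frequency is computed from thresholded
regression predictions by default; `freq_mode = "classification"` uses the
binomial model's majority vote instead. The analysis drivers use the
classification mode for the recovery/compensation threshold scans because
those quantities are read off the binomial model's frequency surfaces,
while the mean-Chla surfaces come from the regression model.

Derived analyses:

* `mean_response_curve()` slices the grid (grid points only, no
  interpolation — scan results are deliberately multiples of the 2% step).
* `characterize_curve_shape()` contrasts a straight line with a
  Michaelis–Menten-type saturating curve by small-sample-corrected AIC;
  ties, constant curves and failed saturating fits fall back to "linear",
  the simpler model. Saturating load–response curves indicate lakes so
  overloaded that only a large load reduction produces improvement;
  near-linear curves indicate proportional gains.
* `delta_chla_contrast()` opposes complete urban removal (`m_LI = 0`)
  to urban doubling (`m_LI = 2`) per lake, against the pressure index
  (LI/LA)·catchment area (LA floored at 1% to keep the index finite;
  any display log-scaling is presentation only).
* `find_recovery_threshold()` and `find_compensation()` scan the grid for
  the load reduction that empties (or halves) the eutrophic class and for
  the LI increase that undoes a load reduction.
* `policy_scenario_2030()` evaluates the combined policy expectation for
  2030 — nutrient loads −30% (`m_S = 0.70`) and impervious cover +20%
  (`m_LI = 1.20`) — and reports observed state, model baseline at (1, 1),
  scenario prediction, and percent changes **against the model baseline**:
  comparing a model projection to observed means would mix model bias into
  the policy effect, so the observed and baseline rows are kept distinct.

## The synthetic lake generator

The original 48-lake survey table is not redistributable, so
`generate_lakes()` creates datasets with the same statistical skeleton,
calibrated to the published per-class summaries, plus a known ground
truth, so that every downstream stage is testable end to end.

Structure per lake: connectivity is Bernoulli(25/48 drainage); lake area
and the S ratio are lognormal with class-specific median/mean pairs
moment-matched via `sdlog = sqrt(2 log(mean/median))` (drainage S: median
33.8, mean 1341.8; seepage S: median 1.2, mean 5.6; drainage lake area
8.8/18.2 ha; seepage 12.3/26.5 ha); depth is truncated normal (2.0 ± 0.9 m
drainage, 3.3 ± 1.4 m seepage, floor 0.5 m); impervious cover is
zero-inflated (point mass 0.15 at zero, Beta otherwise, class means
19.5% / 11.8%); the non-urban remainder splits LA:LF by a Beta(1.8, 1.2)
draw; drainage density is lognormal with median 1 km/km²; altitude is
uniform on 30–180 m (a sedimentary-plateau region).

**Why catchment area is derived.** The published per-class summaries are
mutually inconsistent under independent lognormal marginals: the median of
a ratio of independent lognormals is the ratio of medians, and
catchment-median/lake-median × 100 is an order of magnitude larger than
the published S medians (real catchment and lake areas are strongly
correlated). Since S is the causal load proxy that drives both the
response and the scenario machinery, the generator draws lake area and S
from their published marginals and derives catchment area = S × lake
area / 100. The stored ratio is then exactly consistent with the areas;
the price is a catchment-area marginal whose median sits below the
published one while keeping its order of magnitude and heavy tail.

**The ground-truth response.** Observed Chla is generated as

  Chla = [ baseline + A · S′/(S′ + K) · s_T · exp(η_lake) ] · ε,

with effective load S′ = S · (1 + γ_LI·(LI/100)·log10(1 + catchment) +
γ_LA·LA/100). Defaults: A = 95 µg/L, K = 60, baseline = 1 µg/L,
γ_LI = 0.8, γ_LA = 0.6; season multipliers 0.5 / 1.0 / 1.7 / 1.2 for
winter/spring/summer/autumn; η_lake and ε are mean-one lognormals with
log-scale sd 0.3 and 0.4. The single half-saturation constant K places
drainage-typical loads in the saturating regime and seepage-typical loads
near the linear one; the catchment-size weighting of the urban term makes
converting impervious to agricultural cover *raise* the expected response
in small agricultural catchments (diffuse pollution dominates) and *lower*
it in large urbanised ones (point sources dominate) — the mechanism behind
the v-shaped LI response of seepage lakes. A and K were calibrated once,
by a Monte Carlo moment calculation over the generator's marginals,
against the published class means (51.5 and 9.6 µg/L) and then frozen; the
remaining response parameters are plausibility choices, not fits.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: the within-class correlation structure between
areas, land cover and loads (only S × lake-area consistency is built in);
spatial or inter-lake correlation; and measurement error of the
fluorometric Chla profiles. One documented consequence: because the
published seepage S dispersion is itself heavy-tailed, a small fraction of
synthetic seepage lakes sits deep in the saturating regime and dominates
the stratum mean, so the seepage load–response curve of the synthetic
population is mildly concave rather than linear — the qualitative
drainage/seepage shape contrast of the original study is not reproduced by
marginal moment matching. Likewise the generator draws LI independently of
S, while the fitted forest pools both classes; the learned (positive,
drainage-dominated) LI effect therefore transfers to seepage lakes in
scenarios, which can mute or reverse the small seepage improvements the
ground truth implies.

## Numerical conventions and degenerate inputs

* Eutrophic means strictly greater than the threshold; exactly 25 µg/L is
  not eutrophic. OECD annual-mean classes default to <2.5 / 2.5–8 / 8–25 /
  >25 µg/L (oligo/meso/eu/hypertrophic; the boundaries are configurable
  because fixed-boundary tables vary between sources), with boundary
  values assigned upward except at 25, keeping "hypertrophic" consistent
  with the strict rule.
* `rebalance_landcover()` returns its inputs untouched for `m_LI = 1` so
  that the identity scenario is exact to the bit, not merely to rounding;
  grid cell (1, 1) therefore reproduces baseline predictions exactly.
* Normalisation rejects constant predictors by name; encoding rejects
  unknown seasons; prediction rejects feature matrices whose column order
  differs from training.
* All randomness flows from explicit integer seeds: the generator consumes
  its `rng_seed` in a fixed draw order, holdout splits are pre-drawn so
  fit-time seeding cannot disturb them, and the classification fit uses
  `rng_seed + 1` so the paired models are decoupled.
* Lognormal targets with mean < median are rejected as infeasible at
  configuration time.

## Problem sizes

The test suite and the acceptance script run the study-sized
configuration (48 lakes, 192 observations, 30 holdout repeats, 500
trees), a 2000-lake draw for population-level calibration checks, and
200-lake draws for signal-recovery and curve-shape properties; the full
101 × 101 grid sweep is exercised in the stage-3 analysis driver and
coarser axes are used inside unit tests, which changes nothing about the
code path being tested.

## Known limitations

Scenario predictions inherit the bounded range of leaf averaging: a forest
cannot predict outside the span of its training responses, so extreme
cells of the grid (both axes near 0 or 2) are compressed toward the
training range and recovery/compensation scans are conservative there.
The pressure multipliers act regionally and uniformly; catchment-specific
demographic projections, internal nutrient loading ("memory" of shallow
lakes), climate forcing and economic costs are out of scope.
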