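# lakescen

Scenario projection of lake and reservoir eutrophication from
catchment-scale descriptors.

## What it is for

Water managers need to know whether planned nutrient-reduction policies
will actually improve the trophic state of the lakes in a region, and how
ongoing urbanisation will push in the other direction. Mechanistic
load–response models need per-catchment data that rarely exist at regional
scale. `lakescen` implements the minimal-parameterisation alternative for
a regional population of small shallow lakes: predict chlorophyll *a*
(Chla, µg L⁻¹, the standard phytoplankton-biomass proxy) from descriptors
available in any GIS —

* the catchment:lake area ratio **S** (a nutrient-load proxy),
* land-cover fractions of the catchment (**LF** forest, **LA**
  agricultural, **LI** impervious/urban),
* drainage-network density **Id**, lake mean depth **D**, altitude, and
  season **T** —

with a pair of random-forest models: a regression forest for Chla and a
classification forest for the binomial state Chla > 25 µg L⁻¹ (the OECD
"significant eutrophication" boundary). Management scenarios are then
expressed as multipliers on the two actionable pressures, m_S ∈ [0, 2] on
the load proxy and m_LI ∈ [0, 2] on urban cover (with the LA:LF ratio held
constant as cover rebalances), and swept over a 101 × 101 grid. Per grid
cell the package reports mean predicted Chla and the eutrophic frequency,
for all lakes and separately for **drainage** lakes (connected to the
stream network, large effective catchments) and **seepage** lakes (no
surface connection, small catchments) — the two classes respond very
differently.

On top of the grid sit the derived analyses: saturating-vs-linear
classification of load–response curves (AICc contest between `y = a + bm`
and `y = y0 + cm/(k+m)`), per-lake contrasts between urban-removal and
urban-doubling scenarios, recovery thresholds (the load reduction that
empties or halves the eutrophic class), compensation thresholds (the LI
increase that undoes a load reduction), and a combined **2030 policy
scenario** (loads −30%, impervious cover +20%).

Validation follows a repeated-holdout protocol: 30 random 80/20 splits by
lake, averaged squared Pearson correlation (R²) for the continuous model
and averaged Cohen's kappa, κ = (p_o − p_e)/(1 − p_e), for the binomial
one.

Because the original survey table is not redistributable, the package
includes a calibrated synthetic generator (`generate_lakes()`) that
reproduces the published per-class structure (lognormal areas and load
ratios, zero-inflated urban cover, truncated-normal depths) together with
a known saturating ground-truth response, so the whole pipeline is
testable end to end. See the methods vignette
(`vignettes/lake-scenarios.Rmd`) for the model, the generator's design and
its documented limitations.

## Worked example

The analysis is organised as three numbered drivers over the package
functions; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # generate + calibrate the 48-lake dataset
Rscript analysis/02_validate.R   # repeated-holdout validation
Rscript analysis/03_project.R    # grid sweep, thresholds, 2030 scenario
```

Stage 1 generates the synthetic study population and compares it with the
published per-class anchors (drainage mean 51.5 µg L⁻¹ with 74% of
observations above 25; seepage 9.6 µg L⁻¹ with 3.3%):

```
generating 48 lakes (seed 1)
  48 records, 192 observations -> results/lakes_synthetic.csv
  n=  48 drainage: 23 lakes, mean Chla 56.5 ug/L, 64.1% of obs > 25
  n=  48 seepage : 25 lakes, mean Chla 12.5 ug/L,   15% of obs > 25
  n=2000 drainage: 1082 lakes, mean Chla 51.2 ug/L, 58.1% of obs > 25
  n=2000 seepage : 918 lakes, mean Chla 8.13 ug/L, 7.57% of obs > 25
```

The class means sit on the anchors at population size; the 48-lake draw
shows the sampling noise any one survey carries. Stage 2 validates the
models on that draw:

```
Repeated holdout validation (30 repeats, 80%/20% by lake)
  mean R-squared (correlation): 0.688
  mean Cohen's kappa:  0.756
```

(The published protocol reported R² = 0.715 and κ = 0.764 on the real
data.) Stage 3 sweeps the grid and projects the 2030 policy scenario —
baseline (model at multipliers (1, 1)) versus scenario, with percent
changes taken against the model baseline:

```
  load-response curve shapes: all=saturating, drainage=saturating, seepage=saturating
  delta-Chla contrast: 17 of 48 lakes greener without urban cover
  seepage full recovery at 90% load reduction (reached: TRUE)
  overall frequency halved at 82% load reduction (reached: TRUE)
Policy scenario at multipliers (m_S = 0.70, m_LI = 1.20)
stratum      mean Chla     (change)   % >25 ug/L     (change)
all          33.6->31.2     (-7.1%)    40.6->39.6     (-2.6%)
drainage     55.9->51.6     (-7.6%)    68.5->67.4     (-1.6%)
seepage      13.1->12.5     (-5.0%)    15.0->14.0     (-6.7%)
```

Read: the planned 30% load reduction buys only a ~7% drop in mean Chla and
barely moves the eutrophic frequency — heavily loaded drainage lakes sit
on the flat part of a saturating load–response curve, so improvement
requires reductions far beyond the policy target (the recovery scans put
the halving point at an ~82% reduction here).

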