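---
title: "Catchment-scale ensemble risk mapping for aquatic invasive species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catchment-scale ensemble risk mapping for aquatic invasive species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aqrisk)
```

## The problem

Managers of aquatic invasive species need spatial risk assessments faster
than conventional species distribution modelling can deliver them. The
motivating use case is an introduced salmonid (rainbow trout) invading and
hybridizing with a native trout in a mountain river network: genetic
monitoring yields point records of population-level admixture (the
proportion of invasive alleles), occurrence databases yield additional
presence points, and satellite products supply temporally explicit
environmental covariates. `aqrisk` implements the full chain from those
raw inputs to per-catchment suitability maps, change maps, uncertainty
maps, extrapolation (MESS) surfaces, and a ranked list of environmental
drivers — with a synthetic study system so every stage is testable with a
known ground truth.

The modelling unit is the catchment-year: records and covariates are
aggregated to hydrologic-unit polygons (HUC-12-like sub-watersheds), and
each catchment-year pair is treated as an independent observation. This
mitigates the footprint mismatch between satellite pixels and the stream
network, and accommodates the mobility of fish within a drainage.

## From points to a design table

**Presence classification.** A record with admixture strictly below 10%
is classified absent: such populations carry some invasive alleles, but
conditions there are evidently unfavourable for establishment. The
threshold is exposed (`prep_config()`), the rule is strict (`0.10` is
present), and when a record carries both an admixture value and a
presence flag, admixture wins — one rule source.

**Spatial thinning.** To blunt spatial autocorrelation from clustered
sampling, records are subsampled so that no two retained points of the
same year lie within 500 m of each other (great-circle distance, mean
Earth radius 6371.0088 km; at 48 N naive degree arithmetic would err by a
non-negligible amount at a 500 m scale). The retained set is built
greedily in a seed-shuffled order and is therefore maximal — no dropped
point could be reinserted — and reproducible. Thinning is idempotent.

**Aggregation.** In occurrence mode a catchment-year is suitable iff it
contains at least one presence record. In admixture mode the response is
the mean admixture weighted by the number of genotyped individuals
(missing sample sizes count as one, with a report). Points on a shared
catchment edge go to the lexicographically smallest `huc_id` — an
arbitrary but deterministic convention.

**Compositing.** Covariate raster time series are reduced per pixel and
year with product-specific reducers: maximum (land-surface temperature —
trout are limited by high temperature), seasonal sums (precipitation:
MAM/JJA/SON/DJF, with December assigned to the following year's winter),
annual sums (gross primary productivity), annual means (vegetation
indices), and the annual *sample* standard deviation of weekly
surface-water extent ("flashiness"). A pixel-year with a single unmasked
observation gets a masked standard deviation rather than 0: one
observation carries no information about variability. Static layers
(topographic diversity, heat-insolation load, long-term surface-water
occurrence) pass through. Composites are averaged over each catchment by
pixel-centre membership (no area weighting — exactly testable and the
common zonal-statistics default), and the per-variable tables are
inner-joined on catchment-year into the design table, dropping and
counting rows with missing covariates.

## Covariate screening

Correlated covariates corrupt the importance methods, so the design table
is screened in two stages.

*Stage 1 (linear):* among each pair with |Pearson r| > 0.7 (absolute
value: a negative duplicate is equally collinear), the member with the
larger mean absolute correlation against the other covariates is dropped;
pairs are visited in descending |r|, ties break alphabetically. Constant
columns are removed first.

*Stage 2 (nonlinear feature dependence):* each covariate is predicted
from the others by a 200-tree random-forest regression, with all
predictors available at every split (the regression-forest formulation
the score follows); the covariate's dependence score is the out-of-bag
R². While the maximum score exceeds 0.6 the single worst offender is
dropped and all scores recomputed — dropping one covariate per iteration
avoids over-pruning mutually dependent groups. The loop's stopping
threshold is 0.6, the stricter terminal condition; a looser 0.7 initial
rule can be set via `screening_config()`. The drop log records variable,
stage, score and partner.

## The weighted ensemble

Six component families, all at library defaults with fixed seeds and no
tuning: logistic/linear regression (GLM), a classification and regression
tree (CTA, rpart), gradient boosted trees (GBM: a slow-learning boosting
profile — learning rate 0.1, depth 3, 100 rounds), a random forest (RF,
ranger, 500 trees), XGBoost at its defaults (XGB), and a single-hidden-
layer neural network (ANN, nnet, 5 units, weight decay 0.01, standardized
inputs). Members are trained on a stratified 80% split and scored on the
withheld 20%: AUC for occurrence, mean absolute error for admixture.

Weights are skill-proportional: `AUC_i / sum(AUC)` for classification and
`(1/MAE_i) / sum(1/MAE)` for regression — "weighting by the error" is
implemented as inverse error, since a lower error must mean a higher
weight for the weighting to be sensible; a zero-MAE member (degenerate
perfect fit) absorbs all weight and is reported. Raw AUC (not AUC − 0.5)
is used, matching the plain weighted-average reading; this compresses the
weights towards uniformity, which is visible in the member tables.

**Degenerate culling.** Rather than excluding the historically
problematic members (GLM, ANN) by fiat, every member is screened against
the prediction windows: a classifier whose predicted class is identical
across every unit of every window, or a regressor that is constant or
predicts outside [0, 1] for a proportion response, is culled with its
reason recorded and the weights renormalized over survivors. This
operationalizes the behaviour that motivated removing those members in
the first place.

**Validation.** `cv_accuracy()` partitions the table into 30 stratified
segments (stratified because ~16-row segments of a ~490-row table can
otherwise lose a class), fits all members on the other 29 — an internal
80/20 split of those segments supplies the training-side AUC for the
weights, after which members are refit on all 29 segments — and scores
the held segment at threshold 0.5. The threshold and fold count are
arguments.

**Maps.** `predict_window()` takes per-catchment mean covariates over a
window of years (e.g. an early and a late half of the record) and emits
the weighted ensemble value, each member's prediction, and the sample
standard deviation across members (0 for a single member) as the
per-catchment uncertainty. `change_map()` reports late-minus-early deltas
and a normalized change obtained by dividing by the maximum absolute
delta — the rescaling convention is ours, chosen for interpretability on
[-1, 1], and both raw and normalized columns are emitted.

## Driver diagnostics

`importance_ensemble()` ranks covariates per retained member by three
techniques and tallies appearances in the top three; each
(member, method) cell contributes exactly three tally increments, so the
total mass is 3 x members x methods:

* *Permutation*: 10 seeded shuffles of each covariate on the holdout,
  mean drop in holdout accuracy (or MAE rise).
* *Recursive feature elimination*: repeatedly refit, removing the
  covariate with the weakest per-step importance (model-native
  importances for trees, boosters and the GLM; a permutation pass for the
  ANN, which has no native ranking); elimination order is the ranking.
* *Backwards elimination*: refit without each covariate in turn and
  measure the skill drop on the same holdout as the member's original
  skill — one consistent currency.

Ties break alphabetically and the full audit matrix is returned.
`pdp()` computes partial dependence on a quantile-based grid (robust to
the right-skewed admixture covariates; 20 points by default): the mean
prediction over all rows with the covariate pinned to each grid value,
ensemble curves being weight-averaged member curves.

`mess()` implements the multivariate environmental similarity surface:
for covariate v with reference minimum m, maximum M and f the fraction of
reference values strictly below the query value p (strict inequality
fixes the tie behaviour testably),

* f = 0: S = 100 (p − m) / (M − m)
* 0 < f ≤ 0.5: S = 200 f
* 0.5 < f < 1: S = 200 (1 − f)
* f = 1: S = 100 (M − p) / (M − m)

and the MESS value is the minimum S over covariates; negative values flag
extrapolation beyond the training range. A constant reference covariate
scores 0 on an exact match and a −Inf sentinel otherwise; the sentinel is
reported but excluded from the minimum unless it is the only covariate.

## The synthetic study system

`synth_config()` fixes the conditions every recovery test runs under; its
defaults are the study conditions, not tuning knobs.

* **Geometry.** An 80 x 80-pixel grid spanning ~1° x 0.6° near 48 N
  (pixels ~1.2 km), tiled into 20 x 20 = 400 rectangular catchments of
  ~6 km² so that the 500 m haversine thinning maths is exercised at a
  realistic latitude and catchments rarely repeat among sampled
  catchment-years.
* **Covariates.** Twelve base covariates mirror the real library (maximum
  LST, seasonal precipitation sums, flashiness, GPP, EVI, tree cover,
  surface-water occurrence, heat load, topographic diversity), generated
  as standardized moving-average-smoothed Gaussian fields (kernel length
  = the covariate's autocorrelation length; length 1 degenerates to white
  noise). Dynamic covariates carry year- and slice-level noise with sd
  0.8 relative to the unit-variance persistent field, and the four
  precipitation seasons use independent per-season fields. Both choices
  keep independent covariates from becoming mutually predictable through
  shared spatial structure — with many fewer catchments, stronger
  persistence, or shared seasonal bases, a random forest can identify a
  catchment from the other covariates ("location fingerprinting") and the
  dependence-screening stage would wrongly prune independent variables.
* **Planted collinearity.** Two extra covariates exercise the screening
  stages: `ndvi` = 0.95 EVI + noise (caught by the Pearson stage) and
  `radiation_index` = (standardized heat load)² + 0.05 noise — nearly
  uncorrelated linearly but almost perfectly dependent (caught by the
  dependence stage; the small noise keeps the catchment-level dependence
  score above the 0.6 threshold after zonal averaging attenuates it).
* **Truth.** Suitability is logistic on standardized *catchment-year*
  values of the composited causal covariates — the scale at which the
  workflow models: logit μ = 2.2 + 4 z(LST) + 2 z(surface water). The
  slopes make the landscape strongly separable; the intercept was
  calibrated once, numerically, so the expected presence fraction among
  sampled sites is ~323/490, the scale of the motivating data set.
  Presence is Bernoulli(μ). Admixture is drawn from a Beta centred on μ
  with concentration 8 (right-skewed at high suitability, as observed in
  heavily invaded populations) and then mapped into the side of the 10%
  threshold that matches the presence draw, so the classification rule
  and the ground truth agree by construction.
* **Sampling.** 490 distinct catchment-year cells get one point each,
  placed with >500 m same-year spacing (so with no clusters, thinning is
  a no-op); a further 25% near-duplicate cluster points (50–450 m from a
  source point, same year) exercise thinning.

What the generator does *not* emulate: real sensor radiometry and QA-bit
semantics, non-random survey effort, dispersal and propagule pressure,
spatially structured residuals beyond the smoothed fields, and
observation error in admixture estimates. Passing the recovery tests
therefore demonstrates that the machinery is correct and that the
pipeline can recover a strong catchment-scale signal — not that any real
invasion is this predictable.

## Numerical choices and degenerate inputs

* Sample (n − 1) standard deviations everywhere a spread is reported
  (flashiness composites, member-prediction uncertainty); a single
  member's map gets sd 0 by convention.
* Composite reducers are accumulation-based and match a naive loop
  exactly for integer inputs (max and sum bitwise; mean and std to
  ~1e-12).
* Classification threshold 0.5; AUC via trapezoidal ROC (pROC) with
  explicit direction so a perfect member scores exactly 1.
* Empty thinning input returns empty; k > n folds, single-class tables,
  non-finite covariates, missing window columns and mismatched unit sets
  are errors naming the offending element.
* Problem sizes in the test suite: oracle checks run on stacks up to
  10 x 10 x 12 and tables up to 300 rows; recovery checks run the full
  default landscape (490 rows, 30-fold CV); the null-calibration check
  uses 20 independent 400-row tables.

## Known limitations

* Partial-dependence curves of a *single* tree-ensemble member are
  step-functions with local non-monotonicities of up to a few hundredths
  even on cleanly monotone truth; the ensemble-averaged PDP is smooth.
  Interpret single-member curves qualitatively.
* Raw-AUC weighting barely separates members of similar skill; the
  ensemble therefore behaves close to an unweighted average unless a
  member is culled.
* The admixture regression inherits whatever spatial incoherence the
  response has; with the Beta observation noise used here its MAE is
  dominated by that noise, mirroring the weaker performance of
  hybridization models on real data.
* GeoJSON support covers single-ring polygons with a `huc_id` property;
  raster file exchange uses the plain-text ESRI ASCII grid format, one
  slice per file.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates the synthetic
study system from the seed, runs preparation, screening, 30-fold CV,
ensemble fitting, culling over two decade-like windows, MESS, change and
importance analyses, and writes the resulting quantities as JSON. The
test suite's `test-acceptance.R` runs the same stages at fixed seeds plus
the brute-force oracle comparisons.
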