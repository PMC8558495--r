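# aqrisk

Rapid, catchment-scale habitat-suitability risk mapping for aquatic
invasive species.

`aqrisk` is for invasion ecologists and managers who have point records of
an invader — occurrence points, or genetic-admixture estimates from
monitored populations — plus environmental raster time series, and who
need per-catchment risk maps fast enough to steer early-detection
surveillance. The motivating system is an introduced trout hybridizing
with a native trout across a mountain river network, with populations
scored by the proportion of invasive alleles (admixture) and the
landscape described by satellite covariates (land-surface temperature,
precipitation, surface-water dynamics, vegetation and topographic
indices).

The workflow:

1. **Prepare** — classify records with < 10% admixture as absences, thin
   points so no two same-year records lie within 500 m (haversine), and
   aggregate to hydrologic-unit catchments: occurrence (any presence) or
   sample-size-weighted mean admixture per catchment-year.
2. **Composite** — reduce covariate rasters per pixel and year (maximum
   LST, seasonal precipitation sums, annual standard deviation of
   surface-water extent, ...), then average over catchments into a tidy
   design table, one row per catchment-year.
3. **Screen** — drop one member of every covariate pair with
   |Pearson r| > 0.7, then iteratively drop covariates whose
   random-forest feature-dependence score (out-of-bag R² of predicting
   them from the rest) exceeds 0.6.
4. **Model** — train six component models (GLM, classification tree,
   gradient boosting, random forest, XGBoost, neural network) on an 80/20
   split and combine them with skill-proportional weights: AUC for
   occurrence classification, inverse mean-absolute-error for admixture
   regression; members with degenerate predictions (no variation across
   catchments, or out of [0, 1] for a proportion) are culled with
   recorded reasons. Accuracy is validated by 30-fold stratified
   cross-validation of the weighted ensemble:

   `accuracy = mean over folds of the fraction of held-out
   catchment-years classified correctly at threshold 0.5`

5. **Map and diagnose** — per-catchment ensemble suitability with
   member-spread uncertainty for any window of years, normalized change
   between windows, multivariate environmental similarity (MESS, negative
   = extrapolation), partial-dependence curves, and a tri-method
   importance tally (permutation, recursive feature elimination,
   backwards elimination; top-3 appearances per member and method).

A synthetic study system (`synth_config()`, `make_landscape()`,
`make_occurrences()`) generates autocorrelated covariate rasters, tiled
catchments, a known logistic suitability truth and clustered, admixture-
linked point records at the scale of the motivating study (~490
catchment-year rows, ~323 presences, 12 covariates plus two planted
collinear ones), so the whole pipeline is testable without any downloads.

## Worked example

```r
library(aqrisk)

cfg  <- synth_config(seed = 42)          # the synthetic study system
pipe <- synth_pipeline(cfg)              # prepare + composite + design table

scr <- screen_covariates(pipe$design_occurrence)
glance(scr)
#>   n_retained n_dropped n_dropped_pearson n_dropped_dependence
#> 1         12         2                 1                    1
tidy(scr)
#>   variable        stage      score partner
#> 1 evi             pearson    0.994 ndvi
#> 2 radiation_index dependence 0.877 <NA>
```

Both planted collinear covariates are caught — the linear EVI/NDVI pair
by the Pearson stage, the squared heat-load index by the nonlinear
dependence stage — leaving the twelve base covariates.

```r
ens <- fit_members(scr$table, "classification", seed = 1)
tidy(ens)
#>   name  skill weight status
#> 1 GLM   0.950  0.170 retained
#> 2 CTA   0.890  0.160 retained
#> 3 GBM   0.942  0.169 retained
#> 4 RF    0.954  0.171 retained
#> 5 XGB   0.940  0.168 retained
#> 6 ANN   0.903  0.162 retained

cv_accuracy(scr$table, k = 30, seed = 1)
#> <aqrisk_cv> 30-fold accuracy 0.853 (fold range 0.688..1.000, n = 490)
```

Skill is the holdout AUC; weights are AUC-proportional. The 30-fold
cross-validated ensemble accuracy of 0.853 sits close to the data ceiling
of this landscape (presence is a Bernoulli draw from the true logistic
suitability, so even the true model cannot reach 1).

```r
w_late <- window_covariates(pipe$zonal, 2009:2015, "2009-2015")
map    <- predict_window(ens, w_late, "2009-2015")
head(map[, 1:4], 4)
#>   huc_id   prob      sd n_members
#> 1 H170101 0.990 0.0161          6
#> 2 H170102 0.995 0.00764         6
#> 3 H170103 0.991 0.0135          6

imp <- importance_ensemble(ens, seed = 1)
head(tidy(imp), 3)
#>   covariate     count
#> 1 lst              18
#> 2 surface_water    18
#> 3 precip_fall       7

mean(mess(scr$table, w_late)$mess < 0)
#> [1] 0.01
```

`prob` is the weighted ensemble suitability for each catchment and `sd`
the spread across members (the uncertainty map). The two covariates that
actually drive the synthetic truth (`lst`, `surface_water`) take every
available top-3 slot — 18 of 18 each across 6 members x 3 methods — and
only 1% of catchments fall outside the training environmental range
(negative MESS). `autoplot()` methods draw the choropleth, importance and
partial-dependence figures; `change_map()` contrasts two windows.

A thin command-line wrapper ships in `inst/exec/aqrisk`
(`prepare`, `screen`, `train`, `predict`, `change`, `synth` subcommands)
for shell pipelines; the R functions above are the primary interface.

## Package layout

| Area | Functions |
| --- | --- |
| Occurrence prep | `prep_config()`, `classify_presence()`, `thin_points()`, `aggregate_to_catchments()` |
| Composites | `raster_stack()`, `temporal_composite()`, `zonal_mean()`, `build_design_table()` |
| Screening | `screening_config()`, `pearson_prune()`, `dependence_prune()`, `screen_covariates()` |
| Ensemble | `model_specs()`, `fit_members()`, `compute_weights()`, `cull_degenerate()`, `cv_accuracy()`, `predict_window()`, `change_map()` |
| Diagnostics | `importance_ensemble()`, `pdp()`, `mess()` |
| Synthetic data | `synth_config()`, `make_landscape()`, `make_occurrences()`, `synth_pipeline()` |
| I/O | `read_occurrences()`, `read_catchments()`, `write_catchments()`, `read_ascii_grid()`, `write_ascii_grid()` |

See the vignette (`vignettes/risk-mapping-workflow.Rmd`) for the model,
its assumptions, the synthetic-data design and known limitations.
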