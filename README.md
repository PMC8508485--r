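# hotspotcv

Predicting which small geographic areas will be *persistent hotspots* of
potentially preventable hospitalisations (PPHs) several years into the
future.

Place-based health interventions are expensive, slow to implement, and slow
to take effect, while areas with currently elevated admission rates tend to
regress to the mean. Planners therefore need predictions of which areas will
*still* be hotspots once an intervention could plausibly bite — typically
three years out — not maps of where rates are high today. `hotspotcv`
implements a full pipeline for this problem on spatially aggregated,
longitudinal administrative data (area × year × age-sex stratum counts):

1. **Hotspot classification.** For each area *j* and year *l*, a directly
   age-sex standardised rate

   ASSR\_jl = (Σ\_i w\_i O\_ijl / n\_ijl) / Σ\_i w\_i,  
   Var(ASSR\_jl) = (Σ\_i w\_i² O\_ijl / n\_ijl²) / (Σ\_i w\_i)²,

   with confidence limits carried over from Byar's approximation to the
   Poisson limits of the all-area count O\_l via
   ASSR\_jl,lower = ASSR\_jl + √(Var(ASSR\_jl)/Var(O\_l)) · (O\_l,lower − O\_l).
   An area is a hotspot when ASSR\_jl,lower exceeds the all-area rate ASSR\_l.
   Age-sex cells with populations under 30 are substituted by their all-area
   stratum totals rather than collapsed across age groups.
2. **Outcome and features.** The prediction target at covariate year *l* and
   horizon *m* is "hotspot in **all** of years *l*+1, …, *l*+*m*". Area-level
   predictors are defined in year *l*: socio-economic index percentiles,
   signed-log-transformed distances to emergency and general-practice care,
   demographic percentages, rurality, and the number of past consecutive
   hotspot years.
3. **All-subset model space.** Every subset of at most five terms that
   respects marginality (quadratics and interactions require their parents)
   and exclusivity (at most one socio-economic index; at most one
   GP-accessibility measure): 1,146 candidate logistic models for the
   state-wide catalogue, 726 for the metropolitan one.
4. **Firth-penalised logistic regression**, so coefficients stay finite when
   rare outcomes separate.
5. **Area-partitioned, time-shifted repeated K-fold CV.** Folds are groups
   of areas; the held-out fold is evaluated on the same layout shifted *m*
   years forward, so the training window keeps its full width (8 years for a
   13-year series at *m* = 3, versus 4 for a rolling forecast window at
   *T* = 10, *m* = 1, *C* = 5). Confusion counts are pooled across folds and
   repeats before metrics are computed, avoiding undefined per-fold ratios.
6. **Calibration–implementation selection.** A short calibration run maps
   the attainable positive predictive value (PPV) across a grid of minimum
   sensitivity thresholds; at the chosen threshold *t\**, a long
   implementation run selects the model maximising pooled PPV subject to
   pooled sensitivity ≥ *t\**, reports 95% quantile intervals across
   repeats, and refits the chosen structure on the latest data to forecast
   future hotspot areas.
7. **Baselines.** The "current hotspots" and "past persistent hotspots"
   prediction rules, for comparison.

A seeded synthetic-data generator (`synthetic_config()`, `generate_panel()`)
produces panels with the assumed structure — Poisson counts, AR(1) area
effects with regression to the mean, covariate-driven rate signal — so every
stage is testable without restricted health data.

## Worked example

```r
library(hotspotcv)

cfg <- synthetic_config(n_areas = 150, n_years = 13, seed = 3,
                        gamma = c(seifa_irsd = -0.7, pct_75plus = 0.7),
                        sigma = 0.15, rho = 0.9)
sim <- generate_panel(cfg)
hs  <- classify_hotspots(sim$panel, sim$standard_population,
                         small_stratum_threshold = 30)
mean(hs$hotspot)
#> [1] 0.2123077

catal  <- dplyr::bind_rows(
  catalogue_term("seifa_irsd_pct", source = "seifa_irsd",
                 transform = "percentile_rank"),
  catalogue_term("pct_75plus"),
  catalogue_term("noise1"),
  catalogue_term("pct_male", transform = "center_within_year"))
models <- enumerate_candidate_models(catal)
train  <- assemble_model_frame(hs, sim$covariates, catal, l = 7,  m = 3)
test   <- assemble_model_frame(hs, sim$covariates, catal, l = 10, m = 3)

sel <- implementation_step(models, train, test,
                           K = 5, Q_impl = 10, t_star = 0.5, seed = 77)
sel
#> Model selection at minimum sensitivity t* = 0.5 (K = 5, Q = 10)
#> Optimal model 13: seifa_irsd_pct + pct_75plus + noise1
#> # A tibble: 4 × 6
#>   metric      pooled    lo    hi median_repeat n_undefined
#>   <chr>        <dbl> <dbl> <dbl>         <dbl>       <int>
#> 1 sensitivity  0.774 0.741 0.815         0.778           0
#> 2 specificity  0.999 0.994 1             1               0
#> 3 ppv          0.995 0.966 1             1               0
#> 4 npv          0.953 0.946 0.961         0.953           0
```

The pooled sensitivity (0.77) is the share of truly persistent future
hotspots the selected model finds; the pooled PPV (0.995) is the share of
its flagged areas that really stay hot — both computed by summing TP/FP/FN/TN
over all folds of all repeats, with 2.5%/97.5% quantiles across the repeats.
Both planted signal covariates are recovered; the stray `noise1` term rides
along because ten repeats still leave ties among near-equivalent models.
`refit_and_forecast(sel$optimal$terms[[1]], test, min_constraint = 0.5)`
then turns the chosen structure into a concrete list of predicted future
hotspot areas.

Baseline comparison on the same panel:

```r
evaluate_baselines(hs, l = 10, m = 3, run_length = 6)
#> # A tibble: 2 × 8
#>   rule                     n_predicted    TP    FP    FN    TN sensitivity   ppv
#>   <chr>                          <int> <int> <int> <int> <int>       <dbl> <dbl>
#> 1 current_hotspots                  35    26     9     1   114       0.963 0.743
#> 2 past_persistent_hotspots          21    20     1     7   122       0.741 0.952
```

The current-hotspots rule finds more of the future hotspots (higher
sensitivity) but wastes more predictions (lower PPV); the persistent rule is
the reverse — the trade-off the model-based method lets you tune instead of
inherit.

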