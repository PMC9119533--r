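# holctools

Linking historical HOLC redlining grades to present-day census tracts.

## The problem

In the 1930s the Home Owners' Loan Corporation (HOLC) graded US city
neighborhoods from A ("best") to D ("hazardous", drawn in red), encoding
racial discrimination into federal mortgage-risk maps. Research on the
long-run health and socioeconomic effects of redlining must attach those
historical grades to present-day census tracts — but tract boundaries do
not nest within the graded areas: most tracts intersect several areas
with different grades, and part of each tract is unrated. Studies have
classified tracts ad hoc (largest-area grade, centroid grade, coverage
proportions, 50%-coverage cutoffs), with no agreed method.

`holctools` implements a systematic, predictive-validity-driven answer
for epidemiologists and social scientists working with tract-level data:

1. **Overlay** — per-tract coverage compositions
   $(p_A, p_B, p_C, p_D, p_U)$, $\sum_g p_g = 100$, from planar polygon
   overlay with same-grade dissolve and optional water masking
   (`compute_coverage()`), plus the centroid-assignment baseline
   (`centroid_grade()`).
2. **Scheme enumeration** — the 54 candidate classifications obtained by
   crossing six binning resolutions (10/20/25/33.3/50-point bins, or
   pure rank order), one to five retained ratings, and inclusion or
   exclusion of unrated area as a pseudo-grade (`enumerate_schemes()`,
   `assign_labels()`).
3. **Cross-validated scoring** — every (scheme, outcome, threshold) cell
   scored by averaged five-fold test MSE of the dummy-coded OLS
   regression of the z-scored outcome on class labels (`run_grid()`;
   54 schemes x 6 outcomes x 7 inclusion thresholds = 2,268 cells).
4. **Meta-analysis and selection** — OLS of cell MSEs on experiment
   features, per-scheme summaries, and selection of the predictively
   optimal and parsimonious schemes (`regress_mse_on_features()`,
   `select_optimal()`, `select_parsimonious()`).
5. **Collapse and description** — the fixed 16-class to 10-class merge
   for applied research, composite standardized outcomes and Cronbach's
   alpha (`collapse_labels()`, `composite_outcome()`,
   `cronbach_alpha()`).
6. **Validation** — R-squared and coefficient comparisons of the novel
   and previously published approaches on held-out outcomes
   (`r2_table()`, `coefficient_table()`, `performance_ratio()`).

A synthetic-data module (`sim_config()`, `simulate_coverages()`,
`simulate_outcomes()`, `polygon_fixture()`) generates compositional
coverages spanning all rank-order grade combinations and correlated
outcomes driven by a monotone A > B > C > D gradient, so the entire
pipeline runs and is tested without any external census, health or map
data. See the vignette (`vignettes/redlining-classification.Rmd`) for
the model, its assumptions and the design decisions.

## Worked example

```r
library(holctools)

cfg <- pipeline_config(
  out_dir = "holc-run",
  simulate = sim_config(n_tracts = 1500, n_outcomes = 9, seed = 1),
  cv_outcomes = paste0("y", 1:6),        # drive the scheme search
  validation_outcomes = paste0("y", 7:9),# held out for comparison
  seed = 1)
res <- run_pipeline(cfg)

res$summary$n_cv_cells      # 2268  (54 schemes x 6 outcomes x 7 thresholds)
res$selection
#> $optimal
#> [1] "set6_r2_noU"
#> $parsimonious
#> [1] "set6_r2_noU"
res$summary$cronbach_alpha  # 0.942
```

The search selects the rank-ordered two-rating classification excluding
unrated area (`set6_r2_noU`): tract labels like `"C-B"` — mainly C, some
B — using 15 regression degrees of freedom, ahead of both coarser
(one-rating) and finer (binned, or unrated-including) schemes:

```r
head(res$scheme_summary[order(res$scheme_summary$mean_mse), ], 3)
#>   scheme_id   mean_mse median_df
#> 1 set6_r2_noU    0.546        15
#> 2 set5_r2_noU    0.552        27
#> 3 set6_r3_noU    0.557        39
```

On the held-out outcomes, the 10-class collapse of that scheme retains
most of the predictive performance of the 40-class optimal candidate at
under a quarter of the degrees of freedom:

```r
res$validation$averages
#>   kind        group      mean_r_squared
#> 1 collapsed10 validation          0.417
#> 2 detailed16  validation          0.458
#> 3 one_rating  validation          0.375
#> 4 optimal40   validation          0.475
#> 5 proportions validation          0.431
res$summary$performance_ratio_pct  # 87.8  (collapsed10 vs optimal40)
```

and the per-class composite outcomes decline from A to D as the planted
gradient dictates (`res$profile`): "Only or mainly A" 0.82, "Only B"
0.44, "Only C" -0.41, "Only D" -1.19.

All artifacts (coverage and CV tables, meta-regression tables, scheme
summaries, class profiles, an MSE-vs-df scatter, `summary.json`, a log
with the seed) are written under `out_dir`; reruns with the same seed
are byte-identical.

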