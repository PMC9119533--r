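---
title: "Classifying census tracts by historical HOLC redlining grades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying census tracts by historical HOLC redlining grades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

In the 1930s the Home Owners' Loan Corporation (HOLC) graded city
neighborhoods from A ("best") to D ("hazardous", outlined in red) on maps
that encoded and institutionalized racial discrimination in mortgage
lending. Present-day health and socioeconomic data are reported for census
tracts, whose boundaries do not nest within the historical graded areas:
a tract typically intersects several areas with different grades, and part
of its area falls outside any graded polygon ("unrated", U). Turning the
polygon overlap into a single categorical exposure — *which class of
historically graded neighborhood is this tract?* — requires a
classification rule, and many defensible rules exist.

`holctools` implements a systematic search over such rules. The atom of
the analysis is the **coverage composition**: for tract $i$, the vector

$$(p_{iA}, p_{iB}, p_{iC}, p_{iD}, p_{iU}), \qquad \sum_g p_{ig} = 100,$$

of percentages of tract (land) area covered by each grade and by unrated
space, computed by planar polygon overlay (`compute_coverage()`; same-grade
polygons are dissolved before intersection, and an optional mask — water,
typically — is subtracted from both layers first).

## The candidate classification space

A **scheme** is a recipe mapping a composition to a class label, indexed by
three design choices (`scheme()`, `enumerate_schemes()`):

* **Set** (1–6): how much of the percentage magnitude is kept. Sets 1–5
  coarsen each grade's percentage into bins of width 10, 20, 25, 33.3 and
  50 points; set 6 keeps only the *rank order* of the grades by covered
  area. Bins are half-open, `[lo, hi)`, with the top bin closed at 100 and
  1-based indices, so 75% in set 1 is bin 8. Set 4 uses the printed
  33.3 / 66.6 boundaries, a boundary value belonging to the upper bin.
* **Number of ratings** (1–5): how many of the largest-coverage grades the
  label retains, e.g. `"C-B"` (set 6, two ratings) or `"A8-B3"` (set 1).
* **Unrated inclusion**: whether U is a pseudo-grade competing for rank
  positions, or is excluded by rebasing the composition to the rated-area
  denominator (`rebase_excluding_unrated()`), i.e. dividing the rated
  percentages by $(100 - p_U)/100$.

Crossing 6 sets with 1–4 ratings excluding U and 1–5 ratings including it
yields the 54 candidate schemes. Exact coverage ties are broken worst
grade first (D, C, B, A, U); the synthetic generator draws continuous
compositions, so results do not depend on this convention. Grades with
exactly zero coverage never enter a label. `enumerate_feasible_labels()`
lists every label a scheme can produce — arrangement counting for set 6
(4, 16, 40, 64 labels for 1–4 ratings excluding U), and an interval
constraint check for binned sets (the listed bins must admit ordered
percentages closing to a 100-point composition, with unlisted-grade mass
allowed only when the label is truncated at the scheme's rating count).

## Scoring schemes by cross-validated prediction

Predictive validity of a scheme for an outcome is the five-fold
cross-validated test mean squared error of a dummy-coded least-squares
regression of the z-scored outcome on the scheme's class labels
(`cv_mse()`). Within each fold the fit equals the per-class training
means — the closed-form least-squares solution for a saturated dummy
design — and classes unseen in training predict the training grand mean,
the least-assumptive fallback. Standardization uses the full
threshold-filtered dataset before fold splitting, reproducing the stated
step order of the procedure (the mild leakage this induces is deliberate
and shared by every scheme equally); a per-training-fold alternative would
change all MSEs by a common factor of order $1/n$ and not the ranking.

`run_grid()` crosses all 54 schemes with the outcomes and with seven
inclusion thresholds (tracts at least 1, 5, 10, 15, 25, 33 and 50 percent
covered by rated area; the comparison is closed, so a tract rated exactly
at the threshold is kept), giving $54 \times 6 \times 7 = 2{,}268$ cells
under the default six-outcome battery. One fold assignment is drawn per
(outcome, threshold) dataset and shared by all schemes, so scheme
comparisons within a dataset are paired. Each cell records the MSE, the
degrees of freedom actually used (distinct observed labels minus one) and
the sample size.

The grid is then analyzed two ways (`meta_features()`,
`regress_mse_on_features()`, `summarize_schemes()`):

* a meta-regression of cell MSEs on the experiment features (ratings
  count, set, unrated inclusion, outcome, threshold), dummy-coded with
  reference levels 2 ratings / set 6 / exclude U / 5% threshold — run one
  feature at a time and all at once; on the (near) balanced factorial the
  two agree;
* per-scheme aggregation over its 42 cells, from which
  `select_optimal()` picks the lowest mean MSE (ties to fewer degrees of
  freedom) and `select_parsimonious()` the fewest-degrees-of-freedom
  scheme within a relative tolerance of the minimum. The tolerance
  default is 0.5% — the source procedure says only "marginally worse",
  so the band is an explicit, configurable constant; both mean and median
  MSE are reported because both appear in descriptions of the procedure,
  and the mean drives selection by default.

The detailed two-rating rank-ordered classification (16 classes) is
collapsed to 10 applied-research classes by a *fixed* map
(`collapse_map()`): the four only-or-mainly-A classes merge, as do the
mainly-C-or-D classes sharing a secondary A (respectively B), and the
mainly-B classes with secondary C or D. The general principle behind the
map — merge classes that are both small and similar in mean outcome — is
frozen into this explicit table rather than re-derived from data, so the
collapsed scheme is identical in every application; `suggest_merges()`
exists only to explore how the principle would generalize.

Validation (`r2_table()`, `coefficient_table()`) compares approaches on
outcomes never used during the scheme search, at the 5% threshold:
continuous rated-area proportions (B, C, D, with A omitted for
identification), the one-rating classification, the collapsed 10-class
and detailed 16-class schemes, the optimal three-rating scheme (39
degrees of freedom) and, when polygon data is available, the historical
centroid-assignment baseline (`centroid_grade()`, implemented as a
guaranteed-interior representative point because true centroids of
concave tracts can fall outside them). `performance_ratio()` expresses
one approach's average explained variance as a percentage of another's.

## What the synthetic generator emulates — and what it does not

All of this is testable without the external census, health and map data
because `sim_config()` / `simulate_coverages()` / `simulate_outcomes()`
generate a study universe with the relevant structure:

* **Compositions.** The set and order of present grades is sampled first
  (about 60% of tracts get two or more grades, mirroring the real overlap
  frequency); their shares are a Dirichlet draw sorted in decreasing
  order, which guarantees strict rank order with no ties. The unrated
  share is drawn independently (mean near a third, a fifth of tracts
  fully rated) and never reaches 100: the universe is tracts with some
  rated coverage. With `ensure_all_combinations = TRUE` every ordered
  rank combination of 1–4 grades is planted, with and without a nonzero
  unrated share (128 planted tracts), so that every feasible rank-order
  class occurs and the optimal scheme's degrees of freedom are exactly
  determined.
* **Outcomes.** Each outcome is `intercept + slope * L + shared + noise`.
  The latent gradient $L$ is a *rank-weighted* mean of the grade weights
  over the rated composition: weights `c(A = 1, B = 0.5, C = 0,
  D = -0.5)` (monotone best-to-worst; magnitudes arbitrary) combined with
  rank weights `c(0.6, 0.3, 0.1, 0)` renormalized over the grades
  present. This is the package's encoding of the regime the search is
  designed to detect: the dominant and secondary grades carry the signal,
  relative rather than absolute coverage matters, and the unrated share
  is missing at random and carries none. A gradient linear in raw area
  shares would instead make the unrated share informative (it behaves as
  a fifth grade of weight zero) and make fine-grained magnitude bins
  genuinely optimal — a different world from the one the method targets.
  The noise splits into a tract-level shared component and an
  idiosyncratic component (`shared_signal_frac = 0.5`,
  `noise_sd = 0.45`), chosen once so that the sign-aligned six-outcome
  battery has Cronbach's alpha in the low 0.9s, the internal-consistency
  regime that justifies averaging outcomes into a composite. Outcomes 2
  and 3 are sign-flipped by default, standing in for ill-health measures
  where higher is worse.
* **Polygons.** `polygon_fixture()` builds rectangular tracts and graded
  areas whose intersection areas are exact rectangle arithmetic,
  including a tract whose interior point falls in a grade that is not its
  largest-area grade — the configuration that separates centroid
  assignment from largest-area assignment.

The generator deliberately does **not** emulate spatial autocorrelation
of tract outcomes, small-area estimation artifacts in surveyed
prevalences, population weighting, or real map geometry (concave
polygons, slivers, topology errors beyond what zero-width repair
handles). Passing tests therefore demonstrate the correctness and
internal logic of the pipeline — enumeration counts, conservation laws,
estimator equivalences, selection behavior under a known gradient — not
that any particular substantive finding transfers to real data.

## Numerical and design details

* Composition closure: generated compositions sum to 100 within 1e-9
  (closure residual assigned to the largest rated share); overlay output
  within 1e-6, with clipper quantization dust clamped at zero.
* Overlay requires planar (projected) coordinates and rejects
  geographic (lon-lat) layers rather than guessing a projection; invalid
  geometries are repaired by even-odd simplification before clipping, and
  failures after repair are errors, not silent drops. A tract fully
  inside the mask is an error naming the tract.
* Bins are computed on the rebased percentage when U is excluded,
  consistent with recomputing percentages on the rated-area denominator.
* The reference class in dummy regressions does not affect predictions
  (class-means equivalence); `coefficient_table()` exposes it only for
  reporting, with conventional (non-robust) standard errors and
  0.05 / 0.01 / 0.001 stars.
* Degenerate inputs error early with the offending rows named: negative
  or >100 percentages, compositions not summing to 100, duplicated tract
  ids, fully unrated tracts reaching rebasing or labeling, constant
  outcomes reaching standardization, thresholds eliminating every tract.
* All randomness flows from explicit integer seeds; fold seeds are
  derived deterministically per (outcome, threshold) dataset, and
  `run_pipeline()` reruns are byte-identical.

The test suite exercises the grid at 1,500 synthetic tracts with six
outcomes and seven thresholds (the full 2,268-cell design), selection
behavior across ten generator seeds, and larger single-purpose draws
(5,000–20,000 rows) for distributional checks; these sizes are the
package's chosen compromise between statistical resolution and quick
iteration.

## Known limitations

* Overlay areas are planar Euclidean; there is no projection handling,
  so inputs must be pre-projected (as the original TIGER-based workflow
  assumes).
* Binned-set feasible-label enumeration treats boundary ties generously
  (a composition tying exactly at a bin edge may be deemed feasible under
  either adjacent label); generated data has no ties, and empirical label
  sets are always a subset of the enumerated ones.
* The collapse map is specific to the two-rating rank-ordered
  classification; other schemes have no canonical collapse.
* Shapefile input is not supported; polygon layers are exchanged as
  GeoJSON (planar coordinates, even-odd ring semantics).

## A minimal run

```{r example}
library(holctools)

cfg <- pipeline_config(
  out_dir = "holc-run",
  simulate = sim_config(n_tracts = 1500, n_outcomes = 9, seed = 1),
  cv_outcomes = paste0("y", 1:6),
  validation_outcomes = paste0("y", 7:9),
  seed = 1)
res <- run_pipeline(cfg)

res$selection
res$summary$n_cv_cells        # 2268
res$summary$n_collapsed_classes  # 10
```
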