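---
title: "Presence-only suitability modelling for plateau pika: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only suitability modelling for plateau pika: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plateau pika (*Ochotona curzoniae*) is a keystone burrowing lagomorph of
the Qinghai–Tibetan Plateau whose distribution both responds to and shapes
rangeland condition. Field surveys record *presences* (plots where active
burrow density indicates an established population) but no reliable
absences: a plot without burrows may be unsuitable, or merely unvisited.
`pikasdm` implements the standard presence-only answer — a maximum-entropy
(Maxent-style) species distribution model on a 1-km raster grid — as a
single, fully scriptable pipeline: covariate derivation, model fitting,
replicate validation, variable importance, threshold optimisation,
suitability mapping, and a paired with/without-anthropogenic-factors
scenario comparison. Field occurrences and basin-scale GIS layers of this
kind are rarely public, so the package ships a synthetic-landscape
generator with a known suitability truth, and every stage can be
exercised end-to-end against ground truth.

## Data model

A `grid_spec` describes a north-up raster of square cells; cell `(r, c)`
covers a half-open square so every point belongs to exactly one cell, and
`y_origin` is the north edge (row 1 is northernmost). Layers
(`px_layer`) are continuous or categorical matrices with `NA` as nodata;
a `layer_stack` is a set of aligned layers, and a cell is *valid* only if
no layer is nodata there — nodata propagates, so the lake is excluded from
modelling, background sampling and area denominators alike. Rasters are
read and written as ESRI ASCII grids (keywords case-insensitive,
`NODATA_value` and `xllcorner`/`xllcenter` honoured). GeoTIFF is not
supported in this build: no GeoTIFF reader is available in the dependency
budget, and the ASCII grid is the format such workflows export
for modelling anyway.

Covariate derivation covers what a practitioner would otherwise do in a
GIS:

* **Terrain** — Horn 3×3 slope and aspect (degrees; aspect clockwise from
  north, flat cells get the sentinel −1; grid edges use replicate
  padding), and a topographic wetness index `TWI = ln(a / tan beta)` with
  `a` from single-direction D8 flow accumulation. Two knobs are ours
  rather than the literature's: D8 ties break toward the first direction
  clockwise from north (deterministic and oracle-checkable), and
  `tan beta` is floored at `eps = 0.001` so flat cells stay finite.
  Because 25-m DEMs are commonly aggregated to 1 km and the aggregation
  order (derive slope then resample, or resample then derive) is genuinely
  ambiguous in practice, `terrain_covariates()` exposes both orders
  without claiming either is canonical.
* **Distances** — Euclidean distance from each cell center to the *vector*
  road/river/resident geometry (not a rasterised copy), which removes any
  rasterisation order dependence and admits an analytic oracle;
  `buffer_mask()` thresholds the same distances to build the road-zone
  bias mask.
* **Time series** — Savitzky–Golay smoothing of vegetation-index cubes by
  local least squares (any window/order pair, truncated-window fits at the
  edges; a polynomial of degree ≤ order is reproduced exactly) and
  per-cell mean/max/min/std summaries. The standard deviation uses the
  population divisor `n`: the statistics summarise one fixed observation
  year, not a sample from a larger one.

## The model

With presence records `x_1..x_m` and background cells `b_1..b_N`, the
model is the Gibbs distribution over background cells

`raw(x) = exp(lambda . f(x)) / Z`,

fitted by maximising the L1-penalised log-likelihood

`(1/m) sum_i lambda . f(x_i) - ln sum_j exp(lambda . f(b_j)) - sum_k beta_k |lambda_k|`.

The feature expansion `f` follows the reference tool: linear, quadratic,
product, threshold, and (forward and reverse) hinge transforms of the
continuous covariates, plus one indicator per observed categorical code.
Continuous features are min–max scaled to `[0, 1]` on *background* bounds
and clamped there at prediction time; hinge/threshold knots sit at
background quantiles (50 per variable by default). Which classes are
active follows the sample-size auto rule (`feature_classes_auto()`):
linear below 10 presences, + quadratic from 10, + hinge from 15, all
classes from 80. The published tool's own default behaviour is not fully
documented, so this rule is an explicit codification, configurable via
`classes`.

Per-feature penalties are `beta_k = beta * s_k / sqrt(m)` with `s_k` the
background standard deviation of feature `k` (per-class multipliers
default to 1). This approximates the published default regularisation
without importing its tuned interpolation tables.

Two numerical points matter:

* **Solver.** The objective is concave, so the fit is a deterministic
  proximal-gradient (FISTA) scheme with backtracking line search and
  gradient-based adaptive restart, run until the objective changes by
  less than `1e-6` (cap 5,000 iterations; exceeding it is an error that
  reports the final gradient norm). No randomness enters the fit.
* **Boundedness.** With the log-partition taken strictly over the supplied
  background, the objective is unbounded whenever some feature direction
  separates presences from background — which happens routinely with rich
  hinge expansions. The reference tool's default answer is to add any
  presence whose feature combination is absent from the background to the
  fitting background, keeping presence means inside the background feature
  hull; `maxent_fit(add_samples = TRUE)` (the default) does the same.
  `add_samples = FALSE` gives the strict formulation used in the
  closed-form tests.

The raw output sums to 1 over the (augmented) training background. The
logistic output is the entropy calibration
`L(x) = e^H raw(x) / (1 + e^H raw(x))` with `H` the entropy of the fitted
raw distribution — equivalent to assuming a typical-site prevalence of
0.5. Training gain is reported relative to the uniform background
distribution, minus the penalty, so the null model has gain exactly 0.

## Evaluation

`run_replicates()` implements repeated-subsample validation: each
replicate splits the presences 50/50 (77 presences → 38 training / 39
test), fits on the training half against the full background, and records
training AUC, test AUC and the maximum TSS. AUC is the rank-based
(Mann–Whitney) form with midranks, so ties are exact. TSS is evaluated on
the 11-point decile threshold grid `{0, 0.1, ..., 1}` — the natural
reading of "all 11 possible thresholds" for a 0–1 output — with ties in
the arg-max broken toward the smaller threshold (favouring sensitivity);
both grid and tie rule are configurable. The pseudo-absence set for TSS
is the background itself: the emulated survey design scores 10,000
pseudo-absences against a background of 10,000, which makes per-replicate
redrawing the identity,
but `pseudo_absence_n` can subsample per replicate (under the replicate
seed) if a smaller redraw is wanted. Each replicate is fitted cold (no
warm starts), so any replicate re-run in isolation reproduces its metrics
bit-identically — the property that makes shared split plans a valid
paired design across scenarios.

Split plans are a pure function of `(n_presence, n_reps, fraction, seed)`
through a hierarchical seed derivation (stage label + replicate id below
2^31), so two scenario runs given the same seed share identical splits.

**Jackknife importance** refits with each variable alone and with each
variable omitted (gains from a single fit on all presences; leave-one-out
fits warm-start from the all-variable solution, which only changes the
iteration path of a convex problem). **Contribution** is permutation
importance: the drop in training gain when one variable's values are
permuted jointly across presence + background rows, averaged over 10
permutations, floored at 0 and normalised to 100%. The original tool's
path-attribution is solver-specific, so the 0.5 exclusion rule is
interpreted as 0.5 *percent* of permutation contribution — an explicit
interpretation, flagged here. **Selection** first prunes correlated pairs
greedily (while any continuous pair has `|r| > 0.75` over background
cells, the lower with-only gain is removed; categorical variables are
exempt because Pearson r is undefined for codes), then drops variables
below the contribution floor.

The paired **Wilcoxon signed-rank test** is implemented from scratch:
zero differences are dropped (standard practice),
midranks handle ties, and for n ≤ 25 the exact two-sided p comes from the
rank generating polynomial (dynamic programming over doubled ranks, so
midranks stay exact); larger n uses the normal approximation with tie and
continuity correction. `stats::wilcox.test` serves only as an independent
cross-check in the tests.

AUC and TSS grades use the published left-open/right-closed boundaries
(AUC: ≤0.5 worse than random, then failed/poor/fair/good/excellent by
decile; TSS: bad/poor/fair/good/excellent by 0.2 steps).

## Mapping and scenario comparison

`predict_map()` produces the per-cell logistic map (replicate-mean when
given an `eval_report`); `binarize()` applies the max-TSS threshold of the
replicate-mean TSS curve; `suitable_area()` counts suitable cells times
the cell area, with the fraction taken over *valid* cells so the lake is
excluded from the denominator.

`compare_scenarios()` takes full and reduced reports fitted on shared
plans, binarises each at its own max-TSS threshold (mirroring the
procedure applied per model), and reports: suitable areas and the
extension percent `100 (A_full - A_reduced) / A_reduced`; the *increase
area* — valid cells where the full model's mean probability exceeds the
reduced one's by more than `delta` (default 0), restricted by default to
cells suitable under the full model; and paired Wilcoxon tests on
training AUC, test AUC and max TSS. There is no canonical
increase-area counting rule, so both `delta` and the suitability
restriction are explicit, recorded knobs. The comparison uses
replicate-mean maps (per-replicate maps are the noted alternative).

## The synthetic world

`generate_study()` emulates the structure of the study system rather than
any particular geography:

* a 100 × 100 grid of 1-km cells with an elliptical lake nodata mask, so
  "fraction of land area" logic is exercised;
* five Gaussian-random-field continuous layers standing in for climate,
  vegetation-index and altitude covariates (squared-exponential
  correlation, lengths 8–25 km — smooth at the basin scale, as bioclim
  and EVI summaries are), plus one 4-code categorical soil layer from a
  quantile-binned field;
* two road polylines, one river, and 15 resident sites clustered near the
  roads (settlement follows roads in the basin), with true-geometry
  distance layers;
* a known logistic suitability truth on min–max-scaled variables. The
  road coefficient is calibrated to the response scale observed for this
  species — about
  −1 logit per km, putting the half-probability contour near 1 km from
  roads when other factors are favourable — and road proximity is
  necessary but not sufficient: a climate stand-in (+3), altitude (−3),
  distance to resident site (−4) and soil-type effects (±1.5) carve the
  road corridor further, so suitable habitat is a small minority of the
  landscape and several variables carry real signal, with distance to
  road dominant and soil ancillary, the importance structure observed in
  the field;
* 77 presences sampled proportionally to suitability times a road-access
  bias `exp(-d_road / 10 km)` (surveys work from roads), greedily thinned
  to 2-km minimum spacing (earlier draw wins — deterministic given the
  draw order), at cell centers, without replacement by cell.

Background defaults: the emulated survey design draws 10,000 background
points over a 29,661-km² basin (about one cell in three); scaled to this
world that is 3,000 of ~9,300 valid cells, which the analysis scripts and
tests use. Background sampling defaults to the *entire* study area; the
10-km road-zone restriction is implemented and available
(`bias_correction = TRUE`), but restricting both the presences (via the
sampling bias) and the background to the same road corridor caps
presence–background discrimination by construction and is not the
default.

What a green recovery test establishes: that the pipeline, run end to
end on data whose generating process matches its assumptions, ranks the
truly dominant driver first, discriminates presences from background, and
detects the degradation when the anthropogenic covariates are withheld.
What it does not establish: realism of any particular bioclim variable,
spatial sampling pathologies beyond road bias (e.g. observer effects,
imperfect detection), registration/projection error between real GIS
layers, or the behaviour of the model under covariate shift outside the
background's feature hull (features are clamped there).

## Numerical choices, in one place

* Convergence: objective change < 1e-6, max 5,000 FISTA iterations,
  backtracking factor 2, adaptive restart; fits are deterministic.
* Features constant over the background are frozen at weight 0 (they
  carry no information and would otherwise unbound the objective).
* Degenerate permutation contributions (all drops 0) are spread evenly
  rather than returning 0/0.
* Points exactly on cell boundaries belong to the half-open cell; the
  grid's east/south edges clamp inward so boundary points are not lost.
* Bilinear resampling interpolates between cell centers and clamps at the
  source hull (edge cells extend outward); any nodata among contributing
  cells yields nodata. Categorical layers must use nearest-neighbour.
* TWI: slope floor `eps = 0.001`; pits and flats drain nowhere but still
  receive accumulation.
* Wilcoxon: exact path up to n = 25; two-sided p is twice the smaller
  tail, capped at 1.
* All stochastic stages (background, splits, permutations, the generator)
  draw through `derive_seed(master, stage, id)`; seeds stay below 2^31.

## Limitations

The solver is plain R + BLAS; at the default 50 knots per variable a full
9-variable fit over 3,000 background cells takes a couple of seconds, so
hundred-replicate designs take minutes, not seconds. The lambdas file
exchanges models between implementations but records only the fitted
predictor, not the training data. Reprojection between coordinate
reference systems is out of scope (`crs_tag` is carried, never
interpreted), as is acquisition of any external data product.
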