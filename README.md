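# pikasdm

Presence-only habitat suitability modelling for plateau pika (*Ochotona
curzoniae*), built as a single reproducible R pipeline: a from-scratch
L1-regularised maximum-entropy (Maxent-style) model plus everything around
it — raster handling, covariate derivation, replicate validation, variable
importance, threshold optimisation, suitability mapping, and a paired
with/without-human-factors scenario comparison — exercised end-to-end on
synthetic landscapes with known truth.

## Who this is for

Ecologists and biostatisticians who model species distributions from
occurrence records plus background samples (no confirmed absences), and
want the whole workflow — not just the estimator — scripted, seeded and
testable. The plateau pika case is the motivating system: a keystone
burrowing lagomorph of the Qinghai–Tibetan Plateau whose 1-km-scale
distribution is driven by both environmental covariates and human
factors (distance to roads and settlements).

## The model

With presence records `x_1..x_m` and background cells `b_1..b_N`, the
fitted distribution over background cells is the Gibbs form

    raw(x) = exp(lambda . f(x)) / Z,
    Z = sum_j exp(lambda . f(b_j)),

with `lambda` maximising the penalised average presence log-likelihood

    (1/m) sum_i lambda . f(x_i)  -  ln Z  -  sum_k beta_k |lambda_k|,

where `f` is the Maxent feature expansion (linear, quadratic, product,
threshold, forward/reverse hinge, categorical indicators; knots at
background quantiles) and `beta_k = beta * s_k / sqrt(m)` scales each
penalty by the feature's background standard deviation. The problem is
convex and solved by a deterministic proximal-gradient (FISTA) scheme to
an objective tolerance of 1e-6. Reported suitability is the logistic
output `L(x) = e^H raw(x) / (1 + e^H raw(x))` with `H` the entropy of the
fitted raw distribution.

Validation follows the repeated-subsample design: per replicate, a 50/50
presence split, training/test AUC (rank-based, tie-exact) against the
background, TSS over the 11-point decile threshold grid, and the max-TSS
threshold for binarising maps. Variable importance uses the jackknife
(with-only / leave-one-out training gains) and permutation contributions;
selection prunes `|r| > 0.75` pairs (lower jackknife gain loses) and drops
contributions below 0.5%. Scenario comparisons share split plans so the
per-replicate metrics are paired, and are tested with an exact Wilcoxon
signed-rank test (2^n enumeration via the rank generating polynomial for
n <= 25).

See `vignettes/pika-suitability-modelling.Rmd` for assumptions, numerical
choices and the synthetic world's design.

## Worked example

The `analysis/` scripts run the full study on the synthetic world
(replicate counts are CLI flags; the defaults scale to desk hardware):

```sh
Rscript analysis/01_simulate.R        --seed 1 --out results/study
Rscript analysis/02_fit_evaluate.R    --seed 1 --reps 20 --out results/fit
Rscript analysis/03_compare_scenarios.R --seed 1 --reps 20 --out results/compare
```

Stage 2 prints (seed 1, 20 replicates):

```
pipeline_result
  variables: lst_day_mean, soil_type, dis_to_road
eval_report: 20 replicates over 3 variables
    metric      mean          sd
 train_auc 0.9485186 0.003565418
  test_auc 0.9422096 0.004584349
   max_tss 0.8073397 0.017781677
max-TSS threshold (replicate-mean curve): 0.1 (TSS 0.7969)
  suitable area 1668 (17.9% of valid land)

jackknife ranking (training gain with only the variable):
jackknife_report: all-variables gain 1.5798
        variable gain_with_only gain_without
     dis_to_road     1.55327816     1.159455
 dis_to_resident     1.00611815     1.579357
        altitude     0.51371848     1.579471
    ...
```

Read: after correlation/contribution screening three variables remain;
the model discriminates test presences from background with mean AUC 0.94
(an "excellent" grade); binarising the replicate-mean map at the max-TSS
threshold (0.1) marks 1,668 km² — 17.9% of the unmasked land — as
suitable; and distance to road carries by far the highest standalone
training gain, i.e. the dominant driver planted in the synthetic truth is
recovered. Stage 3 then refits without the two human factors on the same
splits and background:

```
scenario_comparison (full vs reduced)
  thresholds: 0.1 / 0.3
  suitable area: 1668 / 2295 (extension -27.3%)
  increase area: 430
  Wilcoxon train_auc W = 210      p = 1.91e-06   (greater)
  Wilcoxon test_auc  W = 210      p = 1.91e-06   (greater)
  Wilcoxon max_tss   W = 209      p = 3.81e-06   (greater)
```

Every accuracy metric drops significantly when the anthropogenic
covariates are withheld (paired p << 0.01), and the full model raises the
presence probability over 430 km² of the suitable range — the qualitative
signature of human factors shaping the species' distribution.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — generates the default synthetic study under the given seed,
fits and evaluates the model (variable selection, replicates, threshold,
maps), runs the with/without-human-factors comparison — and writes its
results summary as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
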