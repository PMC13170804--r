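---
title: "Methods: modelling and upscaling CH4 emissions from nutrient-enriched rivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and upscaling CH4 emissions from nutrient-enriched rivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverch4)
```

## The problem

Rivers draining human-impacted landscapes — urban settlements, croplands,
or regions with population density above 20 people km^-2 — are
nutrient-enriched, and nutrient enrichment (total phosphorus and ammonium
nitrogen in particular) is strongly coupled to riverine methane
concentration and diffusive flux. `riverch4` implements the full analysis
chain that turns that coupling into gridded emission estimates and
counterfactual mitigation numbers:

1. **Driver screening** — standardized (Z-score) bivariate regressions
   between aquatic variables and CH4 concentration/flux, globally, within
   subgroups (continent, disturbance type, impacted vs. pristine) and
   along a population-density gradient, with Wilcoxon rank-sum group
   comparisons.
2. **Monthly ensembles** — for each calendar month, a random forest, a
   gradient-boosted tree model and an RBF support-vector regressor are
   fitted to log CH4 concentration or log diffusive flux on the month and
   its two adjacent months, with a seeded 70/30 split, 10-fold-CV
   hyperparameter tuning, LOOCV evaluation, per-algorithm importance
   fused to a 0–1 ranking, nutrient ablation and partial dependence.
3. **Upscaling** — per-grid-cell nutrient concentrations from loads and
   runoff, monthly river surface area (reach width × length, masked for
   dry/ice months, extrapolated to unmapped small Strahler orders),
   flux × area × days × 16.04 mg mmol^-1 to grams, a population-density
   stratified ebullitive component, and annual/regional aggregation.
4. **Scenarios** — nutrient fields edited under *sustainable* (country
   reduction ratios), *half* and *pristine* (per-basin pristine levels)
   counterfactuals, re-predicted with the same models; mitigation is the
   current-minus-scenario difference.

Everything is exercised against a synthetic world with a known response
surface, so the tests are parameter-recovery tests rather than snapshot
comparisons.

## The synthetic world

`truth_params()` fixes the generative model

$$\ln F = a + \sum_s \beta_s \ln C_s + \beta_T T + \sum_j \gamma_j z_j +
  \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),$$

with $F$ the diffusive flux (mmol m^-2 d^-1), $C_s$ the four nutrient
concentrations (mg L^-1), $T$ water temperature (°C) and $z_j$
standard-normal latents behind the terrestrial predictors. CH4
concentration follows the same linear form scaled by `conc_beta_scale`
with its own intercept and noise. Defaults and the reasoning behind them:

* `beta_logTP = 0.5`, `beta_logNH4 = 0.4` — TP and NH4-N are the dominant
  drivers, with standardized coefficients in the 0.4–0.6 range observed
  for enriched rivers; `beta_logTN = 0.1`, `beta_logNO3 = 0.05` — weak,
  reflecting the ambiguous role of oxidized nitrogen.
* `noise_sd = 0.3` log-units — yields theoretical R² near 0.85 for the
  single-driver world, consistent with monthly model skill in the 0.6–0.9
  range reported for this kind of data.
* `enrichment_multipliers = (urban 20, cropland 10, dense 8, pristine 1)`
  — impacted-class nutrient medians are drawn 5–40× above pristine
  levels, the order of magnitude of observed contrasts. Nutrients are
  log-normal (`nutrient_sdlog = 0.8`) because river nutrient
  concentrations span orders of magnitude.
* Landscape class is assigned *before* population density, and density is
  drawn class-conditionally (pristine ≤ 20, "dense" > 20 people km^-2),
  so the >20-rule used by `classify_human_impacted()` is self-consistent
  by construction.
* `ebullition_breaks = (0, 20, 200, Inf)`, `ratios = (0.2, 0.4, 0.6)` —
  the ebullitive:diffusive ratio rises with population density. The
  source analysis stratifies this relationship by density group but does
  not print the bins, so they are configuration, not constants; the
  per-group constant ratio is a declared stand-in for whatever functional
  form the original relationship had.
* All randomness flows from the single integer `seed`; identical
  parameters give byte-identical tables, and generator calls restore the
  caller's RNG state.

What the generator deliberately does **not** emulate: real river routing
or network topology (reaches are i.i.d. within cells), spatial
autocorrelation between neighbouring cells, measurement error in the
covariates, and seasonal covariance structures beyond a sinusoidal
temperature/runoff cycle. A green recovery test therefore establishes
that the *pipeline machinery* is correct — not that the effect sizes are
transportable to real rivers.

`truth_theoretical_r2()` and `truth_theoretical_correlation()` return the
analytic targets the recovery tests compare against, including the
cross-species covariance induced by the shared class multiplier (all four
nutrients are scaled by the same landscape-class factor, so their logs
are positively correlated).

## The learners

No random-forest, boosting or SVM package is assumed: the three learners
are implemented in compiled code inside the package.

* **Forest** — bagged CART regression trees, per-node feature subsampling
  (`mtry`, default p/3). Importance is the mean increase in out-of-bag
  MSE under within-column permutation (the %IncMSE idea, unscaled — the
  fusion step min-max normalizes anyway).
* **Boosting** — least-squares gradient boosting of depth-limited trees
  (default depth 3, shrinkage 0.1). Importance is mean |SHAP| from an
  exact path-dependent TreeSHAP; the test suite checks local accuracy
  (attributions + base value = prediction) and equality with a
  brute-force Shapley enumeration on small trees.
* **SVR** — epsilon-insensitive regression with an RBF kernel. The bias
  term is folded into the kernel (K + 1), which removes the dual equality
  constraint; the resulting box-constrained problem is solved exactly by
  cyclic coordinate descent with soft-thresholding. This formulation is
  deterministic and is verified against a quadratic-programming solution
  of the same dual. Predictors and the response are standardized
  internally; `gamma` defaults to 1/p on the standardized scale.
  Importance is seeded permutation importance.

Both tree engines draw from R's RNG stream, so `set.seed()` (or the
pipeline's recorded seeds) makes fits bit-reproducible.

## Numerical and design choices

* **Back-transformation.** Ensemble averaging happens in log space (the
  three log-scale predictions are averaged, then exponentiated). Plain
  exponentiation is the default; a Duan smearing factor estimated from
  training residuals is available via `smearing = TRUE`. The retransform
  choice is not dictated by the source description, so it is a flag, not
  a constant.
* **Monthly windows.** A month's model trains on the focal month and its
  two neighbours, wrapping the year boundary (January uses December,
  January, February); the three months are weighted equally.
* **Tuning.** Grid search by seeded k-fold CV minimizing mean squared
  residual; ties break in first-in-grid order. Shipped grids are small
  (`default_grids("test")`) so the suite stays inside desk budgets;
  `"full"` widens them.
* **LOOCV.** Exactly n fits by contract; above a configurable `cap`
  (default 200) a fixed-seed subsample is used with a warning — n model
  fits at database scale is not a desk-scale operation.
* **Skew handling.** Variables gated by a Shapiro–Wilk test (p < 0.05 →
  natural log). The test statistic is defined for limited n, so samples
  above 5000 are subsampled with a fixed seed. Zeros under the log branch
  are offset by half the smallest positive value, and the offset is
  recorded; signed predictors (e.g. air temperature) never take the log
  branch. Transform decisions are made once on the training table and
  travel with the fitted ensemble, so prediction-time tables are
  transformed identically.
* **Screening.** Bivariate standardized regressions by default (the
  coefficient then *is* the Pearson correlation); `mode = "adjusted"`
  fits one multiple regression per response and subgroup instead.
  Subgroups under `min_n = 10` complete pairs are emitted flagged
  `low_n`, never silently dropped. The density-gradient curve is
  loess-smoothed with span 0.75 (degree 1), both configurable.
* **Wilcoxon.** Exact rank-sum p-value when both samples have fewer than
  50 values and no ties; otherwise the normal approximation with tie and
  continuity correction. The exact branch is verified against full
  enumeration of rank assignments for n+m ≤ 10.
* **Units.** Molar mass fixed at 16.04 g mol^-1 CH4; month lengths from a
  non-leap 365-day calendar (`leap = TRUE` switches February). Emission =
  flux (mmol m^-2 d^-1) × area (m^2) × days × 16.04 / 1000 g, aggregated
  to Tg (10^12 g).
* **Strahler extrapolation.** ln(area) is fitted linearly on stream order
  over a cell's observed orders (≥ 2 required) and evaluated at unmapped
  smaller orders; the extrapolated area is added to the cell's masked
  area. Cells with a single observed order contribute no extrapolation.
* **Uncertainty.** Regional totals carry half the range across the three
  ensemble members, propagated through the full upscaling chain. A
  bootstrap over training rows would be the other defensible option; it
  is not implemented because n model refits per bootstrap replicate is
  outside the desk-scale budget, and the member spread already reflects
  the dominant algorithmic disagreement.
* **Scenarios.** Only the four nutrient fields change; `apply_scenario()`
  tags its output and re-application is a no-op. The pristine lookup is
  the per-basin *median* of pristine-river concentrations (the summary
  statistic is unstated in the source; the median is robust to the
  log-normal spread), with the regional pristine median as fallback for
  basins lacking pristine rivers, flagged per cell. The half scenario
  applies the ×0.5 literally, with no clamping at pristine levels. At
  desk scale the pipeline uses the continent label as the basin stand-in
  when deriving lookups from observations; user-supplied lookups may key
  on any basin identifier.
* **Determinism.** Every stage consumes an explicit seed recorded in the
  run manifest together with a content hash of the configuration
  (excluding the output directory) and md5 sums of every output file; two
  runs of one configuration are byte-identical.

## Known limitations

* The learners are compact reference implementations: no sparsity-aware
  splitting, no early stopping, no SMO shrinking heuristics. They are
  exact where it matters (tests against closed forms and QP/enumeration
  oracles) but slower than the heavily optimized libraries at database
  scale.
* The ebullition model is a per-density-group constant ratio — a
  declared stand-in where the original analysis fit group-specific
  relationships.
* The synthetic world's theoretical R² assumes the generator's own
  covariance structure; comparisons against it are meaningful only for
  generator output.
* Scenario predictions extrapolate the fitted models into nutrient ranges
  (pristine levels) sparsely covered by impacted training data; tree
  learners clamp rather than extrapolate there, which is conservative.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "run", n_sites = 150, n_cells = 6,
                       reaches_per_cell = 3,
                       params = truth_params(seed = 2024),
                       seed = 77, min_n = 8,
                       scenarios = c("half", "pristine"))
res <- run_pipeline(cfg)
res$mitigation[res$mitigation$region_type == "global", ]
```

The same run is available from the shell:

```sh
Rscript -e 'riverch4::riverch4_cli()' run --config config.yml
```

Every number shown in the README's worked example is produced by this
code path; the vignette states no empirical result that the tests or
`scripts/acceptance.R` do not themselves compute.
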