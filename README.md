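# riverch4

Estimating methane (CH4) emissions from nutrient-enriched, human-impacted
rivers — and how much of them nutrient management could remove.

Rivers draining urban settlements, croplands, or landscapes with more than
20 people km⁻² carry strongly elevated nutrient loads, and nutrient
concentrations (total phosphorus and ammonium nitrogen above all) are
tightly coupled to riverine CH4 concentration and diffusive flux. This
package implements, as a tested and fully reproducible pipeline, the
analysis chain that quantifies that coupling and turns it into gridded
emission and mitigation estimates:

1. **Driver screening.** Standardized regression coefficients
   (both sides Z-scored, so the bivariate coefficient equals Pearson *r*)
   between aquatic variables and CH4 concentration/flux — globally, by
   continent, by disturbance type, impacted vs. pristine, and along a
   population-density gradient with loess smoothing; Wilcoxon rank-sum
   tests for group contrasts. Variables are log-transformed when a
   Shapiro–Wilk test rejects normality.
2. **Monthly three-learner ensembles.** For each calendar month (trained
   on the month and its two neighbours, wrapping the year), a random
   forest, gradient-boosted trees and an RBF support-vector regressor
   predict ln CH4 concentration and ln diffusive flux from 21 reach-scale
   predictors (16 terrestrial + 4 nutrients + water temperature), with
   10-fold-CV tuning, a seeded 70/30 split, LOOCV evaluation, and variable
   importance fused across algorithms (%IncMSE, SHAP, permutation — each
   min-max normalized to 0–1, then averaged). The three learners are
   implemented in compiled code inside the package and verified against
   independent oracles (a quadratic-programming solution of the SVR dual,
   brute-force Shapley enumeration for TreeSHAP).
3. **Upscaling.** Cell nutrient concentration = 1000 × load / runoff
   (mg L⁻¹); monthly river surface area = Σ width × length over active
   reaches, masked for dry/ice months and extrapolated to unmapped small
   Strahler orders by a log-linear order fit; emission = flux × area ×
   days × 16.04 mg mmol⁻¹; an ebullitive component is added as a
   population-density-group multiple of the diffusive flux; totals are
   aggregated per cell, climate zone, continent and income group in
   Tg CH4 yr⁻¹.
4. **Counterfactual scenarios.** Nutrient fields edited under
   *sustainable* (country-specific reduction ratios, phosphorus reduced
   equivalently), *half* (×0.5) and *pristine* (per-basin pristine
   medians) scenarios, re-predicted with the same models; mitigation =
   current − scenario emissions, absolute and percent.

A synthetic-data module (`truth_params()`, `simulate_observations()`,
`generate_network()`) generates observation, reach and grid-cell tables
from a known log-linear response surface, so every stage is tested by
parameter recovery with analytic targets — no external downloads.

## Worked example

```r
library(riverch4)

cfg <- pipeline_config(out_dir = "run", n_sites = 150, n_cells = 6,
                       reaches_per_cell = 3,
                       params = truth_params(seed = 2024),
                       seed = 77, min_n = 8,
                       scenarios = c("half", "pristine"))
res <- run_pipeline(cfg)
#> inputs: 150 observations, 18 reaches, 6 cells
#> screening: 24 coefficient records
#> train: 12 monthly models x 1 responses
#> predict: 60 cell-month predictions
#> upscale: total 3.819e-06 Tg CH4 yr-1
#> scenario: 2 scenarios evaluated
#> manifest: 23085fa19fc7cad7a771de23c4299812

res$mitigation[res$mitigation$region_type == "global",
               c("scenario", "current_Tg", "reduction_Tg", "reduction_pct")]
#>  scenario   current_Tg reduction_Tg reduction_pct
#>      half 3.819115e-06 6.581878e-07      17.23404
#>  pristine 3.819115e-06 1.267819e-06      33.19667
```

Reading this: the six-cell synthetic world emits 3.8 × 10⁻⁶ Tg CH4 yr⁻¹
(a desk-scale world, hence the tiny absolute number); halving nutrient
concentrations removes ~17 % of it, resetting them to pristine levels
~33 % — the pristine counterfactual bounds the nutrient-attributable
share. Driver screening on the same run recovers the built-in coupling:

```r
subset(res$coefficients, predictor %in% c("TP", "NH4N") &
                         response == "diff_flux")[,
       c("predictor", "subgroup", "coefficient", "n_used")]
#>  predictor subgroup coefficient n_used
#>         TP   global       0.852    150
#>       NH4N   global       0.815    150
#>         TP impacted       0.597    114
#>         TP pristine       0.628     36
#>       NH4N impacted       0.533    114
#>       NH4N pristine       0.395     36
```

The coefficients are on the Z-score scale (here: the Pearson correlation
between log-transformed flux and nutrient). Per-month importance fusion
(`fuse_importance(res$ensembles$ln_flux[["6"]])`) ranks predictors on the
0–1 fused scale; with only ~35 windowed observations per month in this
small example the single-month ranking is noisy by design — the
acceptance tests use larger samples where TP leads.

### Command line

```sh
Rscript -e 'riverch4::riverch4_cli()' run --config config.yml
# or staged:
Rscript -e 'riverch4::riverch4_cli()' simulate --config config.yml
Rscript -e 'riverch4::riverch4_cli()' screen   --config config.yml
Rscript -e 'riverch4::riverch4_cli()' train    --config config.yml
Rscript -e 'riverch4::riverch4_cli()' scenario --config config.yml
```

Configs are YAML (`write_pipeline_config()` / `read_pipeline_config()`);
exit code 2 flags validation errors, 1 runtime failures. Outputs —
`coefficients.csv`, `predictions.csv`, `emissions.csv`,
`regional_summary.csv`, `mitigation.csv`, `manifest.json` — are
byte-identical across reruns of the same configuration.

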