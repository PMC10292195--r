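# biomeshift

Stacked-ensemble modelling of biome distributions under climate scenarios,
with spatial block cross-validation, probability-based skill scores,
per-pixel uncertainty layers and equal-area transition accounting.

## What problem this solves

Ecologists modelling the potential distribution of biomes face a
multiclass classification problem with two awkward properties: observation
points are spatially clustered (so naive cross-validation leaks and
flatters the model) and class frequencies are wildly imbalanced (so
hard-label accuracy misleads). `biomeshift` packages the full workflow for
this setting:

1. **Fit** a stacked ensemble — random forest, gradient-boosted trees and a
   lasso multinomial GLM, combined by a multinomial logistic meta-learner
   trained on out-of-fold class probabilities — with folds built from
   100 km equal-area blocks rather than individual points.
2. **Evaluate** with k-fold spatial cross-validation repeated r times,
   reporting overall accuracy, logloss and the log-loss skill score

   R²_logloss = 1 − LL(model) / LL(baseline),

   where the baseline is the constant class-prevalence predictor (per-class
   values use one-vs-rest binary logloss), plus TPR and F1 per class.
3. **Predict** per-pixel probability cubes (percent, summing to 100) with
   two uncertainty layers: the spread (SD, n = 3) of the base learners'
   probabilities, and the **margin of victory** — the gap in percentage
   points between the top two class probabilities (0 = tied, 100 = certain).
4. **Aggregate** the 20-class biome legend to the six terrestrial IUCN
   biomes (T1–T6) by exact probability-mass summation.
5. **Detect transitions** between a current and a scenario-perturbed
   prediction, keep only pixels with margin of victory ≥ 50 %, count
   scenario agreement, and tally km² per (from → to) biome pair using the
   exact spherical-zone pixel area R²·Δλ·(sin φ_top − sin φ_bottom) on the
   authalic sphere (R = 6371.0072 km).

A seeded synthetic-data module (smooth autocorrelated covariate fields,
threshold-rule labels with geometric class imbalance, clustered noisy
sampling, additive-warming / precipitation-scaling scenarios) makes the
whole pipeline testable end to end without any downloads.

## Worked example

```r
library(biomeshift)

g <- grid_spec(48, 48, lon_min = -6, lat_min = 20, cell_size = 0.5)
layers <- data.frame(
  name = c("bio01", "bio12", "elev"),
  kind = c("temperature", "precipitation", "terrain"))
stack  <- generate_covariates(g, layers, corr_length = 6, seed = 1)
labels <- generate_true_labels(stack, K = 4, rule_seed = 2, prevalence_skew = 2)
obs    <- sample_observations(labels, g, n_points = 600, n_clusters = 12,
                              label_noise = 0.1, seed = 3)

blocks <- assign_blocks(obs)                  # 100 km sinusoidal blocks
X   <- extract_features(stack, obs)
fit <- biome_stack(X, obs$label, blocks, seed = 4)
fit
#> <biome_stack> 4 classes, 3 features, 600 training points
#>   base learners: random forest, gradient-boosted trees, lasso GLM
#>   meta-learner : multinomial logistic (ridge 0.001)
#>   stacked OOF  : accuracy 0.900, logloss 0.413 nats

run_spatial_cv(X, obs$label, blocks, k = 5, repeats = 2, seed = 5)
#> <cv_report> 5-fold spatial CV x 2 repeats
#>   overall_accuracy  0.899 +/- 0.006
#>   logloss           0.473 +/- 0.014
#>   r2_logloss        0.585 +/- 0.015
#> Per-class (mean over repeats):
#>     class n_obs  tpr   f1 r2_logloss
#>  class_01   259 0.97 0.94       0.70
#>  class_02   245 0.96 0.92       0.65
#>  class_03    41 0.48 0.63       0.27
#>  class_04    55 0.63 0.73       0.36
```

The stacked out-of-fold accuracy of 0.90 sits close to the 10 % label-noise
ceiling; the skill score 0.585 says the model's logloss is 58.5 % below the
prevalence baseline's; the two rare classes show the depressed TPR/skill
that heavy imbalance produces.

```r
pred   <- predict_probabilities(fit, stack)       # percent cube + SD layers
future <- perturb_scenario(stack, temperature_shift = 3,
                           precipitation_scale = 0.85,
                           scenario_tag = "warm_dry")
pred_f <- predict_probabilities(fit, future)

cur <- list(hard = hard_classify(pred$cube),   mov = margin_of_victory(pred$cube))
fut <- list(hard = hard_classify(pred_f$cube), mov = margin_of_victory(pred_f$cube))
transition_areas(detect_transitions(cur, fut, threshold = 50),
                 pixel_areas(g))
#> <transition_table> total confident changed area 5.814e+05 km^2 (MoV >= 50, filter both)
#>           to
#> from       class_01 class_02 class_03 class_04
#>   class_01        0   219400   202400    18730
#>   class_02        0        0        0    57840
#>   class_03        0        0        0        0
#>   class_04        0        0    83100        0
```

Each cell is the equal-area km² of pixels that confidently (margin of
victory ≥ 50 % in both epochs) switch from the row class to the column
class under the 3 °C warmer, 15 % drier scenario.

`run_pipeline("config.yaml")` (or `run_demo()`, or the thin CLI under
`inst/cli/biomeshift`) orchestrates all of the above from a single YAML
config — see `inst/extdata/demo_config.yaml` — writing ASCII-grid rasters,
CSV/GeoJSON points, transition tables and a JSON run manifest.

## Further reading

The methods vignette (`vignettes/biomeshift-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical conventions.
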