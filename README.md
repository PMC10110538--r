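# sketchcomm

Analysis machinery for **repeated drawing-based reference games** — the
experimental paradigm in which a *sketcher* repeatedly draws target objects
so that a *viewer* can pick them out of a 4-object context, and the pair
gradually converges on sparse, pair-specific graphical conventions.

The package is aimed at cognitive and behavioral scientists studying visual
communication. It provides:

* **Communicative efficiency.** The per-trial *balanced integration score*,
  `BIS = z(accuracy) − z(RT)` with z-scoring within an interaction (sample
  sd; optional balanced 16-trial pre/post scope), and linear mixed-effects
  fits of its trajectory: repetition trend (continuous appearance index
  1–8 plus orthogonalized quadratic, by-dyad random slopes), the
  pre/post × condition (repeated vs. control) interaction, and the
  group × repetition interaction for yoked vs. shuffled recognition
  controls.
* **Drawing similarity trajectories.** Drawings embedded as fixed-length
  feature vectors; similarity `s_ij = cov(r_i, r_j) / sqrt(var(r_i)
  var(r_j))` (Pearson). Within-dyad convergence `s(k, k+1)` of successive
  drawings, between-dyad divergence of same-object same-repetition
  drawings, and a permutation test that scrambles repetition labels within
  each sketcher × object cell (two-sided, add-one corrected).
* **Diagnosticity scoring.** Drawn-region masks and per-object
  diagnosticity heatmaps in object-image coordinates; a drawing's score is
  the mean map value over its mask pixels (controlling for drawing size),
  and a mixed model tests whether repeated objects gain diagnosticity from
  pre to post relative to controls.
* **Design generators.** The exact 40-trial session structure
  (8 pre + 24 repetition + 8 post; repeated objects targeted 8×, controls
  2×), yoked and shuffled recognition sequences (10 sources × 4 drawings,
  repetition slots preserved), attention-check insertion and the 4-of-5
  inclusion rule.
* **A first-class synthetic-data generator** (`sim_config()`,
  `generate_world()`, `simulate_cohort()`): a seeded generative model of
  convention formation (stroke simplification biased toward diagnostic
  parts, embedding drift toward dyad-specific attractors, a logistic
  viewer) whose ground truth is known, so every analysis can be validated
  by sign-recovery and type-I calibration.

File formats are plain text: trials CSV, strokes JSON-lines, 8-bit
grayscale PNG masks/maps.

## Worked example

```r
library(sketchcomm)
cfg <- sim_config(n_dyads = 10, seed = 2024)
report <- run_pipeline(cfg, n_perm = 199)
report
```

```
== sketchcomm pipeline report ==
dyads: 10  config: 10602beb067b96d512b1d96d56994016  version: 0.1.0
viewer accuracy: 80.2% overall, 75.0% at first appearance
efficiency (BIS) repetition trend:   <trend_fit rep_c: b = 0.3869, t = 12.1, p = 5.89e-07 [lmer: y ~ rep_c + rep_q + (1 + rep_c | unit)]>
stroke-count repetition trend:       <trend_fit rep_c: b = -0.6438, t = -17.6, p = 4.75e-14 [lmer: y ~ rep_c + rep_q + (1 + rep_c | unit)]>
pre/post x condition (BIS):          <trend_fit phasepost:conditionrepeated: b = 1.581, t = 3.52, p = 0.00294 [lmer: y ~ phase * condition + (1 + phase * condition | unit)]>
  ... balanced 16-trial z-scoring:   <trend_fit phasepost:conditionrepeated: b = 1.407, t = 3.44, p = 0.00339 [lmer: y ~ phase * condition + (1 + phase * condition | unit)]>
within-dyad convergence trend:       <trend_fit k_c: b = 0.006472, t = 7.13, p = 0.00475 [lmer: s ~ k_c + (1 + k_c | object_id) + (1 + k_c | dyad_id)]>
between-dyad divergence trend:       <trend_fit k_c: b = -0.04646, t = -37.8, p = 1.67e-06 [lmer: s ~ k_c + k_q + (1 + k_c | object_id)]>
divergence permutation null:         <permutation_result: observed = -13.74, p = 0.005 (n_perm = 199), null 95% [-1.13, 1.36]>
pre/post x condition diagnosticity:  <trend_fit phasepost:conditionrepeated: b = 0.01353, t = 1.13, p = 0.261 [lmer: y ~ phase * condition + (1 + phase + condition | sketcher_id) + (1 + phase + condition | object_id)]>
```

Reading the report: viewers start near the engaged-but-not-at-ceiling
level (75% at first appearance vs. 25% chance) and efficiency rises with
each repetition (`b = 0.39` BIS units per appearance) while stroke counts
fall (`b = −0.64` strokes per appearance). Efficiency gains are larger for
repeatedly drawn objects than for controls (positive phase × condition
interaction under both z-scoring scopes). Successive drawings within a
dyad grow more similar (positive convergence slope), while drawings of the
same object by *different* dyads drift apart (negative divergence slope,
far outside the scramble null: observed t = −13.7 vs. null 95% interval
[−1.1, 1.4]). The diagnosticity interaction is positive (repeated objects'
drawings become relatively more selective for diagnostic parts), modest at
this cohort size. Each line records the mixed-model formula actually fit
after pruning non-converging random-effects structures.

A thin command-line wrapper is included at
`inst/scripts/sketchcomm.R` (`simulate` and `report` subcommands); the
methods vignette (`vignettes/graphical-conventions.Rmd`) documents the
model, its parameters and the package's statistical choices.

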