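# vitalvar

Early warning of sepsis onset from bedside-monitor vital signs.

ICU monitors log mean arterial pressure (MAP), heart rate (HR), respiratory
rate (RR) and temperature (TEMP) every 10 minutes. Patients heading toward
sepsis tend to become physiologically *unstable* hours before clinicians
recognize the syndrome. `vitalvar` turns that observation into a tested
analysis pipeline:

* **Variability features.** For a `T`-hour window (`N = 6·T` samples per
  sign) ending a fixed horizon before the detection moment `T0`, the series
  `X` is reduced to its ordered interior local extrema `Y` (plateaus
  collapsed, endpoints appended). Five features per sign:
  * `f1 = |Y|` — the number of trend changes,
  * `f2..f5 = mean, median, min, max { |y_(i+1) − y_i| }` — the swing
    intensities, in sign units;

  20 features per patient, against a descriptive comparator set
  (mean/median/min/max/sd of the raw samples).
* **A calibrated synthetic cohort generator** — the original EMR records are
  not publicly available — whose extracted-feature distributions are
  moment-matched to the published per-group feature statistics
  (`reference_group_stats()`), with septic instability ramping up toward
  `T0` so that collection-interval and prediction-horizon sweeps remain
  meaningful.
* **Selection, classification, evaluation.** Permutation-importance top-2
  per model with merged union; stratified 75/25 split; 10-fold CV tuning;
  logistic regression, linear/RBF/polynomial SVMs (sigmoid-mapped
  probabilities) and a single-hidden-layer neural network; ROC/PR curves,
  AUC, AUC-PR, sensitivity/specificity/PPV/NPV/accuracy at the strict 0.5
  threshold; collection-interval and horizon sweeps and a
  variability-vs-baseline comparison.

See `vignettes/variability-features.Rmd` for the model, every convention
the feature definitions leave open, calibration details and limitations.

## Worked example

The canonical hand-worked case — a triangular MAP excursion 60 → 95 → 60:

```r
library(vitalvar)
compute_features(c(60, 95, 60))
#> f1 f2 f3 f4 f5
#>  1 35 35 35 35
```

One trend change (the peak), and every swing statistic equals the 35-mmHg
excursion: an unstable-looking record with a single large swing.

An end-to-end run on a small simulated cohort (60 septic + 60 control,
8-h window, 4-h horizon):

```r
cfg <- default_pipeline_config(seed = 3)
cfg$n_septic <- 60; cfg$n_control <- 60; cfg$n_repeats <- 10
m <- run_pipeline(cfg, out_dir = "results")
print(m)
#> <run_manifest> 2026-09-23T13:33:29+0000
#>   config 4093fdb5a9365b37a3cad88f6fafc411
#>   selected: RR_f2, RR_f5, MAP_f1, RR_f4
#>       family    auc auc_pr sensitivity specificity    ppv    npv accuracy
#> 1         LR 0.8489 0.8043      0.8667      0.6667 0.7222 0.8333   0.7667
#> 2 SVM_linear 0.9111 0.8803      1.0000      0.6667 0.7500 1.0000   0.8333
#> 3    SVM_RBF 0.9378 0.9495      1.0000      0.5333 0.6818 1.0000   0.7667
#> 4   SVM_poly 0.9556 0.9558      1.0000      0.5333 0.6818 1.0000   0.7667
#> 5        ANN 0.9333 0.9236      1.0000      0.7333 0.7895 1.0000   0.8667
```

Reading the output: the selection phase merged the per-model top-2 lists
into four features (dominated by respiratory-rate and arterial-pressure
variability); each row is one classifier evaluated on the held-out 25%
(30 patients here), with threshold-free AUC/AUC-PR and 0.5-threshold
confusion metrics. On synthetic cohorts the classes separate more cleanly
than in the real study (see the vignette's limitations), so these AUCs are
structural, not clinical, numbers. All artifacts (cohort CSV, feature CSV,
selection JSON, report JSON, manifest with checksums) land in `results/`
and regenerate bit-identically from the same configuration and seed.

A thin command line wraps the same functions:

```sh
inst/exec/vitalvar simulate --seed 42 --out cohort.csv
inst/exec/vitalvar extract --in cohort.csv --features variability --T 8 --horizon 4 --out features.csv
inst/exec/vitalvar run --config pipeline.json --out results/
```

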