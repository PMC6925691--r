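---
title: "Vital-sign variability features for early sepsis prediction: methods"
author: "vitalvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vital-sign variability features for early sepsis prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vitalvar)
```

## The problem and the method

Patients who develop sepsis in the ICU tend to pass through a period of
physiologic *instability* before the syndrome is clinically recognized.
`vitalvar` quantifies that instability from the four vital signs every ICU
monitor records — mean arterial pressure (MAP, mmHg), heart rate (HR, bpm),
respiratory rate (RR, breaths/min) and core temperature (TEMP, °C) — sampled
every 10 minutes, and uses it to predict whether a patient will reach the
sepsis detection moment `T0` a fixed horizon later.

The 12 hours before `T0` are split into a *collection interval* of `T` hours
(default 8, so `N = 6·T = 48` samples per sign) and a *prediction horizon*
(default 4 h) separating the prediction moment from `T0`. Windows are sliced
half-open — `[T0 − (T + horizon), T0 − horizon)` — so the sample at the
prediction moment itself is excluded, and patients without complete coverage
on the sampling grid are rejected rather than imputed.

For each windowed series `X` the extractor finds the ordered sequence of
interior local extrema (each one a *trend change*: a reversal of the
series' direction). Runs of equal consecutive values are collapsed first, so
a flat summit or valley counts as a single extremum. Augmenting the extrema
with the window's first and last samples gives the swing sequence from which
five features are computed per sign:

* `f1` — number of trend changes (count of interior extrema);
* `f2`–`f5` — mean, median, minimum and maximum of the absolute differences
  between consecutive points of the augmented sequence (sign units).

Twenty features per patient (5 × 4 signs) feed a standard supervised
pipeline: per-model permutation importance, top-2-per-model merged feature
selection, a stratified 75/25 split, 10-fold cross-validated tuning, and
five classifiers (logistic regression; linear, RBF and polynomial SVMs with
sigmoid-mapped probabilities; a single-hidden-layer neural network).
Evaluation reports ROC and PR curves, AUC (trapezoid over the empirical
ROC, equal to the Mann–Whitney statistic with mid-ranks), AUC-PR, and the
0.5-threshold confusion metrics, with PPV/NPV reported as `NA` (never 0)
when no positive or negative calls exist. A *descriptive baseline* feature
set (per-sign mean, median, min, max, sd) is provided as the prior-work
comparator.

### Conventions the definitions leave open

* Intensity features use the **augmented** sequence. A symmetric triangular
  excursion 60→95→60 then yields `f1 = 1` and `f2 = f3 = f4 = f5 = 35`,
  matching the published worked example; intensities over interior extrema
  alone would be undefined for a single extremum.
* `f1` counts **interior** extrema only.
* A constant window scores `f1 = 0` and, via the augmented endpoints, a
  single zero swing, so `f2..f5 = 0`: a total-variation-zero series carries
  zero instability.
* The median of an even-length swing sequence is the midpoint average; the
  baseline sd uses the n−1 denominator.
* A predicted probability strictly above 0.5 is a sepsis call; exactly 0.5
  is a negative call.
* Ranking ties in feature selection break lexicographically by feature
  name; cross-validation ties in tuning resolve to the least complex grid
  point (lowest cost, then lowest kernel/architecture parameter).
* The RBF kernel is parameterized as `K = exp(−σ·r²)` (the form in which
  the reference optimum σ = 0.440227 was reported);
  `rbf_sigma_to_width()` converts to the bandwidth form
  `K = exp(−r²/(2s²))`.

## The synthetic cohort generator

The EMR records behind the published study are not publicly available, so
the package ships a generator whose *extracted-feature* distributions are
calibrated to the published per-group feature statistics
(`reference_group_stats()`: group means and sds of `f1`–`f5` per sign for
300 septic and 300 control patients).

Each simulated series is built mechanistically:

1. a Poisson number of turning points, with expected count
   `extrema_count_mean` per reference 8-h window, placed by stratified
   inverse-CDF sampling with a hard minimum spacing of 1.2 sampling gaps
   (turning points closer than one grid step partially cancel on the grid);
2. gamma-distributed swing magnitudes (`swing_magnitude_mean`/`_sd`)
   alternating up and down from a clinically typical baseline
   (MAP 75 mmHg, HR 80 bpm, RR 16 /min, TEMP 37.0 °C), folded into hard
   physiologic bounds;
3. linear resampling onto the 10-minute grid, i.i.d. Gaussian noise
   (default 5% of the swing mean — small enough that nominal turning
   points survive extraction instead of being swamped by noise-induced
   reversals), clipping to bounds, and rounding to the instrument
   resolution (1 mmHg, 1 bpm, 1 breath/min, 0.1 °C), which collapses
   sub-quantum noise into plateaus exactly as a monitor log does;
4. between-patient heterogeneity: a mean-one lognormal multiplier per
   window (log-sd `dispersion`, default derived from the published f1
   spreads, capped at 0.5) scales the turning-point rate and, independently,
   the swing scale.

**Septic ramp.** Control patients are simulated at constant control-level
instability, with `T0` placed 12 h after the simulated record begins.
Septic instability interpolates linearly from control level 12 h before
`T0` to full septic level 9 h before `T0`, remaining full thereafter
(`instability_ramp()`). The shape was chosen so that (a) the default
8-h/4-h window carries enough septic signal for the published group means
to be reachable by calibration, and (b) windows pushed away from `T0` by
longer prediction horizons overlap the ramp more and dilute the signal,
reproducing the reported direction of the horizon sweep (similar AUC at
horizons 1–4, a drop at 5). The published material does not describe the
temporal shape of pre-onset instability; this is the package's own
modelling choice. A corollary: the collection-interval sweep rises steeply
from very short windows but saturates once the window sits fully inside
the ramp (by `T ≈ 4` h), whereas the published sweep keeps rising to 8 h —
real pre-onset dynamics evidently accumulate signal over a longer span.

**Calibration** (`calibrate_generator()`) is damped multiplicative moment
matching, simulating windows through the same path the feature pipeline
uses (full-span record, ramp, slicing, extraction): the turning rate chases
the group-mean `f1`, the swing mean chases one intensity moment (`f2` by
default), and the swing spread chases the median `f3`. Respiratory rate
overrides the plan because its published minimum swing is the feature the
models select: septic RR matches (`f1`, `f2`, `f4`), control RR matches
(`f1`, `f4`) with the spread pinned at maximal concentration — its
published minimum swing (4.086) and median/mean (7.03/7.18) are not
simultaneously attainable for any gamma swing distribution, since a high
minimum requires concentration while the median demands spread. The cost,
which we accept and disclose, is that control-RR `f2`/`f3` run ~15% above
their published values; the four model-selected features
(`MAP_f1`, `RR_f1`, `RR_f4`, `HR_f3`) are matched within 2 standard errors
in both groups. Stabilizers: common random numbers across iterations,
per-iteration update factors capped to [0.6, 1.6], the swing mean capped
at one third of the physiologic range (beyond that the boundary fold makes
intensity moments non-monotone in the swing mean), and the noise level
frozen at its initial absolute value (tying it to the evolving swing mean
couples the updates into a runaway). Dispersion is *not* iterated: the
extraction's response to the patient multiplier is non-monotone (near-flat
windows gain noise extrema), which makes the published spreads — but not
the means — unreachable; see *Limitations*.

```{r calibrate-example}
cal <- calibrate_generator(seed = 1)
cal$diagnostics
cohort <- simulate_cohort(
  cohort_spec(n_septic = 300, n_control = 300, seed = 2),
  cal$septic_params, cal$control_params
)
features <- featurize_cohort(cohort)
group_stats(features)
```

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `T_hours` | h | 8 | reference collection interval of the published design |
| `horizon_hours` | h | 4 | reported best accuracy/practicality trade-off |
| `sampling_per_hour` | 1/h | 6 | 10-minute monitor logging |
| `n_septic`, `n_control` | patients | 300 + 300 | published cohort size (600 feature vectors) |
| `train_frac` | — | 0.75 | published 450/150 stratified split |
| `cv_folds` | — | 10 | published tuning protocol |
| `noise_sd` | sign units | 5% of swing mean | below the reversal threshold of the extractor |
| `dispersion` | log-sd | from published f1 sds, ≤ 0.5 | between-patient spread without destabilizing calibration |
| RBF grid | — | σ ∈ {0.1, 0.25, 0.440227, 1, 2}, C ∈ {0.25, 0.5, 1, 2} | brackets the reported optimum σ = 0.440227, C = 0.25 |
| poly grid | — | degree {2,3}, scale {0.01, 0.1, 1}, C as above | brackets degree 3, scale 0.1, C = 0.25 |
| ANN grid | — | size {3,5,7}, decay {0.01, 0.1, 0.5} | brackets 5 hidden units, decay 0.1; "hidden layers = 5" is read as one hidden layer of 5 units, the single-hidden-layer toolkit convention |

Feature standardization (z-score on training statistics) happens inside
every fit; kernel widths and weight decay are meaningless on raw scales.
In the phase-one selection fits, which run on all 20 features, the RBF
width uses the median pairwise-distance heuristic (`kernlab::sigest`)
instead of the 4-feature reference optimum, which would collapse the
kernel at 20 standardized dimensions.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish in minutes on one
CPU while keeping every comparison statistically meaningful: parameter
recovery calibrates all eight sign × group processes (400 windows per
iteration) and verifies a fresh 300 + 300 cohort; the property suites use
1000 random windows for the extraction oracle and 100–200 for the
algebraic invariants; the directional comparisons average 20 seeds of
60 + 60-patient cohorts. The acceptance script repeats calibration and a
300-patient septic simulation from a caller-supplied seed.

## Limitations

* **Means are calibrated; spreads are approximate.** The generator matches
  the published per-group feature *means* (and the four selected features
  within 2 SE in both groups), but its between-patient sds reach only
  about half the published values: pushing the lognormal dispersion higher
  makes near-flat windows accumulate noise extrema, raising the f1 mean
  while compressing its spread, so the published CVs of ~0.5–1 are
  structurally out of reach for this mechanism. Synthetic cohorts therefore
  separate more cleanly than the real one (classifier AUCs typically 0.85
  up to 1.0 depending on cohort size and dispersion, against the reported
  best of 0.8838), and all model-performance comparisons on synthetic data
  are structural/directional, never numeric reproductions of the published
  performance tables.
* **Signs are simulated independently.** The published material does not
  characterize within-patient cross-sign correlation, so none is imposed.
  One consequence: the published selection of the median heart-rate swing
  (`HR_f3`, whose marginal group separation is small) as a top feature
  presumably reflects multivariate structure in the real data that an
  independent-signs generator cannot reproduce, so the exact published
  four-feature selection is not asserted on generated cohorts.
* **The ramp shape is an assumption.** Only its direction (instability
  grows toward onset) has published support; timing (full from 9 h before
  `T0`) was set for calibration feasibility.
* **No waveform realism.** Ten-minute sampled values only; no beat-to-beat
  dynamics, no labs or SIRS-criteria channels, no missingness (patients
  with gaps are excluded, as in the source design).
* The uniform "<0.00001" p-values printed alongside the published group
  statistics are not reproducible by any standard two-sample test at
  n = 300 per group (several printed group means are nearly equal);
  `group_stats()` reports genuine Welch p-values and reproduces the
  table's structure, not those values.
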