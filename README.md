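# cardiowave

Classify the chronotropic drug exposure of spontaneously beating
cardiomyocytes from voltage-sensitive dye (VSD) line-scan recordings.

Clusters of stem-cell-derived cardiomyocytes (hiPS-CM) beat spontaneously;
a membrane-bound VSD reports each depolarization as a transient rise in
fluorescence. Scanning a single line across 1–5 cell membranes at
kilohertz rates produces a kymograph (lines × pixels) in which every beat
of every membrane is resolved. β-adrenergic drugs reshape the
depolarization waveform — isoproterenol (agonist) raises beat rate,
upstroke speed and peak height and narrows the waveform; propranolol
(antagonist) slows beating and widens it — and those shape changes are
enough to identify the exposure from single beats.

`cardiowave` implements the full measurement-and-classification pipeline:

1. **Membrane tracking** (`detect_membranes`, `track_membrane`) — each
   membrane's position is followed line-by-line with a least-squares
   Gaussian fit `F·exp(−(x−μ)²/2σ²) + offset`; the fitted amplitude `F`
   is the motion-corrected fluorescence readout.
2. **Photobleach correction** (`correct_photobleach`) — a
   double-exponential `a·e^{bt} + c·e^{dt}` (b, d ≤ 0) is fitted to the
   trace; the output is ΔF/F = (F − fit)/fit.
3. **Smoothing and beat metrics** (`smooth_trace`, `detect_beats`,
   `compute_metrics`) — a 50-line moving average, prominence-based peak
   detection, and per-beat extraction of the five waveform metrics:
   maximum height `h_max`, upslope `m_up` and downslope `m_down` (slopes
   at 50% of maximum height), width at half-maximum `w`, and plateau
   height `h_plateau` (height at the width midpoint), all relative to the
   flanking-trough baseline.
4. **Classification** (`stratified_split`, `train_forest`, `predict`,
   `reduce_model`, `aggregate_recording`) — a 50-tree bagged decision
   forest (bootstrap resamples, ⌈√p⌉ candidate features per split, fully
   grown trees) with the out-of-bag (OOB) error curve, standardized OOB
   permutation importance, importance-guided sequential feature removal,
   and recording-level majority-vote aggregation of per-waveform calls.
5. **Evaluation** (`confusion_report`, `roc_auc`, `group_stats`,
   `evaluate_predictions`) — confusion matrices, one-vs-rest ROC/AUC from
   the vote-fraction scores, pooled-variance t-tests, one-way ANOVA with
   Tukey HSD.

Because no recordings ship with the package, a first-class synthetic-data
module (`pulse_params`, `make_ap_pulse`, `simulate_feature_table`,
`simulate_recording`, `default_synth_config`) generates ground-truthed
feature tables and full kymographs — trapezoidal ΔF/F pulses with
closed-form metrics, hierarchical cell/beat variability, beat-coupled
membrane motion, double-exponential bleaching and configurable noise.

## Worked example

```r
library(cardiowave)

cfg <- default_synth_config()            # 457 waveforms: 145/100/212
tab <- simulate_feature_table(cfg, seed = 1)$features
sp  <- stratified_split(tab, fraction = 0.33, seed = 2)
model <- train_forest(sp$train, n_trees = 50, seed = 3)
round(model$importance, 2)
#>     h_max      m_up    m_down         w h_plateau
#>      0.34      2.12      1.15      3.33      0.30

red <- reduce_model(sp$train, sp$validation, seed = 3)
red$report[, c("step", "features", "oob_error", "val_accuracy")]
#>   step                      features oob_error val_accuracy
#> 1    0 h_max+m_up+m_down+w+h_plateau     0.132         86.3
#> 2    1                 m_up+m_down+w     0.139         85.9
#> 3    2                        m_up+w     0.159         84.0

report <- evaluate_predictions(predict(red$model, sp$validation))
report
#>                predicted
#> truth           control isoproterenol propranolol
#>   control            73            12          12
#>   isoproterenol      17           124           1
#>   propranolol         7             0          60
#> overall accuracy: 84.0%
#> AUC: control=0.917, isoproterenol=0.965, propranolol=0.965
#> recording-level accuracy: 97.9% (48 recordings)
```

The importance line shows the standardized OOB permutation importances of
the five metrics; features under 1 (`h_max`, `h_plateau` on this draw —
both are strongly redundant with the retained three) are removed in the
first reduction step, and further single-feature removals continue while
held-out accuracy stays within the 5-point stop margin. The confusion
matrix rows are true conditions; the commonest error is calling a control
waveform isoproterenol. Aggregating per-waveform votes over each
simulated recording lifts accuracy from 84% per waveform to 98% per
recording here.

The same pipeline runs end-to-end from raw kymographs (simulated or read
from TIFF) via `run_pipeline(config, seed)`; see the methods vignette
(`vignettes/cardiowave-methods.Rmd`) for the model, parameter and
calibration details.

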