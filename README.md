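# restmvpa

Cross-decoding analysis of resting-state fMRI: does spontaneous activity in
motor-related cortex contain multi-voxel patterns that resemble the patterns
evoked by discrete movements (wrist vs. finger)?

`restmvpa` implements the full analysis as a tested pipeline:

1. **Train** an L2-regularized logistic regression (RLR) decoder on
   block-design movement-task runs to discriminate wrist from finger
   movement, `P(y = Finger | x) = σ(xᵀw + b)`, and evaluate it by
   leave-one-session-out cross-validation.
2. **Cross-decode**: project each resting scan `x_t` onto the trained
   weights to obtain the task-relevancy index `RI_t = x_tᵀw + b`.  If
   resting activity contains task-similar components, the RI series is
   wider than a task-irrelevant projection, so the test statistic is its
   standard deviation, `SD_RS`.
3. **Null model**: build 1000 surrogate decoders by shuffling the weight
   vector with the iterative amplitude-adjusted Fourier transform (IAAFT),
   which keeps the weights' value distribution exactly and their spatial
   amplitude spectrum approximately.  Each surrogate yields a
   task-irrelevant spread `SD_IC`.
4. **Correct and test**:

   ```
   SD_RS ← SD_RS − (mean(SD_IC) + SD(SD_IC))
   SD_IC ← SD_IC − mean(SD_IC)
   ```

   The subject is flagged significant when the corrected `SD_RS` strictly
   exceeds the 50th-largest of the 1000 corrected `SD_IC` values
   (one-sided 5% empirical threshold).  The extra `−SD(SD_IC)` term makes
   the test conservative by construction.

Because suitable public data do not exist for this design, the package
ships a first-class synthetic-subject generator with known ground truth —
block-design task runs (18 s blocks, TR 3 s, 4 trials per class per
session, 102 scans/session), a 200-scan resting run built as a weighted
sum of task-relevant and task-irrelevant components, and realistic
nuisance processes (CSF/WM/global signal, six motion parameters) — plus
the temporal preprocessing the analysis assumes (nuisance regression with
`[N N′ N² N′²]` regressors, trend removal, 0.010–0.10 Hz fourth-order
zero-phase band-pass for resting runs).  A `load_real_run()` adapter reads
measured 4-D NIfTI volumes through an ROI mask.

## Worked example

```r
library(restmvpa)
cfg <- experiment_config(n_subjects = 3, seed = 42)
report <- run_experiment(cfg)
report
#> <experiment_report> 3 subjects; mean accuracy 87.5%; 3/3 significant
round(subset(report$subjects, select = -seed), 4)
#>   subject accuracy n_trials sd_rs_raw sd_rs_corrected critical_value
#> 1       1   0.9219       64    0.3900          0.2122         0.0298
#> 2       2   0.8750       64    0.3633          0.1974         0.0260
#> 3       3   0.8281       64    0.3291          0.1815         0.0249
#>   empirical_p significant
#> 1       0.001           1
#> 2       0.001           1
#> 3       0.001           1
```

Each simulated subject completes the whole pipeline: 8 task sessions are
generated and preprocessed, 64 trial patterns are extracted (8 per
session), the decoder reaches 83–92% leave-one-session-out accuracy
(chance is 50%), and the resting run — which here contains a genuine
task-relevant component (`rc_amplitude = 3`) — yields a corrected `SD_RS`
(≈ 0.18–0.21) far above the 5% critical value of its IAAFT null
(≈ 0.03), so all three subjects are flagged significant with empirical
p = 1/1001.  Setting `cfg$simulation$rc_amplitude <- 0` produces a null
world in which the significance rate stays at or below 5%.

`run_experiment(cfg, out_dir = "...")` additionally writes `summary.tsv`,
`report.json` (validated by `validate_report()` against the schema in
`inst/extdata/report-schema.json`) and optional weight maps.

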