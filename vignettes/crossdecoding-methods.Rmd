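---
title: "Cross-decoding resting-state fMRI: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-decoding resting-state fMRI: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the statistic

Resting-state BOLD activity is not noise: it appears to contain components
that echo task-evoked activation patterns.  `restmvpa` asks a sharp version
of that question for two neighbouring effectors with overlapping cortical
territory — wrist and finger movement: does spontaneous activity in a
motor ROI contain multi-voxel patterns similar to the ones that
discriminate those movements?

The analysis is a two-step cross-decoding procedure:

1. **Training step.**  A binary decoder is trained on movement-task runs
   to classify wrist vs. finger from single-trial voxel patterns, using
   L2-regularized logistic regression:
   $P(y=\text{Finger}\mid x) = \sigma(x^\top w + b)$, with
   $\sigma(z) = 1/(1+e^{-z})$ and penalty
   $\tfrac{\lambda}{2}\lVert w\rVert^2$ (bias unpenalized).  Finger is the
   positive class throughout: positive decoder output means finger-like.
   Decoder quality is measured by leave-one-session-out cross-validation
   and, across subjects, each ROI can be compared against a control ROI by
   a paired two-sided Wilcoxon signed-rank test with Bonferroni correction
   for the 8 ROIs tested.

2. **Extraction step.**  Each resting scan is projected onto the trained
   weights, giving the task-relevancy index $RI_t = x_t^\top w + b$.  The
   resting run is modelled as an additive mixture of task-relevant
   components (RCs — the wrist/finger patterns modulated by slow
   coefficients) and task-irrelevant components (ICs).  Under the pure-IC
   null the RI series stays close to the decision boundary; genuine RC
   content widens it.  The test statistic is therefore the sample standard
   deviation $SD_{RS}$ of the RI series.

The null distribution of the spread is built by replacing $w$ with IAAFT
surrogates (see below) 1000 times and recording each surrogate's RI
spread, $SD_{IC}$.  Projecting the data onto a shuffled weight vector is
equivalent to shuffling the data's voxels by the inverse arrangement, so
this is a voxel-arrangement null that keeps the weight value distribution
and its spatial amplitude spectrum while destroying the alignment between
weights and patterns.  Both spreads are then bias-corrected:

$$SD_{RS} \leftarrow SD_{RS} - \left(\mathrm{mean}(SD_{IC}) + \mathrm{SD}(SD_{IC})\right),
\qquad SD_{IC} \leftarrow SD_{IC} - \mathrm{mean}(SD_{IC}),$$

and the subject is flagged significant when the corrected $SD_{RS}$
strictly exceeds the $k$-th largest corrected null value with
$k = \mathrm{round}(\alpha n)$ (the 50th of 1000 at $\alpha = 0.05$).  The
empirical p-value uses the add-one convention $(\#\{SD_{IC} \ge SD_{RS}\}+1)/(n+1)$,
so it is never exactly zero.  Note the correction subtracts one null
standard deviation *beyond* centring; the test is therefore conservative
by construction, and the type-I calibration test asserts the one-sided
bound (rate at or below the binomial envelope of $\alpha$), not two-sided
equality.

## Why the RI behaves like a correlation

When a scan and the weight vector are both mean-centred and unit-normed,
$x^\top w$ *equals* the Pearson correlation between scan and weight map
(the $(n-1)$ and SD factors cancel exactly).  The pipeline unit-normalizes
every scan (task scans always; rest scans by default, controlled by
`normalize_scans`), mirroring the training-step normalization so task and
rest projections live on comparable scales.  The ground-truth patterns of
the generator are centred by construction, which keeps this
correlation reading close to exact on synthetic data.  $SD_{RS}$ is
invariant to the bias $b$, so including $b$ in the RI (we do) cannot
change any significance decision.

## The IAAFT surrogate and its fidelity

A surrogate must keep the multiset of weight values exactly — otherwise
the null confounds arrangement with amplitude — and preserve the spatial
amplitude spectrum so that smooth weight maps are compared against
equally smooth surrogates.  The iterative amplitude-adjusted Fourier
transform alternates (i) imposing the original DFT magnitudes on the
current sequence while keeping its phases with (ii) rank-remapping onto
the original values, until the rank order stabilizes (at most `max_iter`
iterations); the final step is always the rank remap, so the value
multiset is exact.

Fidelity is a property of the fixed points this iteration reaches.  At
vector length 256 with a pink (1/f power) spectrum, a single surrogate's
mean relative amplitude-spectrum error plateaus around 1–2% regardless of
initialization, restarts or post-hoc refinement — the residual is
intrinsic to rank-remapping at this length and shrinks with vector
length.  It is fluctuation, not bias: the mean spectrum of a surrogate
*ensemble* matches the input within a few tenths of a percent.  Since the
method consumes surrogates only as a 1000-member null ensemble, the
ensemble-level fidelity is the operative guarantee; the unit tests bound
the per-draw error at 2.5% and the ensemble error at 1%.  Each surrogate
records its iteration count and final spectrum error so convergence can
be audited per null distribution.

## Temporal preprocessing

The nuisance model follows the standard 36-parameter expansion: nine base
series (CSF, WM, global signal, six motion parameters), each contributing
itself, its temporal derivative, its square and its squared derivative.
Numerical conventions:

* **Derivative**: first difference with a leading zero (length
  preserved).  The scheme is not dictated by the design; any one-sided
  difference changes results negligibly after normalization.
* **"Maximum value 1" normalization**: division by the maximum *absolute*
  value, sign-preserving.  A signed maximum would flip or explode
  negative-dominated series; identically-zero columns stay zero.
* **Trend model**: constant plus linear ramp scaled to $[-1, 1]$.
* **Regression**: residuals via SVD pseudoinverse, so duplicated or
  collinear regressors are harmless (residuals are unique regardless of
  rank); the QR route is kept as an independent oracle in the tests.
* **Band-pass (resting runs only)**: fourth-order Butterworth, passband
  0.010–0.10 Hz, applied forward–backward (`filtfilt`) for zero phase;
  the effective power gain is the squared magnitude response.  Each
  series is demeaned before filtering — DC lies outside the passband, and
  removing it exactly avoids edge transients that the recursion would
  otherwise smear into the series.  At TR 3 s the design passes 0.05 Hz
  with gain > 0.99 and suppresses 0.15 Hz below $10^{-5}$.
* **Order for resting runs**: demean → filter → regress, with the
  nuisance regressors passed through the *same* band-pass (then
  re-normalized).  Regressing unfiltered nuisance against filtered data
  would reintroduce frequencies the filter removed.
* Task runs are regressed (noise + trend) but not band-pass filtered;
  the trial signal itself lives at block frequency and would be damaged.

One caveat a user of TR 3 s data should know: frequencies above the
0.167 Hz Nyquist do not exist in the sampled series — e.g. a 0.3 Hz
physiological signal aliases to 0.033 Hz, *inside* the passband — so the
band-pass cannot be expected to remove super-Nyquist artefacts.

## The synthetic-data generator

The generator exists so that every stage is testable against known ground
truth; its defaults encode the emulated study design.

| parameter | default | meaning |
|---|---|---|
| `tr_seconds` | 3 | sampling interval (s) |
| `block_seconds` | 18 | movement and rest block length (s) |
| `trials_per_class_per_session` | 4 | movement blocks per class |
| `n_sessions` | 8 | task sessions per subject |
| `rest_scans` | 200 | resting-run length |
| `n_voxels` | 200 | voxels per simulated ROI |
| `task_amplitude` | 1.5 | task-evoked pattern gain |
| `rc_amplitude` | 3 | resting task-relevant gain (0 = null world) |
| `noise_sd` | 1 | white scan noise SD |
| `pattern_overlap` | 0.1 | wrist/finger pattern correlation |
| `nuisance_gain` | 0.5 | nuisance-to-voxel coupling |

A task session is an initial rest block followed by eight movement blocks
(alternating classes, odd sessions starting with wrist) each followed by
rest: $17 \times 6 = 102$ scans.  Task signal is the class pattern scaled
by a canonical double-gamma HRF (peak 6 s, undershoot 16 s, peak
normalized to 1) convolved with the block boxcar; no GLM is fit anywhere
in the pipeline, so any plausible HRF serves.  The resting run is
$rc \cdot (a_w(t)\,p_w + a_f(t)\,p_f)$ plus white noise and nuisance
coupling, where $a_w, a_f$ are independent zero-mean, unit-variance
processes low-passed below 0.1 Hz (fourth-order Butterworth on white
noise, edges discarded) — the additive RC/IC mixture the statistic
assumes, with ≥ 95% of coefficient power inside the analysis passband.
Ground-truth patterns are zero-mean unit vectors whose correlation equals
`pattern_overlap` exactly by construction in the centred subspace.
Nuisance processes are plumbing, not physiology: slow
sinusoid-plus-noise for CSF/WM/GS and standardized random walks for the
six motion parameters, coupled into voxels through Gaussian loadings.

Realism constants were fixed once: `task_amplitude = 1.5` puts default
leave-one-session-out accuracy in the low-to-high 80s% — inside the range
a motor ROI achieves in practice and far from both chance and ceiling —
and `rc_amplitude = 3` gives rest scans a modest (~0.2) correlation with
the ground-truth patterns.  `rc_for_scan_correlation()` inverts the
generator's variance budget when a specific scan–pattern correlation is
wanted (e.g. ≈ 0.5 for power analyses); the inversion treats the slow
coefficients as unit-variance, so realized RMS correlations run slightly
below target.

What the generator does **not** emulate: 3-D anatomy (voxels are a flat
index; spatial weight maps are exported as flat arrays), scanner
artefacts, slice timing, motion-induced spatial shifts, physiological
aliasing, or a "common component" shared between task and rest — the
resting run contains only RC + IC + nuisance, so passing tests show the
statistic behaves correctly under the additive mixture model, not that
real resting data satisfy that model.

## Degenerate inputs and tie-breaks

* All-zero scans cannot be unit-normalized: error (they would otherwise
  silently poison trial averages).
* Prediction tie at probability exactly 0.5 → Wrist (fixed, arbitrary).
* Weight-map thresholding keeps `ceiling(fraction * n)` voxels; exact
  magnitude ties break by lowest voxel index.
* A tie between corrected $SD_{RS}$ and the critical value is *not*
  significant (strictly-greater rule).
* Constant weight vectors have a single arrangement: the IAAFT surrogate
  is the input itself.
* Identical paired samples in the ROI-vs-control comparison give p = 1
  rather than an error from the degenerate signed-rank statistic.

The decoder is fit by damped Newton iteration to gradient norm
$\le 10^{-8}$ by default (the convergence contract is $10^{-6}$); with a
positive penalty the objective is strictly convex, so separable toy
problems converge as reliably as noisy ones.  `glmnet`'s ridge logistic
path (with its $1/n$ loss scaling folded into $\lambda$) reproduces the
weights to $10^{-4}$ and serves as the independent oracle in the tests.

## Open design points, resolved

* **Group-level summary**: whether the group test should be per-subject,
  pooled, or on subject means is genuinely underdetermined.  The report
  keeps per-subject decisions as primary and exposes the per-subject
  corrected spreads so any aggregate can be formed; no single aggregate
  is labelled "the" result.
* **Bias in the RI**: the projection includes $b$; the spread statistic
  is shift-invariant, so the choice is cosmetic and documented rather
  than consequential.
* **Rest-scan normalization** before projection defaults to on, matching
  the task-scan treatment; it is a flag (`normalize_scans`) because the
  rationale is scale comparability, not a mathematical requirement.
* **Voxel ordering for IAAFT** is the flat voxel index order of the run;
  for real data `load_real_run()` records the mask's flat index order on
  the result so the arrangement is reproducible.

## Reproducibility and problem sizes

Every stochastic stage accepts a seed; `run_experiment()` derives
per-subject seeds from the master seed by a documented rule
(`subject_seed()`), so reports are byte-identical across runs.  The
validation suite exercises the pipeline at deliberately modest sizes —
200-voxel ROIs, 200-iteration nulls for the repeated-subject studies
(200 null-world subjects for type-I calibration, 50 subjects per
amplitude level for power and monotonicity), and full 1000-iteration
nulls where the threshold's order statistic itself is under test.  These
sizes keep each property estimable with useful precision while the whole
suite stays desk-scale; real analyses should use the full 1000-iteration
null, as the defaults do.

## Limitations

* The decoder is plain penalized logistic regression; the historical
  variational-Bayes RLR it stands in for would give numerically different
  weights (the cross-decoding logic is agnostic to this).
* The empirical null is the only supported inference; there is no
  parametric alternative and no FDR across ROIs (Bonferroni is applied
  only to the accuracy comparisons).
* Spatial preprocessing (realignment, slice timing, coregistration,
  normalization) is out of scope: `load_real_run()` expects volumes that
  are already spatially preprocessed and masked.
* The conservative correction trades type-I error for power; with weak
  task-relevant content the test under-rejects relative to nominal
  $\alpha$.
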