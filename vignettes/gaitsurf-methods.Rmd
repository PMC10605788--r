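---
title: "Methods: walking-surface classification with gaitsurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: walking-surface classification with gaitsurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling and numerical choices behind
`gaitsurf`. Code chunks are illustrative and not evaluated at build
time because several of them train networks for minutes.

## Problem setting

The task is 9-way classification of the surface being walked on — flat
even (`FE`), stairs up/down (`StrU`/`StrD`), slopes up/down
(`SlpU`/`SlpD`), grass (`GR`), banked left/right (`BnkL`/`BnkR`) and
cobblestone (`CS`) — from short windows of inertial data. Each trial
carries up to six sensors (wrist, right/left thigh, right/left shank,
trunk), each recording 22 channels at 100 Hz in seven signal groups:

```{r}
library(gaitsurf)
signal_groups()
```

The reference cohort design is 30 participants × 9 surfaces × 6
repeated trials (1,620 trials) of roughly 16 s each. That design is
encoded as the defaults of `sim_config()`; the examples below use
smaller cohorts for speed.

## Synthetic cohort simulator

No external recordings are bundled; `simulate_cohort()` produces
kinematically self-consistent trials so the entire pipeline is
testable offline.

Each trial draws a smooth orientation trajectory (yaw, pitch, roll)
around a per-participant baseline and derives every channel from it:

* `Acc` is gravity rotated into the body frame plus a gait oscillation
  at the trial's cadence (vertical) and half-cadence (lateral), plus
  noise; `FreeAcc` is the same signal minus the gravity projection
  (exact identity), and `VelInc` is `Acc / fs` (exact identity).
* `Gyr` is the analytic angular velocity of the Euler trajectory, so
  gyroscope and orientation channels are mutually consistent.
* `Mag` is the Earth field rotated into the body frame.
* `Ori` is a unit quaternion increment (unit-norm by construction) and
  `YPR` repeats the Euler angles, so orientation is available both in
  increment and absolute form.

Surfaces differ through an effects table (`default_surface_effects()`):
baseline pitch (slopes ±5°, stairs reinforced), baseline roll (banked
surfaces ∓8°), cadence factors (stairs slower), vertical amplitude
(stairs larger) and orientation jitter (cobblestone and grass noisier
than flat pavement). These values were fixed from gait-mechanics
reasoning before any classifier accuracy was measured and define the
emulated recording conditions; they are deliberately not tuned against
downstream results.

**Site gains.** All surface-dependent terms are scaled by a per-site
gain (`default_site_gain()`): shanks 1.0, thighs 0.6, trunk 0.4, wrist
0.05. Distal lower-limb segments express terrain mechanics most
strongly, while the wrist swings almost independently of foot–ground
interaction. Because every informative term scales with this gain, the
expected informativeness ordering of placements (shank > thigh > trunk
≫ wrist) is a structural property of the simulator, not an accident of
one random draw.

**Magnetic anomalies.** `sim_config(mag_surface_shift = s)` adds a
fixed, surface-specific offset to the world-frame magnetic field
(deterministic directions spread over the unit circle, magnitude `s`).
This emulates environment-specific magnetic disturbances — stairwells
and indoor corridors perturb the local field in ways open grass does
not — and provides a controlled "planted signal": with a degenerate
effects table (all surfaces kinematically identical) only the `Mag`
group carries class information, which the selection harness must then
recover. The default is 0 (off).

**Missingness.** `inject_missing()` marks a configurable number of
trials (default 14) as having one unusable sensor (left thigh by
default), stored as an all-`NA` matrix; `drop_unusable()` excludes such
trials when the affected sensor is required.

## Preprocessing

* **Smoothing:** zero-phase low-pass Butterworth (order 2, 6 Hz cutoff
  at 100 Hz) via `signal::filtfilt`, applied per channel. `filtfilt`
  zero-pads internally, which distorts edges; `butterworth_lowpass()`
  therefore mirror-pads each end with `min(n - 1, 100)` reflected
  samples first. Even reflection is used because odd reflection
  injects a step discontinuity whose low-frequency content survives
  the filter.
* **Missing-value repair:** `fill_missing()` carries the nearest
  preceding observation forward (`zoo::na.locf`), falling back to
  backward fill for leading gaps.
* **Segmentation:** non-overlapping windows of `L` samples;
  `floor(n / L)` windows per trial, remainder discarded.
* **Standardization:** per-channel min–max scaling to [0, 1]. The
  scaler is fit on the training folds only and applied unchanged to
  validation and test segments (values outside the training range may
  fall outside [0, 1]; they are not clipped). Fitting on anything that
  overlaps the test fold is treated as a hard error by the training
  harness.

## Fusion

`assemble_segments()` concatenates the chosen signal groups of the
chosen sensors column-wise into an `L × C` matrix per window, with a
canonical column order (group-major, then canonical sensor order, then
channel) so that the same configuration always yields the same layout
regardless of the order the user lists groups or sensors.

## Network

`build_surface_cnn()` constructs a 25-layer 1D CNN: five blocks of
convolution (kernel 3, stride 1, "same" padding) → ReLU → batch
normalization → max-pool (size 3, stride 3, ceil mode), with
64/64/128/128/128 filters, dropout (rate 0.5) after the last three
pools, then flatten and a 9-way softmax layer.

Ceil-mode pooling is load-bearing: it maps length 100 through
34 → 12 → 4 → 2 → 1, so the shortest standard window still reaches the
dense layer. `layer_manifest()` exposes the per-layer shapes and
`count_parameters()` the exact parameter count, which tests verify
against an independent closed form.

No deep-learning framework is available to this package, so forward,
backward and optimizer passes are written directly on BLAS matrix
products: a batch is held as a `(B·L) × C` matrix (time fastest), the
kernel-3 convolution is an im2col product of three row-shifted copies
against a stacked `(3·C_in) × C_out` weight, and pooling tracks argmax
indices for the backward pass. All gradients are verified against
central finite differences in the test suite.

Training (`train_config()`, `train_one_fold()`): Adam (learning rate
1e-3, β₁ 0.9, β₂ 0.999, ε 1e-7), batch size 32, sparse categorical
cross-entropy, early stopping on validation accuracy with best-weights
restore, and learning-rate reduction on plateau.

### Batch-norm momentum at small scale

Batch normalization keeps exponential running averages of activation
statistics for inference. With the conventional momentum default of
0.99 these averages have a time constant of roughly 100 optimizer
steps; at full cohort scale (thousands of steps) this is immaterial,
but a short run on a small cohort may finish with the running
statistics still far from the true batch statistics, so training-mode
accuracy looks fine while inference-mode accuracy sits at chance — and
best-weights restore then happily freezes an early epoch's garbage
statistics. The running statistics are stored with the weights, so
snapshots are at least internally consistent, but the cure for short
runs is a faster-converging average:

```{r}
cfg <- train_config(epochs = 18, patience_stop = 8, patience_lr = 4,
                    bn_momentum = 0.9, seed = 1)
```

Guidance: keep the default `bn_momentum = 0.99` when a fold sees on
the order of a thousand optimizer steps or more; use 0.9 for
desk-scale experiments (tens of trials, ≤ 20 epochs). This option
changes only how fast inference statistics track the data, never the
learned weights' objective.

## Evaluation

`make_fold_plan()` assigns whole trials to 6 folds, stratified so each
(participant, surface) pair contributes equally across folds — all
windows of a trial stay on one side of every split, preventing
within-trial leakage. `cross_validate()` rotates the test fold through
all six (validation = next fold, training = rest), fits the scaler per
rotation, trains per rotation with a fold-derived seed, and aggregates
all test predictions into one confusion matrix.

`per_class_metrics()` / `weighted_metrics()` report precision, recall,
F1 and accuracy with class weights equal to actual class counts (so
weighted recall equals accuracy identically — a useful invariant the
tests assert). A `paper_literal` flag swaps the row/column roles of
precision and recall to reproduce tables computed under the transposed
convention; F1 and accuracy are invariant under the swap.

## Wrapper selection

Two greedy searches share one injected evaluator so every candidate is
scored under identical folds and preprocessing:

* **Signal groups** (`greedy_signal_selection()`): classic forward
  selection — evaluate every remaining group added to the current set,
  accept the best only on *strict* improvement, stop otherwise. A full
  run from 7 groups that accepts five times therefore costs
  7 + 6 + 5 + 4 + 3 + 2 = 27 evaluations.
* **Sensors** (`greedy_sensor_selection()`): rank the six sites by
  single-sensor accuracy, then walk the ranking, keeping each site
  only on strict improvement. After the walk, if two or more sites
  were rejected, the current set augmented with *all* rejected sites
  is scored once as a full-complement check (accepted only on strict
  improvement); with exactly one rejected site that candidate would
  duplicate one already scored and is skipped. A typical run costs
  6 + 5 + 1 = 12 evaluations.

`window_sweep()` evaluates one configuration across window lengths
(100–500 samples by default). `make_holdout_evaluator()` provides a
cheap screening evaluator (one train/validation/test rotation) with
the same interface as the full cross-validation evaluator.

## Limitations

* The simulator is a structural emulation: it reproduces the
  *mechanics* that make surfaces separable (posture offsets, cadence,
  amplitude, jitter, field projections), not the full richness of real
  gait. Absolute accuracies on synthetic cohorts are therefore not
  comparable to accuracies on real recordings.
* The CNN runs on a single CPU through BLAS; full-scale cohorts train
  for hours. The package targets correctness and reproducibility, not
  training speed.
* The on-disk CSV format is self-describing but uncompressed; large
  cohorts are better kept in memory or regenerated from a seed.
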