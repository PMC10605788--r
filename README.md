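# gaitsurf

Classifying the surface a person is walking on — flat pavement, stairs
up/down, slopes up/down, grass, banked left/right, cobblestone — from
body-worn inertial measurement unit (IMU) recordings. Walking-surface
recognition is a building block of environment-aware fall-risk
assessment: the same gait pattern carries different risk on cobblestone
than on even pavement, so a wearable system should know the terrain
context it is observing.

The package implements the full experimental pipeline in plain R:

* **Data model** — 9 surface conditions, 6 sensor sites (wrist, both
  thighs, both shanks, trunk), 22 channels per sensor organised into 7
  signal groups (acceleration, free acceleration, rate of turn,
  magnetic field, velocity increment, orientation-increment
  quaternion, Euler angles).
* **Synthetic cohort simulator** — kinematically self-consistent
  multi-sensor gait trials (gravity and Earth-field projections through
  a common orientation trajectory, analytic gyroscope, exact
  strap-down identities), with surface-dependent posture, cadence and
  jitter effects. Everything in the package is runnable and testable
  without any external recordings.
* **Preprocessing** — zero-phase low-pass Butterworth smoothing,
  nearest-preceding missing-value repair, exclusion of trials with
  unusable required sensors, non-overlapping windowing, per-fold
  min-max standardization.
* **Model** — a 25-layer 1D convolutional network (five
  conv–ReLU–batchnorm–maxpool blocks with 64/64/128/128/128 filters,
  dropout after the last three pools, softmax output), implemented
  directly on BLAS matrix products with hand-written backpropagation
  and Adam — no deep-learning framework required.
* **Evaluation** — trial-stratified 6-fold cross-validation with
  aggregated predictions, weighted precision/recall/F1/accuracy.
* **Wrapper selection** — greedy forward selection over signal groups,
  ranked greedy selection over sensor placements, and a window-length
  sweep, all driven by an injectable evaluator.

## Quick start

```r
library(gaitsurf)

# a small synthetic cohort: 3 participants x 9 surfaces x 2 trials
ds <- simulate_cohort(sim_config(n_participants = 3,
                                 trials_per_condition = 2))
ds
#> <gait_dataset> 54 trials (synthetic)

ds <- preprocess_dataset(ds)

# fuse all signal groups of the two shank sensors into 1-second windows
set <- assemble_segments(ds, names(signal_groups()),
                         c("shankR", "shankL"), window_length = 100)
set
#> <segment_set> 486 segments of 100 x 44

# the network
model <- build_surface_cnn(100, 44, seed = 1)
model
#> <surface_cnn> input 100 x 44 -> 9 classes; 153377 parameters (untrained)
head(layer_manifest(model), 4)
#>   layer block       kind output_length output_channels
#> 1     1     1     conv1d           100              64
#> 2     2     1       relu           100              64
#> 3     3     1 batch_norm           100              64
#> 4     4     1 max_pool1d            34              64

# trial-stratified 6-fold cross-validation (a few minutes on one CPU)
cfg <- train_config(epochs = 18, patience_stop = 8, patience_lr = 4,
                    bn_momentum = 0.9, seed = 1)
cv <- cross_validate(ds, names(signal_groups()), c("shankR", "shankL"),
                     100, config = cfg, preprocess = FALSE)
cv_metrics(cv)$accuracy
```

Wrapper searches reuse one preprocessed dataset and one fold plan so
candidate configurations are compared on identical terms:

```r
ev <- make_cv_evaluator(ds, config = cfg, preprocess = FALSE)
sel <- greedy_signal_selection(sensors = c("shankR", "shankL"),
                               window_length = 100, evaluator = ev)
sel$selected
```

For quick screening, `make_holdout_evaluator()` scores each candidate
on a single train/validation/test rotation instead of all six.

## Notes on scale

The emulated full study design (30 participants × 9 surfaces × 6
trials, ~16 s at 100 Hz) produces ~1,600 trials and hours of training;
the defaults of `sim_config()` encode that design. Examples, tests and
the acceptance script run scaled-down cohorts (2–6 participants) that
finish in minutes while exercising every stage of the pipeline. The
`bn_momentum` option of `train_config()` exists for exactly this
scaling: batch-norm running statistics need hundreds of optimizer steps
at the 0.99 default, so short runs should lower it (0.9 works well).

## License

MIT (see `LICENSE`).
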