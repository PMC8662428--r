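---
title: "Identifying users from partial gait data with a stacked LSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying users from partial gait data with a stacked LSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Gait is a usable biometric: people differ in cadence, stride length and the
acceleration waveforms their feet produce while walking. Classical
identification pipelines first segment a walking record into individual
steps (via pressure peaks or gait-event detection) and then classify
per-step features. Segmentation becomes the weak point whenever only
*partial* data are available -- a fragment shorter than one complete step
cannot be segmented at all.

`gaitid` implements a segmentation-free alternative. The classifier is a
two-layer stacked LSTM that consumes a raw window of bilateral smart-insole
accelerometry -- six channels (`xL, yL, zL, xR, yR, zR`) at 30 Hz -- of *any*
length, and emits a softmax distribution over users. The trick is entirely
in how training data are constructed: windows are drawn with a random size
(20 to 200 samples, i.e. 0.67 s to 6.67 s) at a random location within each
walk, so one set of weights learns to identify users from fragments of every
admissible length and phase. No step detection, gait-cycle analysis, or
alignment is needed at training or inference time.

## The model

Input is a `T x 6` window, `20 <= T <= 200` during training (any `T >= 1`
at inference). The architecture is fixed:

* LSTM layer 1: 64 units, returns the full output sequence (`T x 64`),
  recurrent dropout 0.2;
* LSTM layer 2: 64 units, returns its last output (a 64-vector),
  recurrent dropout 0.2;
* dropout 0.5 on the 64-vector;
* dense layer to `n` units with softmax, `n` = number of users.

Training minimizes categorical cross-entropy with Adam (learning rate
`1e-3`), the de facto defaults for this architecture family; both are
exposed in `model_config()`. Recurrent dropout is variational: one
Bernoulli mask per sequence is applied to the hidden state entering the
recurrent transition, constant across time steps. All dropout is disabled
at inference.

The forward pass and full backpropagation-through-time are implemented in
C++ (RcppArmadillo); the test suite verifies the analytic gradients against
central finite differences. Weight initialization is deterministic per
seed: Glorot-uniform input kernels, per-gate orthogonal recurrent kernels,
zero biases with forget-gate biases at 1.

### Batch construction for variable lengths

Every mini-batch uses a single window size `T`, drawn uniformly from
`[20, 200]`; the batch's 32 windows then come from uniformly chosen
training recordings at uniform random starts. This keeps tensors
rectangular (no padding or masking, which would fabricate signal at the
sequence tails) while still exposing the model to all sizes -- `T` varies
batch to batch. An epoch is `windows_per_epoch` windows (default 2048,
i.e. 64 batches).

### Desk scale versus full scale

The full-scale protocol (the `"full"` profile of `run_config()`) uses 1000
epochs of 36828 windows and 5 repeats of five-fold cross-validation --
appropriate for a real 16-subject study, far beyond what a package check
should run. The `"desk"` profile keeps the same architecture and data
protocol but trains 30 epochs of 2048 windows with a single
cross-validation repeat; on the default synthetic population this reaches
~99% training accuracy and >95% held-out window accuracy at `T = 200` in
about three minutes on one CPU. All tests and the worked examples use desk
scale; the full profile is expressible but never required.

## Normalization

Each recording is z-scored per channel over its own samples
(`normalize_recording()`), before any windowing. Per-recording (rather than
pooled-training-set) statistics were chosen because they make inference
self-contained -- a deployed classifier sees one recording at a time -- and
leak no statistics across cross-validation folds. A pooled variant would
be a one-line change; with simulated amplitudes the two differ little
because the generator already produces roughly unit-scale signals. A
constant (zero-variance) channel has no z-score; it raises an error naming
the channel rather than silently producing NaNs.

## The synthetic-data generator

The real study population (16 subjects, 10 walks of 10 m each) is private,
so the package ships a generator whose *defaults are the study conditions*:
16 users, 10 trials, 30 Hz, six channels, recording lengths inside the
observed 216-290 sample envelope (walks of 7.2-9.6 s).

Each user is a `gait_profile`:

| parameter | default draw | rationale |
|---|---|---|
| walking speed | U(10/9.6, 10/7.2) m/s | exactly spans the observed 7.2-9.6 s range of a 10 m walk |
| stride frequency | U(0.8, 1.1) Hz | normal-walking cadence range |
| harmonic amplitudes | U(0.3, 1.0) x h^-0.7, 3 axes x 4 harmonics | decaying harmonic spectrum; units arbitrary since data are z-scored downstream (no gravity offset modeled for the same reason) |
| harmonic phases | U(0, 2pi) | unconstrained |
| left/right offset | U(0.45, 0.55) stride periods | near anti-phase gait |
| noise sd | 0.3 | moderate sensor + biomechanical noise relative to O(1) amplitudes |

A trial is the harmonic sum at the jittered stride frequency, with the
right-foot channel of each axis being the left-foot waveform delayed by
`left_right_offset` stride periods, plus white Gaussian noise. Harmonic
parameters are stored per axis and shared between feet so that the
left/right relationship is an exact time shift -- this is what makes the
anti-phase property testable by an exhaustive cross-correlation oracle.
Trial-to-trial jitter multiplies cadence by N(1, 0.02) truncated to
[0.94, 1.06] and amplitudes by N(1, 0.05) truncated positive, and shifts
the global phase uniformly; the magnitudes are our invention (within-user
variability beyond length differences is not characterized anywhere) and
are exposed as tunables.

The recording length obeys `L = round(30 * distance / v)` where `v` is the
jittered walking speed clamped to the admissible band -- the clamp keeps
every default trial inside the 216-290 envelope while preserving an exact,
testable length law.

The `separation` dial exists for falsification: `"high"` places users on a
deterministic cadence/amplitude grid (with zero noise, nearest-centroid
classification on power spectra is perfect -- the upper-bound control);
`"low"` gives every user the same parameter point, so no classifier can
beat chance in expectation (the negative control used by the chance-level
acceptance check).

What the generator does *not* emulate: biomechanical waveform shapes
(heel-strike transients, swing asymmetries), sensor drift and saturation,
speed variation within a walk, or any pressure/gyroscope channels. Passing
tests therefore show that the pipeline learns and evaluates
user-distinguishing periodic structure under realistic lengths, noise and
trial variability -- not that it reproduces accuracies measured on real
insole data.

## Evaluation protocol

Recordings (whole walks) are the cross-validation unit. `make_folds()`
permutes each user's trials and partitions them into five equal blocks:
every fold tests 2 trials per user (32 recordings) and trains on the
remaining 128. `cross_validated_report()` repeats the shuffle-and-split
(independent seeded shufflings) and averages over all fold x repeat runs.

Accuracy is per-window: for each test recording and each window size
`T in {20, 30, 50, 100, 150, 200}`, `k = 10` windows are extracted at
random starts (the placement rule for evaluation windows is not pinned
down anywhere, so random placement with a fixed evaluation seed was chosen
as the stable estimator; `k` is exposed). A window counts as correct when
the softmax argmax equals the true user. Per-recording majority voting is
deliberately not the default -- the reported quantity is a *single-window*
identification rate, which is the harder and more informative claim for
partial-data identification. The data-rate analysis is the same mechanics
at sizes 42/63/84, labeled by the fraction of a full walk they represent
(26/39/52%); the percentages are labels only, since the denominator behind
them is not reconstructible from any stated recording length.

Recordings shorter than a requested size are excluded from that cell (with
a reported count) rather than padded; padding would fabricate signal. In
the shipped configuration this never triggers, as all recordings have
at least 216 samples and the largest evaluated window is 200.

Reported durations round *up* at the second decimal
(`window_seconds()`: a 100-sample window at 30 Hz spans just over 3.33 s
and is reported as 3.34 s), so a printed duration never understates the
span of the window it describes.

## Numerical choices and degenerate inputs

* Ties in the softmax argmax break toward the lowest class index
  (`which.max`); with continuous weights ties have measure zero.
* Cross-entropy clamps probabilities at `1e-12` before the log.
* All randomness flows through R's RNG under seeds derived from one master
  seed per independent stream (profiles, per-trial jitter, fold shuffles,
  weight init, per-epoch window draws, dropout masks, evaluation
  placement), so every result in a report is bit-reproducible from its
  recorded seeds, and generating trial `(u, t)` does not depend on how many
  trials were generated before it.
* `epochs = 0` is a valid configuration returning the initialized model --
  useful as the untrained baseline.
* A recording shorter than `t_min` cannot be sampled and raises an error;
  window sizes are capped at the recording length (`T` uniform on
  `[t_min, min(t_max, L)]`), which matters only if recordings shorter than
  200 samples are supplied.

## Known limitations

* The harmonic generator is a statistical stand-in, not a biomechanical
  simulation; absolute accuracies on it say nothing quantitative about real
  insole data.
* Training is plain BPTT over up-to-200-step sequences on one CPU; the
  full-scale profile (1000 epochs) is hours of compute, by design not part
  of any test.
* The per-epoch "total amount of data" of the full-scale protocol is
  ambiguous in its source; `windows_per_epoch` makes the choice explicit
  rather than replicating an unreconstructible number.
* Only accelerometer channels are modeled and consumed; pressure and
  gyroscope channels, walking-speed robustness and cross-session drift are
  out of scope.
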