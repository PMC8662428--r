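# gaitid

Segmentation-free gait-based user identification from bilateral smart-insole
accelerometry.

## What it does

People can be identified from how they walk. Conventional gait-biometric
pipelines first cut a walking record into individual steps and classify
per-step features, which fails outright on *partial* data — a fragment too
short to contain a complete step. `gaitid` implements the alternative:

* a **two-layer stacked LSTM** — LSTM(64, full sequence, recurrent dropout
  0.2) → LSTM(64, last output, recurrent dropout 0.2) → dropout 0.5 →
  dense(*n*) softmax over *n* users — that accepts a raw `T × 6` window of
  insole accelerometer channels (`xL, yL, zL, xR, yR, zR`, 30 Hz) of **any
  length**;
* **random-window training**: windows of uniformly random size
  `T ∈ [20, 200]` (0.67–6.67 s) at uniformly random locations, so a single
  trained model identifies users from fragments of every admissible length
  — no step detection, segmentation or alignment anywhere;
* per-channel, per-recording **z-score normalization**;
* the **evaluation protocol**: stratified five-fold cross-validation over
  whole walks (2 test walks per user per fold), repeated with reshuffling,
  reporting per-window identification rates by test window size
  ({20, 30, 50, 100, 150, 200} samples) and by data rate (windows of
  42/63/84 samples ≈ 26/39/52 % of a full walk);
* a **synthetic dataset generator** emulating the kind of private study
  data such methods are evaluated on: 16 users × 10 walks of 10 m,
  recording lengths 216–290 samples, per-user quasi-periodic harmonic gait
  signatures with left/right anti-phase, trial jitter and sensor noise —
  with `separation = "high"` / `"low"` dials providing perfect-separability
  and chance-level controls.

The LSTM forward pass and full backpropagation-through-time are implemented
in C++ (RcppArmadillo) and verified against finite differences in the test
suite.

## Worked example

Simulate a 16-user population, train on one cross-validation fold
(128 walks), and score the held-out 32 walks (about 3 minutes on one CPU):

```r
library(gaitid)

profiles   <- sample_profiles(16, rng_seed = 101)
recordings <- lapply(generate_dataset(profiles, n_trials = 10, rng_seed = 101),
                     normalize_recording)

folds <- make_folds(recordings, n_folds = 5, rng_seed = 102)
ids   <- vapply(recordings, `[[`, character(1), "recording_id")
train <- recordings[ids %in% folds[[1]]$train_ids]
test  <- recordings[ids %in% folds[[1]]$test_ids]

model <- train_model(build_model(model_config(n_classes = 16, epochs = 30,
                                              rng_seed = 103)), train)
evaluate_by_window_size(model, test, rng_seed = 104)
```

```
 window_size seconds n_windows n_excluded accuracy
          20    0.67       320          0  94.6875
          30    1.00       320          0  99.6875
          50    1.67       320          0 100.0000
         100    3.34       320          0 100.0000
         150    5.00       320          0 100.0000
         200    6.67       320          0 100.0000
```

Each row: 10 windows of the given size were cut at random positions from
each of the 32 held-out walks (320 windows) and classified independently;
`accuracy` is the percentage whose softmax argmax named the true user. The
signature trend of the method is visible: even 0.67 s fragments — far less
than one step — identify the right user 94.7 % of the time, and accuracy
climbs toward 100 % as the window grows. The data-rate analysis
(`evaluate_by_data_rate(model, test, rng_seed = 104)`) evaluates the same
model at 42/63/84-sample windows and showed 99.7/100/100 % here.

`cross_validated_report()` wraps the whole protocol (all folds × repeats)
and `write_report()` renders it as JSON plus the two CSV accuracy tables.
A command-line wrapper with `simulate` / `run` / `evaluate` / `report`
subcommands ships in `inst/cli/gaitid.R`.

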