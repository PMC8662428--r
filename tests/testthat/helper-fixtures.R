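# Shared fixtures, built once per test session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small separable dataset: 4 users x 5 trials, high separation, low noise.
tiny_dataset <- function() {
  memo("tiny", {
    profs <- sample_profiles(4, rng_seed = 11, separation = "high",
                             noise_sd = 0.05)
    lapply(generate_dataset(profs, n_trials = 5, rng_seed = 11),
           normalize_recording)
  })
}

# A briefly trained model on the tiny dataset (separable; a handful of
# epochs is enough to be well above chance).
tiny_model <- function() {
  memo("tiny_model", {
    cfg <- model_config(n_classes = 4, epochs = 8, windows_per_epoch = 256,
                        batch_size = 16, rng_seed = 5)
    train_model(build_model(cfg), tiny_dataset())
  })
}

# Desk-scale run shared by the acceptance trend checks: 16 default-separation
# users, 10 trials, train on fold 1 (128 recordings), 30 epochs.
desk_run <- function() {
  memo("desk", {
    profs <- sample_profiles(16, rng_seed = 101, separation = "default")
    recs <- lapply(generate_dataset(profs, n_trials = 10, rng_seed = 101),
                   normalize_recording)
    folds <- make_folds(recs, n_folds = 5, rng_seed = 102)
    ids <- vapply(recs, `[[`, character(1), "recording_id")
    cfg <- model_config(n_classes = 16, epochs = 30, rng_seed = 103)
    model <- train_model(build_model(cfg),
                         recs[ids %in% folds[[1]]$train_ids])
    list(model = model,
         test = recs[ids %in% folds[[1]]$test_ids],
         recordings = recs)
  })
}

# Circular cross-correlation argmax lag (brute force over all lags), after
# truncating to a whole number of periods.
xcorr_peak_lag <- function(a, b, period) {
  n <- floor(length(a) / period) * period
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  cors <- vapply(seq_len(period) - 1L, function(lag) {
    sum(a * b[((seq_len(n) - 1L + lag) %% n) + 1L])
  }, numeric(1))
  which.max(cors) - 1L
}
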