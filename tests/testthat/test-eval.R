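# Cross-validation protocol and the accuracy analyses.

test_that("stratified folds partition the dataset, 2 test trials per user", {
  recs <- lapply(generate_dataset(sample_profiles(16, rng_seed = 1), 10,
                                  rng_seed = 1), identity)
  folds <- make_folds(recs, n_folds = 5, rng_seed = 4)
  ids <- vapply(recs, `[[`, character(1), "recording_id")
  users <- setNames(vapply(recs, `[[`, integer(1), "user_id"), ids)
  all_test <- character(0)
  for (f in folds) {
    expect_length(f$test_ids, 32)
    expect_length(f$train_ids, 128)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_true(all(table(users[f$test_ids]) == 2))
    all_test <- c(all_test, f$test_ids)
  }
  expect_setequal(all_test, ids)
  expect_identical(anyDuplicated(all_test), 0L)
})

test_that("fold invariants hold across many seeds; edge and error cases", {
  recs <- tiny_dataset()  # 4 users x 5 trials
  ids <- vapply(recs, `[[`, character(1), "recording_id")
  for (seed in 1:100) {
    folds <- make_folds(recs, n_folds = 5, rng_seed = seed)
    test_sets <- unlist(lapply(folds, `[[`, "test_ids"))
    expect_setequal(test_sets, ids)
    expect_true(all(lengths(lapply(folds, `[[`, "test_ids")) == 4))
  }
  # one user, five trials, five folds: one test trial per fold
  one <- recs[vapply(recs, `[[`, integer(1), "user_id") == 0]
  folds <- make_folds(one, n_folds = 5, rng_seed = 1)
  expect_true(all(lengths(lapply(folds, `[[`, "test_ids")) == 1))
  # indivisible trial count names the user
  expect_error(make_folds(recs[-1], n_folds = 5, rng_seed = 1), "user 0")
})

test_that("window durations round up at the second decimal", {
  expect_identical(window_seconds(c(20, 30, 50, 100, 150, 200)),
                   c(0.67, 1.00, 1.67, 3.34, 5.00, 6.67))
  expect_identical(window_seconds(3), 0.10)  # guard against FP ceiling slips
  expect_identical(window_seconds(42), 1.40)
})

test_that("a well-trained model on separable data scores near-perfectly", {
  m <- tiny_model()
  recs <- tiny_dataset()
  ws <- evaluate_by_window_size(m, recs, sizes = c(50L, 150L), k = 5,
                                rng_seed = 6)
  expect_identical(ws$n_windows, c(100L, 100L))
  expect_identical(ws$n_excluded, c(0L, 0L))
  expect_true(all(ws$accuracy >= 90))  # 4 separable users, trained model
})

test_that("an untrained model scores near chance and sizes can exclude", {
  recs <- tiny_dataset()
  m0 <- build_model(model_config(n_classes = 4, rng_seed = 17))
  m0$classes <- 0:3
  ws <- evaluate_by_window_size(m0, recs, sizes = c(20L, 100L), k = 25,
                                rng_seed = 7)
  expect_true(all(abs(ws$accuracy - 25) < 12))  # 1/4 chance, 500 windows
  # a size longer than every recording is reported missing, not an error
  expect_warning(
    long <- evaluate_by_window_size(m0, recs, sizes = 1000L, k = 2,
                                    rng_seed = 7),
    "no recording long enough")
  expect_true(is.na(long$accuracy))
  expect_identical(long$n_excluded, length(recs))
})

test_that("data-rate analysis keys cells by rate label over fixed sizes", {
  m <- tiny_model()
  dr <- evaluate_by_data_rate(m, tiny_dataset(), k = 3, rng_seed = 8)
  expect_identical(dr$data_rate, c(26, 39, 52))
  expect_identical(dr$window_size, c(42L, 63L, 84L))
  expect_true(all(dr$window_size >= 20 & dr$window_size <= 200))
  expect_true(all(dr$accuracy >= 0 & dr$accuracy <= 100))
})

test_that("cross-validated report tests every recording once per analysis", {
  recs <- tiny_dataset()
  cfg <- model_config(n_classes = 4, epochs = 1, windows_per_epoch = 64,
                      batch_size = 16, rng_seed = 5)
  rep1 <- cross_validated_report(recs, cfg, n_repeats = 1, n_folds = 5,
                                 sizes = c(30L, 120L), k = 4, rng_seed = 9)
  # 5 folds x 4 test recordings x 4 windows = 80 windows per size cell
  expect_identical(rep1$by_window_size$n_windows, c(80L, 80L))
  expect_identical(rep1$by_window_size$n_runs, c(5L, 5L))
  expect_true(all(rep1$by_window_size$mean_accuracy >= 0 &
                  rep1$by_window_size$mean_accuracy <= 100))
  expect_true(all(rep1$by_data_rate$mean_accuracy >= 0 &
                  rep1$by_data_rate$mean_accuracy <= 100))
  expect_identical(rep1$by_data_rate$data_rate, c(26, 39, 52))
  # seconds column accompanies the window-size table
  expect_identical(rep1$by_window_size$seconds, window_seconds(c(30, 120)))
})

test_that("reports serialize with a reproducibility block", {
  recs <- tiny_dataset()
  cfg <- model_config(n_classes = 4, epochs = 1, windows_per_epoch = 32,
                      batch_size = 16, rng_seed = 5)
  rep1 <- cross_validated_report(recs, cfg, n_repeats = 1, n_folds = 5,
                                 sizes = 50L, k = 2, rng_seed = 10)
  dir <- withr::local_tempdir()
  paths <- write_report(rep1, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_identical(js$reproducibility$seeds$master, 10L)
  expect_match(js$reproducibility$config_hash, "^[0-9a-f]{8}$")
  tab <- data.table::fread(paths[["window_size"]])
  expect_identical(nrow(tab), 1L)
})
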