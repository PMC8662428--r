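# Cross-validation protocol and the window-size / data-rate accuracy
# analyses.  Recordings (whole walks) are the unit of splitting: per user,
# trials are permuted and partitioned into equal fold blocks, so with 16
# users x 10 trials every fold holds 32 test and 128 training recordings
# (2 test trials per user).  Accuracy is per-window: each extracted test
# window counts as one identification attempt.

#' Stratified fold assignment
#'
#' Per-user random permutation of trials, partitioned into `n_folds` equal
#' blocks; fold i's test set is block i of every user.  Deterministic given
#' the seed.
#'
#' @param recordings List of [accel_recording()].
#' @param n_folds Number of folds (default 5).
#' @param rng_seed Integer seed.
#' @return List of `n_folds` `fold_split` objects with fields `fold_index`
#'   (0-based), `train_ids`, `test_ids`.
#' @export
make_folds <- function(recordings, n_folds = 5L, rng_seed = 1L) {
  ids <- vapply(recordings, `[[`, character(1), "recording_id")
  users <- vapply(recordings, `[[`, integer(1), "user_id")
  if (anyDuplicated(ids)) stop("duplicate recording ids", call. = FALSE)
  by_user <- split(ids, users)
  for (u in names(by_user)) {
    if (length(by_user[[u]]) %% n_folds != 0L) {
      stop(sprintf(
        "user %s has %d trials, not divisible by %d folds",
        u, length(by_user[[u]]), n_folds), call. = FALSE)
    }
  }
  assign_fold <- withr::with_seed(derive_seed(rng_seed, "folds", 0L), {
    out <- character(0)
    fold_of <- integer(0)
    for (u in names(by_user)) {
      perm <- sample(by_user[[u]])
      k <- length(perm) / n_folds
      out <- c(out, perm)
      fold_of <- c(fold_of, rep(seq_len(n_folds) - 1L, each = k))
    }
    stats::setNames(fold_of, out)
  })
  lapply(seq_len(n_folds) - 1L, function(f) {
    test <- names(assign_fold)[assign_fold == f]
    structure(list(fold_index = f,
                   train_ids = setdiff(ids, test),
                   test_ids = test),
              class = "fold_split")
  })
}

#' Seconds spanned by a window of T samples at 30 Hz
#'
#' Durations are rounded up at the second decimal (a window of 100 samples
#' spans slightly more than 3.33 s, reported as 3.34 s).
#'
#' @param T Window size(s) in samples.
#' @return Duration(s) in seconds at 2 decimals.
#' @export
window_seconds <- function(T) {
  ceiling(round(T * 100 / SAMPLE_RATE, 6)) / 100
}

# Shared mechanics of both accuracy analyses: k fixed-size windows per
# eligible test recording, per-window argmax accuracy in percent.
accuracy_for_sizes <- function(model, recordings, sizes, k, rng_seed) {
  lens <- vapply(recordings, recording_length, integer(1))
  rows <- withr::with_seed(derive_seed(rng_seed, "eval", 0L), {
    lapply(sizes, function(T) {
      eligible <- which(lens >= T)
      if (!length(eligible)) {
        warning(sprintf("no recording long enough for window size %d", T))
        return(data.frame(window_size = T, n_windows = 0L,
                          n_excluded = length(recordings),
                          accuracy = NA_real_))
      }
      wins <- unlist(lapply(recordings[eligible], extract_test_windows,
                            T = T, k = k), recursive = FALSE)
      truth <- vapply(wins, `[[`, integer(1), "user_id")
      pred <- predict(model, wins, type = "class")
      data.frame(window_size = T, n_windows = length(wins),
                 n_excluded = length(recordings) - length(eligible),
                 accuracy = 100 * mean(pred == truth))
    })
  })
  do.call(rbind, rows)
}

#' Identification accuracy by test window size
#'
#' For each size T, k windows are extracted at random locations from every
#' eligible test recording (recordings shorter than T are excluded for that
#' size, with the count reported) and scored by the trained model; accuracy
#' is the percentage of windows whose predicted user matches the truth.
#'
#' @param model Trained `gait_lstm`.
#' @param recordings Normalized test recordings.
#' @param sizes Window sizes in samples (default the six evaluation sizes
#'   20, 30, 50, 100, 150, 200).
#' @param k Windows per recording per size (default 10).
#' @param rng_seed Seed for window placement.
#' @return `data.frame` with columns `window_size`, `seconds`, `n_windows`,
#'   `n_excluded`, `accuracy` (percent).
#' @export
evaluate_by_window_size <- function(model, recordings,
                                    sizes = c(20L, 30L, 50L, 100L, 150L, 200L),
                                    k = 10L, rng_seed = 1L) {
  out <- accuracy_for_sizes(model, recordings, sizes, k, rng_seed)
  cbind(out[, "window_size", drop = FALSE],
        seconds = window_seconds(out$window_size),
        out[, c("n_windows", "n_excluded", "accuracy")])
}

#' Identification accuracy by data rate
#'
#' Same mechanics as [evaluate_by_window_size()] at the three fixed sizes 42,
#' 63 and 84 samples, reported under their data-rate labels (26, 39, 52% of
#' a full walk).  The rate labels are labels only; the evaluation uses the
#' literal window sizes.
#'
#' @inheritParams evaluate_by_window_size
#' @param window_sizes Sizes in samples (default 42, 63, 84).
#' @param rate_labels Matching data-rate percentages (default 26, 39, 52).
#' @return `data.frame` with columns `data_rate`, `window_size`, `n_windows`,
#'   `n_excluded`, `accuracy` (percent).
#' @export
evaluate_by_data_rate <- function(model, recordings,
                                  window_sizes = c(42L, 63L, 84L),
                                  rate_labels = c(26, 39, 52),
                                  k = 10L, rng_seed = 1L) {
  stopifnot(length(window_sizes) == length(rate_labels))
  out <- accuracy_for_sizes(model, recordings, window_sizes, k, rng_seed)
  cbind(data.frame(data_rate = rate_labels),
        out[, c("window_size", "n_windows", "n_excluded", "accuracy")])
}

#' Repeated five-fold cross-validated evaluation
#'
#' For each repeat the dataset is reshuffled and split into `n_folds`
#' stratified folds; a model is trained on each fold's training recordings
#' and both accuracy analyses are run on its test recordings.  Reported
#' accuracies are means over the `n_repeats * n_folds` runs, with standard
#' deviations.
#'
#' @param recordings Normalized recordings (all users, equal trial counts).
#' @param config A [model_config()]; its seed is re-derived per fold/repeat.
#' @param n_repeats Shuffle-and-split repetitions (default 5).
#' @param n_folds Folds per repetition (default 5).
#' @param sizes,window_sizes,rate_labels,k Passed to the two analyses.
#' @param rng_seed Master seed governing shuffles, training and evaluation.
#' @param verbose Print progress per fold.
#' @return Object of class `eval_report`: tables `by_window_size` and
#'   `by_data_rate` (mean/sd/n), all per-cell fold values, and the seed
#'   record.
#' @export
cross_validated_report <- function(recordings, config, n_repeats = 5L,
                                   n_folds = 5L,
                                   sizes = c(20L, 30L, 50L, 100L, 150L, 200L),
                                   window_sizes = c(42L, 63L, 84L),
                                   rate_labels = c(26, 39, 52),
                                   k = 10L, rng_seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  ids <- vapply(recordings, `[[`, character(1), "recording_id")
  ws_runs <- list(); dr_runs <- list()
  seeds <- list(master = rng_seed)
  run <- 0L
  for (rep_i in seq_len(n_repeats)) {
    fold_seed <- derive_seed(rng_seed, "repeat", rep_i)
    folds <- make_folds(recordings, n_folds = n_folds, rng_seed = fold_seed)
    seeds[[paste0("repeat", rep_i)]] <- fold_seed
    for (fold in folds) {
      run <- run + 1L
      cfg <- config
      cfg$rng_seed <- derive_seed(rng_seed, "fit", run)
      train_recs <- recordings[ids %in% fold$train_ids]
      test_recs <- recordings[ids %in% fold$test_ids]
      model <- train_model(build_model(cfg), train_recs)
      ev_seed <- derive_seed(rng_seed, "evalrun", run)
      ws <- evaluate_by_window_size(model, test_recs, sizes = sizes, k = k,
                                    rng_seed = ev_seed)
      dr <- evaluate_by_data_rate(model, test_recs,
                                  window_sizes = window_sizes,
                                  rate_labels = rate_labels, k = k,
                                  rng_seed = ev_seed)
      ws$repeat_index <- rep_i; ws$fold_index <- fold$fold_index
      dr$repeat_index <- rep_i; dr$fold_index <- fold$fold_index
      ws_runs[[run]] <- ws; dr_runs[[run]] <- dr
      if (verbose) {
        message(sprintf("repeat %d fold %d: acc(T=%d) = %.1f%%", rep_i,
                        fold$fold_index, max(sizes),
                        ws$accuracy[ws$window_size == max(sizes)]))
      }
    }
  }
  ws_all <- do.call(rbind, ws_runs)
  dr_all <- do.call(rbind, dr_runs)
  agg <- function(df, key) {
    res <- do.call(rbind, lapply(split(df, df[[key]]), function(d) {
      data.frame(key = d[[key]][1], window_size = d$window_size[1],
                 mean_accuracy = mean(d$accuracy),
                 sd_accuracy = stats::sd(d$accuracy),
                 n_runs = nrow(d), n_windows = sum(d$n_windows))
    }))
    res <- res[order(res$key), ]
    rownames(res) <- NULL
    res
  }
  by_ws <- agg(ws_all, "window_size")
  names(by_ws)[1] <- "window_size"
  by_ws <- by_ws[, c("window_size", "mean_accuracy", "sd_accuracy",
                     "n_runs", "n_windows")]
  by_ws <- cbind(by_ws[, 1, drop = FALSE],
                 seconds = window_seconds(by_ws$window_size),
                 by_ws[, -1])
  by_dr <- agg(dr_all, "data_rate")
  names(by_dr)[1] <- "data_rate"
  structure(list(by_window_size = by_ws,
                 by_data_rate = by_dr,
                 runs_window_size = ws_all,
                 runs_data_rate = dr_all,
                 n_repeats = n_repeats, n_folds = n_folds,
                 k_windows = k, seeds = seeds,
                 config = unclass(config)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d repeats x %d folds, %d windows/recording\n",
              x$n_repeats, x$n_folds, x$k_windows))
  cat("\nIdentification rate by window size:\n")
  print(x$by_window_size, row.names = FALSE, digits = 4)
  cat("\nIdentification rate by data rate:\n")
  print(x$by_data_rate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Serializes the full report as JSON (with a reproducibility block: seeds,
#' config hash, package version) and renders the two summary tables as CSV:
#' window size with its seconds column, and data-rate label with the window
#' size used.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- do.call(model_config, report$config)
  obj <- list(reproducibility = list(
                seeds = report$seeds,
                config_hash = config_hash(cfg),
                package_version = as.character(utils::packageVersion("gaitid"))),
              config = report$config,
              n_repeats = report$n_repeats, n_folds = report$n_folds,
              k_windows = report$k_windows,
              by_window_size = report$by_window_size,
              by_data_rate = report$by_data_rate,
              runs_window_size = report$runs_window_size,
              runs_data_rate = report$runs_data_rate)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  ws_csv <- file.path(dir, "accuracy_by_window_size.csv")
  dr_csv <- file.path(dir, "accuracy_by_data_rate.csv")
  data.table::fwrite(report$by_window_size, ws_csv)
  data.table::fwrite(report$by_data_rate, dr_csv)
  invisible(c(json = json, window_size = ws_csv, data_rate = dr_csv))
}
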