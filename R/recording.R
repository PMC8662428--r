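# Recording and window containers plus the random-window sampling that is
# the core training-data construction: windows of random size (20-200
# samples) at random locations, so one model learns partial walking data of
# any length without step segmentation.

CHANNELS <- c("xL", "yL", "zL", "xR", "yR", "zR")

#' One labeled insole accelerometer recording
#'
#' An L x 6 matrix of acceleration samples at 30 Hz, channel order
#' `xL, yL, zL, xR, yR, zR`, with the user label and trial metadata.  The
#' recording is the unit of cross-validation.
#'
#' @param samples Numeric L x 6 matrix, L >= 20.
#' @param user_id Integer user label.
#' @param trial_id Integer trial index.
#' @param recording_id Unique string id; defaults to `"u<user>_t<trial>"`.
#' @param normalized Logical flag set by [normalize_recording()].
#' @return Object of class `accel_recording`.
#' @export
accel_recording <- function(samples, user_id, trial_id = 0L,
                            recording_id = NULL, normalized = FALSE) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 6L) {
    stop(sprintf("recording must have exactly 6 channels, got %d",
                 ncol(samples)), call. = FALSE)
  }
  if (nrow(samples) < 20L) {
    stop("recording must have at least 20 samples", call. = FALSE)
  }
  colnames(samples) <- CHANNELS
  if (is.null(recording_id)) {
    recording_id <- sprintf("u%02d_t%02d", as.integer(user_id),
                            as.integer(trial_id))
  }
  structure(
    list(recording_id = recording_id,
         user_id = as.integer(user_id),
         trial_id = as.integer(trial_id),
         sample_rate = SAMPLE_RATE,
         normalized = isTRUE(normalized),
         samples = samples),
    class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %s: user %d, trial %d, %d samples @ %d Hz%s\n",
              x$recording_id, x$user_id, x$trial_id, nrow(x$samples),
              x$sample_rate, if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An [accel_recording()].
#' @return Integer length L.
#' @export
recording_length <- function(rec) nrow(rec$samples)

#' Per-channel z-score normalization
#'
#' Each of the six channels is independently centred to mean 0 and scaled to
#' (sample) standard deviation 1 over the recording's own L samples.  Applied
#' per recording, before any windowing, so inference is self-contained and no
#' cross-trial statistics leak between folds.
#'
#' @param rec An [accel_recording()].
#' @return The recording with normalized samples; labels and metadata
#'   unchanged.
#' @export
normalize_recording <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  x <- rec$samples
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- CHANNELS[which(sds == 0)[1]]
    stop(sprintf("channel '%s' has zero variance; cannot z-score", bad),
         call. = FALSE)
  }
  rec$samples <- scale(x, center = TRUE, scale = sds)
  attr(rec$samples, "scaled:center") <- NULL
  attr(rec$samples, "scaled:scale") <- NULL
  rec$normalized <- TRUE
  rec
}

#' A contiguous window of a recording
#'
#' The unit of training and prediction: a T x 6 slice starting at a 0-based
#' sample offset, carrying its source recording's user label.
#'
#' @param data T x 6 numeric matrix.
#' @param user_id Integer label.
#' @param source_recording Recording id string.
#' @param start_index 0-based offset of the first sample in the source.
#' @return Object of class `gait_window`.
#' @export
gait_window <- function(data, user_id, source_recording = NA_character_,
                        start_index = 0L) {
  data <- as.matrix(data)
  if (ncol(data) != 6L) stop("window must have 6 channels", call. = FALSE)
  structure(list(data = data,
                 user_id = as.integer(user_id),
                 source_recording = source_recording,
                 start_index = as.integer(start_index),
                 T = nrow(data)),
            class = "gait_window")
}

#' @export
print.gait_window <- function(x, ...) {
  cat(sprintf("<gait_window> T=%d from %s[%d:%d), user %d\n",
              x$T, x$source_recording, x$start_index, x$start_index + x$T,
              x$user_id))
  invisible(x)
}

#' Draw one random training window
#'
#' The window size T is drawn uniformly from the integers
#' `[t_min, min(t_max, L)]` and the 0-based start uniformly from
#' `[0, L - T]`, so training sees partial data of every admissible size at
#' every location.  Consumes the caller's RNG stream (seed with
#' `set.seed()` for reproducibility).
#'
#' @param rec A normalized [accel_recording()] with `L >= t_min`.
#' @param t_min,t_max Inclusive window-size bounds in samples (default
#'   20--200).
#' @return A [gait_window()].
#' @export
sample_training_window <- function(rec, t_min = 20L, t_max = 200L) {
  stopifnot(inherits(rec, "accel_recording"))
  L <- recording_length(rec)
  if (L < t_min) {
    stop(sprintf("recording %s has %d < t_min = %d samples",
                 rec$recording_id, L, t_min), call. = FALSE)
  }
  hi <- min(t_max, L)
  T <- if (hi == t_min) t_min else
    t_min + sample.int(hi - t_min + 1L, 1L) - 1L
  start <- if (L == T) 0L else sample.int(L - T + 1L, 1L) - 1L
  gait_window(rec$samples[(start + 1L):(start + T), , drop = FALSE],
              user_id = rec$user_id,
              source_recording = rec$recording_id,
              start_index = start)
}

#' Extract fixed-size test windows
#'
#' k windows of exact size T at uniformly random start positions (with
#' replacement), each labeled with the recording's user id.  Deterministic
#' given `rng_seed`; with `rng_seed = NULL` the caller's RNG stream is used.
#'
#' @param rec An [accel_recording()] with `L >= T`.
#' @param T Window size in samples.
#' @param k Number of windows.
#' @param rng_seed Optional integer seed.
#' @return List of k [gait_window()] objects, all T x 6.
#' @export
extract_test_windows <- function(rec, T, k = 10L, rng_seed = NULL) {
  stopifnot(inherits(rec, "accel_recording"))
  L <- recording_length(rec)
  if (T > L) {
    stop(sprintf("window size %d exceeds recording length %d (%s)",
                 T, L, rec$recording_id), call. = FALSE)
  }
  draw <- function() {
    if (L == T) rep(0L, k) else sample.int(L - T + 1L, k, replace = TRUE) - 1L
  }
  starts <- if (is.null(rng_seed)) draw() else
    withr::with_seed(derive_seed(rng_seed, "testwin", 0L), draw())
  lapply(starts, function(s) {
    gait_window(rec$samples[(s + 1L):(s + T), , drop = FALSE],
                user_id = rec$user_id,
                source_recording = rec$recording_id,
                start_index = s)
  })
}
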