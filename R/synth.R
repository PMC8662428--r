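# Synthetic bilateral smart-insole accelerometer data.
#
# The generator emulates the statistical structure that the classifier
# assumes: each user has a quasi-periodic, user-specific gait signature on
# six accelerometer channels (xL, yL, zL, xR, yR, zR) sampled at 30 Hz, with
# the right foot anti-phase to the left, and trial-to-trial variability in
# cadence, amplitude and phase.  Each channel is a sum of H harmonics of the
# stride frequency plus white Gaussian noise; the right-foot channel of each
# axis is the left-foot waveform delayed by a fraction of the stride period.

# 10 m walks last between 7.2 s and 9.6 s, so walking speeds live in this
# fixed band (m/s).
SPEED_MIN <- 10 / 9.6
SPEED_MAX <- 10 / 7.2
SAMPLE_RATE <- 30

#' Per-user latent gait parameters
#'
#' A `gait_profile` drives the simulator: stride frequency sets the
#' periodicity, walking speed sets the recording length for a fixed walk
#' distance, and the per-axis harmonic amplitudes/phases form the user's
#' signature waveform shared (time-shifted) between the two feet.
#'
#' @param user_id Integer label, >= 0.
#' @param stride_frequency Full gait cycles (left+right) per second, Hz.
#' @param walking_speed Metres per second; must lie in `[10/9.6, 10/7.2]` so
#'   that a 10 m walk lasts between 7.2 s and 9.6 s.
#' @param harmonic_amplitudes 3 x H matrix (rows: x, y, z axis) of harmonic
#'   amplitudes in arbitrary acceleration units; H >= 3.
#' @param harmonic_phases 3 x H matrix of phases in radians.
#' @param left_right_offset Fraction of the stride period, in `[0.4, 0.6]`,
#'   by which the right foot lags the left (nominal 0.5).
#' @param noise_sd Standard deviation of additive white Gaussian noise.
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(user_id, stride_frequency, walking_speed,
                         harmonic_amplitudes, harmonic_phases,
                         left_right_offset = 0.5, noise_sd = 0.3) {
  user_id <- as.integer(user_id)
  if (is.na(user_id) || user_id < 0L) {
    stop("'user_id' must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(stride_frequency) || stride_frequency <= 0) {
    stop("'stride_frequency' must be positive", call. = FALSE)
  }
  if (walking_speed < SPEED_MIN - 1e-12 || walking_speed > SPEED_MAX + 1e-12) {
    stop(sprintf("'walking_speed' must lie in [%.4f, %.4f] m/s",
                 SPEED_MIN, SPEED_MAX), call. = FALSE)
  }
  harmonic_amplitudes <- as.matrix(harmonic_amplitudes)
  harmonic_phases <- as.matrix(harmonic_phases)
  if (nrow(harmonic_amplitudes) != 3L || ncol(harmonic_amplitudes) < 3L) {
    stop("'harmonic_amplitudes' must be a 3 x H matrix with H >= 3",
         call. = FALSE)
  }
  if (!identical(dim(harmonic_amplitudes), dim(harmonic_phases))) {
    stop("'harmonic_phases' must match the dimensions of 'harmonic_amplitudes'",
         call. = FALSE)
  }
  if (left_right_offset < 0.4 || left_right_offset > 0.6) {
    stop("'left_right_offset' must lie in [0.4, 0.6]", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(
    list(user_id = user_id,
         stride_frequency = stride_frequency,
         walking_speed = walking_speed,
         harmonic_amplitudes = harmonic_amplitudes,
         harmonic_phases = harmonic_phases,
         left_right_offset = left_right_offset,
         noise_sd = noise_sd),
    class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(
    "<gait_profile> user %d: %.2f Hz stride, %.2f m/s, %d harmonics, noise sd %.2f\n",
    x$user_id, x$stride_frequency, x$walking_speed,
    ncol(x$harmonic_amplitudes), x$noise_sd))
  invisible(x)
}

#' Draw a population of gait profiles
#'
#' Draws `n_users` profiles with distinct user ids `0 .. n_users - 1`.
#' `separation` controls how distinguishable the users are:
#' \describe{
#'   \item{`"default"`}{independent random draws per user: stride frequency
#'     uniform on 0.8--1.1 Hz, speed uniform over the admissible band,
#'     amplitudes random with a 1/h^0.7 roll-off -- realistically separable.}
#'   \item{`"low"`}{every user shares one common parameter point, so no
#'     classifier can beat chance in expectation (negative control).}
#'   \item{`"high"`}{cadence and amplitudes laid out on a deterministic grid
#'     (distinct stride frequencies, distinct dominant harmonics) for maximal
#'     spectral separability.}
#' }
#'
#' @param n_users Number of users, >= 0.
#' @param rng_seed Integer seed; identical arguments reproduce identical
#'   profiles field by field.
#' @param separation `"default"`, `"low"` or `"high"`.
#' @param noise_sd Noise standard deviation stored in every profile.
#' @param n_harmonics Harmonics per channel, H >= 3.
#' @return List of [gait_profile()] objects.
#' @export
sample_profiles <- function(n_users, rng_seed = 1L,
                            separation = c("default", "low", "high"),
                            noise_sd = 0.3, n_harmonics = 4L) {
  separation <- match.arg(separation)
  if (!is.numeric(n_users) || length(n_users) != 1L || n_users < 0 ||
      n_users != round(n_users)) {
    stop("'n_users' must be a non-negative integer", call. = FALSE)
  }
  n_users <- as.integer(n_users)
  if (n_users == 0L) return(list())
  H <- as.integer(n_harmonics)

  draw_random <- function(uid) {
    withr::with_seed(derive_seed(rng_seed, "profile", uid), {
      amps <- matrix(runif(3 * H, 0.3, 1.0), nrow = 3) *
        matrix(rep(seq_len(H)^-0.7, each = 3), nrow = 3)
      gait_profile(
        user_id = uid,
        stride_frequency = runif(1, 0.8, 1.1),
        walking_speed = runif(1, SPEED_MIN, SPEED_MAX),
        harmonic_amplitudes = amps,
        harmonic_phases = matrix(runif(3 * H, 0, 2 * pi), nrow = 3),
        left_right_offset = runif(1, 0.45, 0.55),
        noise_sd = noise_sd)
    })
  }

  switch(separation,
    default = lapply(seq_len(n_users) - 1L, draw_random),
    low = {
      base <- draw_random(0L)
      lapply(seq_len(n_users) - 1L, function(uid) {
        p <- base
        p$user_id <- uid
        p
      })
    },
    high = {
      freqs <- if (n_users == 1L) 0.95 else seq(0.8, 1.1, length.out = n_users)
      speeds <- if (n_users == 1L) mean(c(SPEED_MIN, SPEED_MAX)) else
        seq(SPEED_MIN, SPEED_MAX, length.out = n_users)
      lapply(seq_len(n_users) - 1L, function(uid) {
        amps <- matrix(rep(seq_len(H)^-0.7, each = 3), nrow = 3) *
          (0.6 + 0.4 * uid / max(1L, n_users - 1L))
        amps[, (uid %% H) + 1L] <- 1.2   # distinct dominant harmonic
        gait_profile(
          user_id = uid,
          stride_frequency = freqs[uid + 1L],
          walking_speed = speeds[uid + 1L],
          harmonic_amplitudes = amps,
          harmonic_phases = matrix(0, nrow = 3, ncol = H),
          left_right_offset = 0.5,
          noise_sd = noise_sd)
      })
    })
}

#' Trial-to-trial jitter
#'
#' Multiplicative cadence and amplitude jitter plus a global phase shift,
#' applied to one simulated walk so repeated trials of the same user differ
#' the way repeated real walks do.
#'
#' @param cadence_scale Multiplier on stride frequency and walking speed, > 0.
#' @param amplitude_scale Multiplier on all harmonic amplitudes, > 0.
#' @param phase_shift Radians added to the stride phase (scaled per harmonic,
#'   i.e. a time shift of the whole waveform).
#' @return Object of class `trial_jitter`.
#' @export
trial_jitter <- function(cadence_scale = 1, amplitude_scale = 1,
                         phase_shift = 0) {
  if (cadence_scale <= 0 || amplitude_scale <= 0) {
    stop("jitter scales must be positive", call. = FALSE)
  }
  structure(list(cadence_scale = cadence_scale,
                 amplitude_scale = amplitude_scale,
                 phase_shift = phase_shift),
            class = "trial_jitter")
}

# Default jitter distribution: cadence ~ N(1, 0.02) truncated to
# [0.94, 1.06]; amplitude ~ N(1, 0.05) truncated positive; phase uniform.
# Consumes the current RNG stream.
sample_trial_jitter <- function(cadence_sd = 0.02, amplitude_sd = 0.05) {
  cs <- rnorm(1, 1, cadence_sd)
  while (cs < 0.94 || cs > 1.06) cs <- rnorm(1, 1, cadence_sd)
  as <- rnorm(1, 1, amplitude_sd)
  while (as <= 0) as <- rnorm(1, 1, amplitude_sd)
  trial_jitter(cs, as, runif(1, -pi, pi))
}

#' Simulate one 10 m walk
#'
#' The recording length follows the length law
#' `L = round(30 * distance_m / v)` where `v` is the jittered walking speed,
#' clamped to the admissible band so all default trials stay within the
#' 216--290 sample envelope.  Each left-foot channel is a sum of harmonics of
#' the (jittered) stride frequency; the matching right-foot channel is the
#' identical waveform delayed by `left_right_offset` stride periods.
#' Independent Gaussian noise is added per channel from the current RNG
#' stream.
#'
#' @param profile A [gait_profile()].
#' @param distance_m Walk distance in metres (> 0), default 10.
#' @param jitter A [trial_jitter()]; default no jitter.
#' @param trial_id Integer trial index stored in the recording metadata.
#' @return An [accel_recording()].
#' @export
generate_trial <- function(profile, distance_m = 10, jitter = trial_jitter(),
                           trial_id = 0L) {
  stopifnot(inherits(profile, "gait_profile"), inherits(jitter, "trial_jitter"))
  if (distance_m <= 0) stop("'distance_m' must be positive", call. = FALSE)
  v <- min(max(profile$walking_speed * jitter$cadence_scale, SPEED_MIN),
           SPEED_MAX)
  L <- round((distance_m / v) * SAMPLE_RATE)
  freq <- profile$stride_frequency * jitter$cadence_scale
  tt <- (seq_len(L) - 1) / SAMPLE_RATE
  H <- ncol(profile$harmonic_amplitudes)
  delay <- profile$left_right_offset / freq
  x <- matrix(0, nrow = L, ncol = 6)
  for (axis in 1:3) {
    left <- numeric(L)
    right <- numeric(L)
    for (h in seq_len(H)) {
      a <- profile$harmonic_amplitudes[axis, h] * jitter$amplitude_scale
      ph <- profile$harmonic_phases[axis, h] + h * jitter$phase_shift
      w <- 2 * pi * h * freq
      left <- left + a * cos(w * tt + ph)
      right <- right + a * cos(w * (tt - delay) + ph)
    }
    x[, axis] <- left
    x[, axis + 3L] <- right
  }
  if (profile$noise_sd > 0) {
    x <- x + matrix(rnorm(L * 6, 0, profile$noise_sd), nrow = L)
  }
  accel_recording(
    samples = x,
    user_id = profile$user_id,
    trial_id = as.integer(trial_id),
    recording_id = sprintf("u%02d_t%02d", profile$user_id, trial_id))
}

#' Simulate a full multi-user dataset
#'
#' One recording per profile per trial, each with freshly drawn trial jitter.
#' Deterministic given `rng_seed`: every (user, trial) pair gets its own
#' derived seed, so recordings do not depend on generation order.
#'
#' @param profiles List of [gait_profile()] objects.
#' @param n_trials Trials (walks) per user, >= 1.
#' @param rng_seed Integer master seed.
#' @param distance_m Walk distance in metres.
#' @return List of [accel_recording()] objects of length
#'   `length(profiles) * n_trials`.
#' @export
generate_dataset <- function(profiles, n_trials = 10L, rng_seed = 1L,
                             distance_m = 10) {
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  out <- vector("list", length(profiles) * n_trials)
  idx <- 1L
  for (p in profiles) {
    for (tr in seq_len(n_trials) - 1L) {
      out[[idx]] <- withr::with_seed(
        derive_seed(rng_seed, "trial", p$user_id * 997L + tr),
        generate_trial(p, distance_m = distance_m,
                       jitter = sample_trial_jitter(), trial_id = tr))
      idx <- idx + 1L
    }
  }
  out
}
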