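# Stacked-LSTM user-identification network.
#
# Architecture: LSTM(64, full sequence, recurrent dropout 0.2) ->
# LSTM(64, last output, recurrent dropout 0.2) -> dropout 0.5 ->
# dense(n) -> softmax.  The same weights score windows of any length T >= 1
# with 6 channels, which is what makes step-segmentation unnecessary:
# training draws windows of random size (20-200) and random location, so one
# model handles partial walking data of every admissible length.
#
# Forward/backward passes live in src/lstm.cpp; all randomness (weight init,
# window draws, dropout masks) is drawn from R's RNG under derived seeds so
# runs are bit-reproducible.

#' Model and training configuration
#'
#' @param n_classes Number of users n (>= 2); size of the softmax output.
#' @param hidden1,hidden2 Units in the first/second recurrent layer
#'   (default 64 each).
#' @param recurrent_dropout Variational dropout rate on the hidden state
#'   entering each recurrent transition (default 0.2).
#' @param final_dropout Dropout rate on the 64-feature vector feeding the
#'   dense layer (default 0.5).
#' @param epochs Training epochs. Default 50 (desk scale); the full-scale
#'   preset uses 1000 (see [run_config()]).
#' @param windows_per_epoch Random windows drawn per epoch (default 2048).
#' @param batch_size Windows per mini-batch; one window size T is drawn per
#'   batch so tensors stay rectangular (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param t_min,t_max Training window-size bounds in samples (default
#'   20--200).
#' @param rng_seed Integer seed; weight-init and window-sampling streams are
#'   derived from it independently.
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_classes, hidden1 = 64L, hidden2 = 64L,
                         recurrent_dropout = 0.2, final_dropout = 0.5,
                         epochs = 50L, windows_per_epoch = 2048L,
                         batch_size = 32L, learning_rate = 1e-3,
                         t_min = 20L, t_max = 200L, rng_seed = 1L) {
  if (n_classes < 2L) stop("'n_classes' must be >= 2", call. = FALSE)
  if (recurrent_dropout < 0 || recurrent_dropout >= 1 ||
      final_dropout < 0 || final_dropout >= 1) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  counts <- c(hidden1 = hidden1, hidden2 = hidden2,
              windows_per_epoch = windows_per_epoch, batch_size = batch_size)
  if (any(counts < 1)) stop("all size counts must be >= 1", call. = FALSE)
  if (epochs < 0) stop("'epochs' must be >= 0", call. = FALSE)
  if (learning_rate <= 0) stop("'learning_rate' must be positive", call. = FALSE)
  if (t_min > t_max || t_min < 1) {
    stop("need 1 <= t_min <= t_max", call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 recurrent_dropout = recurrent_dropout,
                 final_dropout = final_dropout,
                 epochs = as.integer(epochs),
                 windows_per_epoch = as.integer(windows_per_epoch),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 t_min = as.integer(t_min), t_max = as.integer(t_max),
                 rng_seed = as.integer(rng_seed)),
            class = "model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nrow = nin)
}

# Per-gate orthogonal recurrent init (QR of a standard-normal square).
orthogonal_gates <- function(h, gates = 4L) {
  do.call(cbind, lapply(seq_len(gates), function(g) {
    qr.Q(qr(matrix(rnorm(h * h), h, h)))
  }))
}

init_params <- function(config) {
  h1 <- config$hidden1; h2 <- config$hidden2; n <- config$n_classes
  withr::with_seed(derive_seed(config$rng_seed, "init", 0L), {
    b1 <- rep(0, 4 * h1); b1[(h1 + 1):(2 * h1)] <- 1  # forget-gate bias 1
    b2 <- rep(0, 4 * h2); b2[(h2 + 1):(2 * h2)] <- 1
    list(Wx1 = glorot(6L, 4L * h1), Wh1 = orthogonal_gates(h1), b1 = b1,
         Wx2 = glorot(h1, 4L * h2), Wh2 = orthogonal_gates(h2), b2 = b2,
         Wd = glorot(h2, n), bd = rep(0, n))
  })
}

#' Build an (untrained) stacked-LSTM identification model
#'
#' Weights are initialized deterministically from the config seed: Glorot
#' uniform input kernels, per-gate orthogonal recurrent kernels, zero biases
#' with the forget-gate bias at 1.
#'
#' @param config A [model_config()].
#' @return Object of class `gait_lstm` with empty training history.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config,
                 params = init_params(config),
                 classes = NULL,
                 opt = NULL,
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      accuracy = numeric())),
            class = "gait_lstm")
}

#' @export
print.gait_lstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<gait_lstm> LSTM(%d)->LSTM(%d)->dense(%d) softmax; rec. dropout %.1f, final dropout %.1f\n",
    cfg$hidden1, cfg$hidden2, cfg$n_classes, cfg$recurrent_dropout,
    cfg$final_dropout))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f, accuracy %.3f\n",
                nrow(x$history), last$loss, last$accuracy))
  } else cat("  untrained\n")
  invisible(x)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(matrix(1, nr, nc))
  matrix(rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

# Assemble a (B, 6, T) array from windows drawn at the given starts.
batch_array <- function(recordings, idx, starts, T) {
  B <- length(idx)
  X <- array(0, dim = c(B, 6L, T))
  for (b in seq_len(B)) {
    s <- starts[b]
    X[b, , ] <- t(recordings[[idx[b]]]$samples[(s + 1L):(s + T), ,
                                               drop = FALSE])
  }
  X
}

#' Train the model on normalized recordings
#'
#' Each epoch draws `windows_per_epoch` training windows: per mini-batch one
#' window size T is drawn uniformly from `[t_min, t_max]`, then `batch_size`
#' recordings are chosen uniformly with replacement and a uniform random
#' start is drawn in each.  The categorical cross-entropy between the softmax
#' output and the true user label is minimized with Adam.  Fully reproducible
#' given the config seed (weight-init and sampling streams are separated).
#'
#' @param model A `gait_lstm` from [build_model()].
#' @param recordings List of normalized [accel_recording()] covering all
#'   `n_classes` users.
#' @param verbose Print per-epoch loss/accuracy.
#' @return The trained model with per-epoch `history`.
#' @export
train_model <- function(model, recordings, verbose = FALSE) {
  stopifnot(inherits(model, "gait_lstm"))
  cfg <- model$config
  if (!all(vapply(recordings, function(r) isTRUE(r$normalized), logical(1)))) {
    stop("all training recordings must be normalized (see normalize_recording)",
         call. = FALSE)
  }
  classes <- sort(unique(vapply(recordings, `[[`, integer(1), "user_id")))
  if (length(classes) != cfg$n_classes) {
    stop(sprintf("config expects %d classes but training data has %d users",
                 cfg$n_classes, length(classes)), call. = FALSE)
  }
  model$classes <- classes
  y_all <- match(vapply(recordings, `[[`, integer(1), "user_id"), classes) - 1L
  lens <- vapply(recordings, recording_length, integer(1))
  if (any(lens < cfg$t_min)) {
    stop("all recordings must have at least t_min samples", call. = FALSE)
  }
  if (is.null(model$opt)) model$opt <- adam_init(model$params)
  n_batches <- ceiling(cfg$windows_per_epoch / cfg$batch_size)
  B <- cfg$batch_size
  start_epoch <- nrow(model$history)

  for (ep in seq_len(cfg$epochs)) {
    res <- withr::with_seed(
      derive_seed(cfg$rng_seed, "epoch", start_epoch + ep), {
      ep_loss <- 0; ep_acc <- 0
      for (bt in seq_len(n_batches)) {
        hi <- min(cfg$t_max, min(lens))
        T <- cfg$t_min + sample.int(hi - cfg$t_min + 1L, 1L) - 1L
        idx <- sample.int(length(recordings), B, replace = TRUE)
        starts <- vapply(idx, function(i) {
          if (lens[i] == T) 0L else sample.int(lens[i] - T + 1L, 1L) - 1L
        }, integer(1))
        X <- batch_array(recordings, idx, starts, T)
        r1 <- drop_mask(B, cfg$hidden1, cfg$recurrent_dropout)
        r2 <- drop_mask(B, cfg$hidden2, cfg$recurrent_dropout)
        dm <- drop_mask(B, cfg$hidden2, cfg$final_dropout)
        out <- cpp_lstm_grad(model$params, X, y_all[idx], r1, r2, dm)
        upd <- adam_step(model$params, out$grads, model$opt,
                         cfg$learning_rate)
        model$params <- upd$params
        model$opt <- upd$state
        ep_loss <- ep_loss + out$loss
        ep_acc <- ep_acc + out$accuracy
      }
      list(model = model, loss = ep_loss / n_batches,
           acc = ep_acc / n_batches)
    })
    model <- res$model
    model$history <- rbind(model$history,
                           data.frame(epoch = start_epoch + ep,
                                      loss = res$loss, accuracy = res$acc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                      start_epoch + ep, res$loss, res$acc))
    }
  }
  model
}

#' Predict user probabilities for windows
#'
#' Dropout is disabled at inference; output rows are softmax probabilities
#' over the trained classes.  Ties in the argmax are broken toward the lowest
#' class index.
#'
#' @param object A trained `gait_lstm`.
#' @param windows A single window (T x 6 matrix or [gait_window()]) or a list
#'   of them; any lengths T >= 1 may be mixed.
#' @param type `"prob"` for an n_windows x n_classes probability matrix
#'   (columns named by user id), `"class"` for the predicted user ids.
#' @param ... Unused.
#' @return Probability matrix or integer vector of user ids.
#' @export
predict.gait_lstm <- function(object, windows, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  if (is.matrix(windows) || inherits(windows, "gait_window")) {
    windows <- list(windows)
  }
  mats <- lapply(windows, function(w) {
    m <- if (inherits(w, "gait_window")) w$data else as.matrix(w)
    if (ncol(m) != 6L) {
      stop(sprintf("window has %d channels; expected 6", ncol(m)),
           call. = FALSE)
    }
    m
  })
  lens <- vapply(mats, nrow, integer(1))
  probs <- matrix(NA_real_, nrow = length(mats),
                  ncol = object$config$n_classes)
  for (T in unique(lens)) {
    sel <- which(lens == T)
    X <- array(0, dim = c(length(sel), 6L, T))
    for (j in seq_along(sel)) X[j, , ] <- t(mats[[sel[j]]])
    probs[sel, ] <- cpp_lstm_predict(object$params, X)
  }
  if (!is.null(object$classes)) colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  cls <- if (is.null(object$classes)) {
    seq_len(object$config$n_classes) - 1L
  } else object$classes
  cls[apply(probs, 1, which.max)]
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Save / load a model checkpoint
#'
#' A single JSON archive holding the weights, the full config (with its
#' seed) and the trained class labels.  `load_model()` verifies the stored
#' config hash before returning.
#'
#' @param model A `gait_lstm`.
#' @param path Destination file.
#' @return `save_model` the path invisibly; `load_model` the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gait_lstm"))
  obj <- list(package = "gaitid",
              config = unclass(model$config),
              config_hash = config_hash(model$config),
              classes = model$classes,
              params = model$params,
              history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config)
  if (!identical(config_hash(cfg), obj$config_hash)) {
    stop("checkpoint config hash mismatch; file corrupted or edited",
         call. = FALSE)
  }
  model <- build_model(cfg)
  model$params <- lapply(obj$params, function(p) {
    if (is.matrix(p)) p else as.numeric(p)
  })
  model$classes <- if (length(obj$classes)) as.integer(obj$classes) else NULL
  model$history <- as.data.frame(obj$history)
  model
}
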