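# Stacked-LSTM model: construction, gradients, training, prediction,
# checkpointing.

test_that("config validation rejects invalid fields", {
  expect_error(model_config(n_classes = 1), ">= 2")
  expect_error(model_config(4, recurrent_dropout = 1), "dropout")
  expect_error(model_config(4, final_dropout = -0.1), "dropout")
  expect_error(model_config(4, batch_size = 0), ">= 1")
  expect_error(model_config(4, learning_rate = 0), "positive")
  expect_error(model_config(4, t_min = 50, t_max = 20), "t_min")
})

test_that("weight initialization is deterministic per seed", {
  a <- build_model(model_config(4, rng_seed = 9))
  b <- build_model(model_config(4, rng_seed = 9))
  expect_identical(a$params, b$params)
  c <- build_model(model_config(4, rng_seed = 10))
  expect_false(identical(a$params, c$params))
  # sized as configured: 16 classes -> 16 output probabilities
  m16 <- build_model(model_config(16))
  expect_identical(ncol(m16$params$Wd), 16L)
  p <- predict(m16, matrix(rnorm(50 * 6), 50))
  expect_identical(dim(p), c(1L, 16L))
})

test_that("one model scores windows of any length with proper softmax", {
  m <- tiny_model()
  set.seed(3)
  for (T in c(1L, 20L, 77L, 200L, 260L)) {
    p <- predict(m, matrix(rnorm(T * 6), T))
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
  # mixed lengths in one call, inference deterministic
  wins <- list(matrix(rnorm(20 * 6), 20), matrix(rnorm(200 * 6), 200))
  expect_identical(predict(m, wins), predict(m, wins))
  expect_error(predict(m, matrix(rnorm(100), 20, 5)), "channels")
})

test_that("BPTT gradients match central finite differences", {
  cfg <- model_config(n_classes = 3, hidden1 = 5, hidden2 = 4, rng_seed = 7)
  m <- build_model(cfg)
  set.seed(42)
  B <- 3L; T <- 6L
  X <- array(rnorm(B * 6 * T), dim = c(B, 6, T))
  y <- c(0, 2, 1)
  r1 <- matrix(rbinom(B * 5, 1, 0.8) / 0.8, B, 5)
  r2 <- matrix(rbinom(B * 4, 1, 0.8) / 0.8, B, 4)
  dm <- matrix(rbinom(B * 4, 1, 0.5) / 0.5, B, 4)
  g <- gaitid:::cpp_lstm_grad(m$params, X, y, r1, r2, dm)
  lossfn <- function(p) gaitid:::cpp_lstm_grad(p, X, y, r1, r2, dm)$loss
  eps <- 1e-6
  for (k in names(m$params)) {
    for (i in sample(length(m$params[[k]]), min(5, length(m$params[[k]])))) {
      pp <- m$params
      pp[[k]][i] <- pp[[k]][i] + eps; up <- lossfn(pp)
      pp[[k]][i] <- pp[[k]][i] - 2 * eps; dn <- lossfn(pp)
      num <- (up - dn) / (2 * eps)
      expect_equal(g$grads[[k]][i], num, tolerance = 1e-4,
                   label = sprintf("d loss / d %s[%d]", k, i))
    }
  }
})

test_that("an untrained model is near-uniform over classes on average", {
  m <- build_model(model_config(n_classes = 4, rng_seed = 21))
  recs <- tiny_dataset()
  set.seed(13)
  wins <- lapply(1:400, function(i) {
    sample_training_window(recs[[sample.int(length(recs), 1)]])
  })
  mp <- colMeans(predict(m, wins))
  expect_true(all(abs(mp - 0.25) < 0.06))
})

test_that("training learns a separable task and records history", {
  m <- tiny_model()
  expect_identical(nrow(m$history), 8L)
  expect_lt(m$history$loss[8], m$history$loss[1])
  expect_gt(m$history$accuracy[8], 0.5)  # chance is 0.25
  # training is reproducible from the config seed
  cfg <- model_config(n_classes = 4, epochs = 2, windows_per_epoch = 64,
                      batch_size = 16, rng_seed = 5)
  m1 <- train_model(build_model(cfg), tiny_dataset())
  m2 <- train_model(build_model(cfg), tiny_dataset())
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("zero epochs returns the initialized model with empty history", {
  cfg <- model_config(n_classes = 4, epochs = 0, rng_seed = 5)
  m <- train_model(build_model(cfg), tiny_dataset())
  expect_identical(nrow(m$history), 0L)
  expect_identical(m$params, build_model(cfg)$params)
})

test_that("training validates labels and normalization", {
  recs <- tiny_dataset()
  cfg <- model_config(n_classes = 5, epochs = 1, windows_per_epoch = 32,
                      batch_size = 8, rng_seed = 5)
  expect_error(train_model(build_model(cfg), recs), "5 classes")
  raw <- generate_dataset(sample_profiles(2, rng_seed = 1), 1, rng_seed = 1)
  cfg2 <- model_config(n_classes = 2, epochs = 1, rng_seed = 5)
  expect_error(train_model(build_model(cfg2), raw), "normalized")
})

test_that("permuting class labels permutes the learned distribution", {
  recs <- tiny_dataset()
  cfg <- model_config(n_classes = 4, epochs = 3, windows_per_epoch = 96,
                      batch_size = 16, rng_seed = 31)
  perm <- c(3L, 1L, 4L, 2L)  # new label of old class k = perm[k] - 1

  m1 <- train_model(build_model(cfg), recs)

  relabeled <- lapply(recs, function(r) {
    r$user_id <- perm[r$user_id + 1L] - 1L
    r
  })
  m2 <- build_model(cfg)
  # make the dense head equivariant to the relabeling, then retrain with
  # the identical sampling/dropout streams
  m2$params$Wd <- m2$params$Wd[, order(perm)]
  m2$params$bd <- m2$params$bd[order(perm)]
  m2 <- train_model(m2, relabeled)

  w <- matrix(rnorm(60 * 6), 60)
  p1 <- predict(m1, w)
  p2 <- predict(m2, w)
  expect_equal(unname(p2[1, perm]), unname(p1[1, ]), tolerance = 1e-6)
})

test_that("checkpoints round-trip and verify their config hash", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  w <- matrix(rnorm(40 * 6), 40)
  expect_equal(predict(back, w), predict(m, w), tolerance = 1e-12)
  expect_identical(back$classes, m$classes)

  txt <- readLines(path)
  txt <- sub('"epochs":8', '"epochs":9', txt, fixed = TRUE)
  writeLines(txt, path)
  expect_error(load_model(path), "hash")
})
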