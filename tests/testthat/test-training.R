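test_that("the loss matches its closed forms", {
  # perfect prediction, no penalty
  p <- matrix(c(1, 0, 0, 0, 0,
                0, 1, 0, 0, 0), 2, byrow = TRUE)
  expect_identical(classifier_loss(p, c(1L, 2L)), 0)
  # uniform 5-class probabilities
  pu <- matrix(0.2, 4, 5)
  expect_equal(classifier_loss(pu, c(1L, 3L, 5L, 2L)), log(5))
  # penalty term alone: w = 2, lambda = 0.1, N_b = 1
  pp <- matrix(c(1, 0), 1)
  expect_equal(classifier_loss(pp, 1L, weights = 2, lambda = 0.1), 0.2)
  # clamping keeps zero probabilities finite
  expect_true(is.finite(classifier_loss(matrix(c(0, 1), 1), 1L)))
})

test_that("gradient clipping rescales only above the threshold", {
  expect_identical(clip_gradient(c(0.06, 0.08), 0.1), c(0.06, 0.08))
  expect_equal(clip_gradient(c(0.12, 0.16), 0.1), c(0.06, 0.08))
  expect_identical(clip_gradient(numeric(3), 0.1), numeric(3))
})

test_that("Adam updates follow the bias-corrected moment equations", {
  st <- adam_init(1)
  # zero gradient: no movement
  up0 <- adam_update(1.5, 0, st, 0.001)
  expect_identical(up0$w, 1.5)
  # first step is approximately eta * sign(g)
  up1 <- adam_update(1.5, 0.01, st, 0.001)
  expect_equal(up1$w, 1.5 - 0.001, tolerance = 1e-5)
  # second step with the same gradient again moves by about eta
  up2 <- adam_update(up1$w, 0.01, up1$state, 0.001)
  expect_equal(up1$w - up2$w, 0.001, tolerance = 1e-5)
})

test_that("Adam matches an independent textbook implementation", {
  # independent oracle: direct loop over the defining equations
  adam_oracle <- function(w0, gs, eta, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
    w <- w0; m <- numeric(length(w0)); v <- numeric(length(w0))
    for (t in seq_along(gs)) {
      g <- gs[[t]]
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^t)
      vhat <- v / (1 - b2^t)
      w <- w - eta * mhat / (sqrt(vhat) + eps)
    }
    w
  }
  set.seed(10)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    w0 <- rnorm(n)
    gs <- replicate(7, rnorm(n), simplify = FALSE)
    st <- adam_init(n)
    w <- w0
    for (g in gs) {
      up <- adam_update(w, g, st, 0.01)
      w <- up$w; st <- up$state
    }
    expect_equal(w, adam_oracle(w0, gs, 0.01), tolerance = 1e-10)
  }
})

test_that("the learning-rate protocol hits its anchors", {
  cfg <- train_config()   # N_b = 256
  expect_equal(learning_rate(1, cfg), 2.56e-5)
  expect_equal(learning_rate(12, cfg), 2.56e-4)
  expect_equal(learning_rate(22, cfg), 2.56e-4 * exp(-0.6))
  # warm-up is linear
  expect_equal(learning_rate(6, cfg) - learning_rate(5, cfg),
               learning_rate(9, cfg) - learning_rate(8, cfg))
  # cool-down decays monotonically
  expect_true(all(diff(vapply(13:30, learning_rate, numeric(1), cfg = cfg)) < 0))
})

test_that("early stopping traces the stated rule", {
  run_until_stop <- function(f1s, patience, min_epochs, max_epochs) {
    for (n in seq_along(f1s)) {
      if (stop_training(f1s[1:n], patience, min_epochs, max_epochs)) return(n)
    }
    length(f1s)
  }
  # best at epoch 2, then five non-improving epochs: stops after epoch 7
  f1s <- c(0.5, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6)
  expect_identical(run_until_stop(f1s, 5, 1, 50), 7L)
  # monotonically improving: runs to the ceiling
  expect_identical(run_until_stop(seq(0.1, 0.9, length.out = 20), 5, 1, 10), 10L)
  # strictly worsening with the floor at 12: stops exactly there
  expect_identical(run_until_stop(seq(0.9, 0.1, length.out = 40), 5, 12, 50), 12L)
})

test_that("training reduces the loss and returns best-epoch weights", {
  set.seed(60)
  trn <- tone_windows(60)
  val <- tone_windows(20)
  cfg <- model_config(n_kernels = 8, n_conv_layers = 2,
                      stride_pattern = c(1, 2), p_dropout = 0, fc_hidden = 8,
                      num_classes = 3, input_len = 64)
  net <- build_network(cfg, seed = 1)
  res <- train_network(net, trn, valid_windows = val,
                       cfg = train_config(batch_size = 32, warmup_epochs = 2,
                                          lr_start_per_sample = 1e-6,
                                          lr_peak_per_sample = 3e-5,
                                          min_epochs = 4, max_epochs = 6,
                                          patience = 3, seed = 2),
                       rebalance = NULL)
  h <- res$history
  expect_gte(nrow(h), 4)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_identical(res$best_epoch, which.max(h$f1_mean))
  expect_gte(max(h$f1_mean), 0.9)   # pure tones are trivially separable
})

test_that("training with a fixed seed is reproducible", {
  set.seed(61)
  trn <- tone_windows(30)
  val <- tone_windows(10)
  cfg <- model_config(n_kernels = 6, n_conv_layers = 2,
                      stride_pattern = c(1, 2), p_dropout = 0.2, fc_hidden = 6,
                      num_classes = 3, input_len = 64)
  tcfg <- train_config(batch_size = 32, min_epochs = 2, max_epochs = 2,
                       seed = 3)
  r1 <- train_network(build_network(cfg, seed = 9), trn, valid_windows = val,
                      cfg = tcfg)
  r2 <- train_network(build_network(cfg, seed = 9), trn, valid_windows = val,
                      cfg = tcfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net$params, r2$net$params)
})

test_that("degenerate training inputs are rejected", {
  val <- tone_windows(5)
  cfg <- model_config(n_kernels = 4, n_conv_layers = 1, stride_pattern = 1,
                      fc_hidden = 4, num_classes = 3, input_len = 64)
  net <- build_network(cfg, seed = 1)
  empty <- tone_windows(1)
  empty$x <- empty$x[0, , drop = FALSE]; empty$labels <- character(0)
  expect_error(train_network(net, empty, valid_windows = val),
               "empty training")
  expect_error(train_network(net, val, valid_windows = empty),
               "empty validation")
})
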