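test_that("hypnogram model validates stochastic rows", {
  P <- diag(5)
  expect_s3_class(hypnogram_model(P), "hypnogram_model")
  P2 <- P; P2[1, 1] <- 0.5
  expect_error(hypnogram_model(P2), "stochastic")
  P3 <- P; P3[2, 1] <- -0.1; P3[2, 2] <- 1.1
  expect_error(hypnogram_model(P3), "stochastic")
})

test_that("absorbing chain and empty chain behave as required", {
  m <- hypnogram_model(diag(5), initial_distribution = c(1, 0, 0, 0, 0))
  h <- generate_hypnogram(m, 40, seed = 3)
  expect_identical(unique(h$labels), "WAKE")
  h0 <- generate_hypnogram(default_hypnogram_model(), 0, seed = 1)
  expect_identical(length(h0$labels), 0L)
})

test_that("sampled transition frequencies match the model within 3 SE", {
  model <- default_hypnogram_model()
  h <- generate_hypnogram(model, 50000, seed = 7)
  emp <- markov_matrix(h$labels, levels = stage_levels(5))
  P <- model$transition_matrix
  visits <- rowSums(emp$counts)
  for (i in 1:5) {
    if (visits[i] < 50) next
    se <- sqrt(P[i, ] * (1 - P[i, ]) / visits[i])
    expect_true(all(abs(emp$probs[i, ] - P[i, ]) <= 3 * se + 1e-12),
                info = paste("row", rownames(P)[i]))
  }
})

test_that("default chain's stationary distribution approximates lab frequencies", {
  pi_ <- stationary_distribution(default_hypnogram_model()$transition_matrix)
  expect_gt(pi_[["WAKE"]], 0.45); expect_lt(pi_[["WAKE"]], 0.65)
  expect_gt(pi_[["NREM"]], 0.30); expect_lt(pi_[["NREM"]], 0.45)
  expect_gt(pi_[["REM"]], 0.03);  expect_lt(pi_[["REM"]], 0.08)
  expect_gt(pi_[["PREREM"]], 0.01); expect_lt(pi_[["PREREM"]], 0.04)
  expect_gt(pi_[["ARTIFACT"]], 0.001); expect_lt(pi_[["ARTIFACT"]], 0.01)
  # physiological cycle: REM reached through pre-REM, not directly
  P <- default_hypnogram_model()$transition_matrix
  expect_lt(P["NREM", "REM"], 0.005)
  expect_gt(P["NREM", "PREREM"], P["NREM", "REM"])
  expect_gt(P["PREREM", "REM"], 0.2)
})

test_that("synthetic epochs carry the stage-defining spectral signatures", {
  z <- synthesize_epoch("NREM", stage_signal_model(c(0.5, 4), 0, 0),
                        fs = 64, seed = 1)
  expect_identical(z, numeric(640))

  nrem <- synthesize_epoch("NREM", fs = 64, seed = 2)
  expect_identical(length(nrem), 640L)
  pk <- peak_frequency(nrem, 64)
  expect_gte(pk, 0.5); expect_lte(pk, 4)

  rem <- synthesize_epoch("REM", fs = 64, seed = 3)
  expect_gt(bandpower(rem, 64, c(7, 8)) / bandpower(rem, 64, c(0.5, 4)), 1)

  art <- synthesize_epoch("ARTIFACT", fs = 992, seed = 4)
  expect_gt(max(abs(art)), 5 * sqrt(mean(art^2)))

  # pre-REM: spindle-band power elevated relative to plain NREM
  pre <- synthesize_epoch("PREREM", fs = 64, seed = 5)
  expect_gt(bandpower(pre, 64, c(10, 15)), bandpower(nrem, 64, c(10, 15)))

  expect_error(synthesize_epoch("REM", fs = 10), "Nyquist")
})

test_that("epoch synthesis is deterministic under a seed", {
  a <- synthesize_epoch("NREM", fs = 64, seed = 99)
  b <- synthesize_epoch("NREM", fs = 64, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, synthesize_epoch("NREM", fs = 64, seed = 100)))
})

test_that("generate_dataset writes aligned, reproducible subject files", {
  d1 <- file.path(withr::local_tempdir(), "a")
  man <- generate_dataset(d1, n_subjects = 3, n_epochs = 20, fs = 128, seed = 5)
  expect_identical(nrow(man), 3L)
  for (i in 1:3) {
    rec <- read_recording(man$recording[i])
    expect_identical(length(rec$samples), 20L * 10L * 128L)
    hyp <- read_hypnogram(man$hypnogram[i], n_epochs = n_epochs(rec))
    expect_identical(length(hyp$labels), 20L)
  }
  # distinct subject streams from one seed
  r1 <- read_recording(man$recording[1])$samples
  r2 <- read_recording(man$recording[2])$samples
  expect_false(identical(r1, r2))
  # byte-identical regeneration under the same seed
  d2 <- file.path(withr::local_tempdir(), "b")
  generate_dataset(d2, n_subjects = 3, n_epochs = 20, fs = 128, seed = 5)
  for (f in list.files(d1)) {
    if (f == "manifest.csv") next   # differs by path only
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("default chain yields Wake fractions in the plausible band", {
  h <- generate_hypnogram(default_hypnogram_model(), 20000, seed = 21)
  frac <- mean(h$labels == "WAKE")
  expect_gte(frac, 0.45); expect_lte(frac, 0.65)
})

test_that("bandpower features linearly separate the standard stages", {
  skip_if_not_installed("MASS")
  set.seed(33)
  stages <- rep(c("WAKE", "NREM", "REM"), each = 120)
  feats <- t(vapply(stages, function(s) {
    x <- synthesize_epoch(s, fs = 64)
    c(delta = log(bandpower(x, 64, c(0.5, 4))),
      theta = log(bandpower(x, 64, c(6, 9))),
      sigma = log(bandpower(x, 64, c(10, 15))),
      rms = log(sqrt(mean(x^2)) + 1e-12))
  }, numeric(4)))
  df <- data.frame(stage = factor(stages), feats)
  idx <- rep(c(TRUE, FALSE), length.out = nrow(df))
  fit <- MASS::lda(stage ~ ., data = df[idx, ])
  acc <- mean(predict(fit, df[!idx, ])$class == df$stage[!idx])
  expect_gte(acc, 0.9)
})
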