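test_that("valid-convolution chain reproduces the published dimensions", {
  lens <- conv_output_lengths(1920, 5, c(1, 2, 1, 2, 1, 2, 1, 2))
  expect_identical(lens, c(1916L, 956L, 952L, 474L, 470L, 233L, 229L, 113L))
  expect_identical(lens[8] * 96L, 10848L)
  expect_identical(conv_output_lengths(5, 5, 1), 1L)
  expect_error(conv_output_lengths(6, 5, c(2, 1)), "shorter than kernel")
})

test_that("network construction matches the architecture contract", {
  net5 <- build_network(model_config(num_classes = 5), seed = 1)
  p <- utils::relist(net5$params, net5$skeleton)
  expect_identical(length(p$fc2_b), 5L)
  expect_identical(dim(p$fc1_W), c(10848L, 80L))
  expect_identical(net5$flat_width, 10848L)
  # depth audit: first conv sees 1 channel, the rest 96
  expect_identical(nrow(p$conv[[1]]$W), 5L)
  for (l in 2:8) expect_identical(nrow(p$conv[[l]]$W), 480L)
  net3 <- build_network(model_config(num_classes = 3), seed = 1)
  p3 <- utils::relist(net3$params, net3$skeleton)
  expect_identical(length(p3$fc2_b), 3L)
})

test_that("inference produces a probability simplex with first-index ties", {
  cfg <- model_config(n_kernels = 8, n_conv_layers = 2, stride_pattern = c(1, 2),
                      fc_hidden = 6, num_classes = 5, input_len = 40)
  net <- build_network(cfg, seed = 2)
  set.seed(1)
  X <- matrix(rnorm(4 * 40), 4)
  pr <- predict_stages(net, X)
  expect_equal(rowSums(pr$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(pr$probs >= 0))
  # identical inputs give identical rows in inference mode
  X2 <- X[c(1, 1, 1), ]
  pr2 <- predict_stages(net, X2)
  expect_equal(pr2$probs[1, ], pr2$probs[2, ])
  expect_equal(pr2$probs[1, ], pr2$probs[3, ])
  # all-zero output layer: uniform probabilities, argmax ties to class 1
  p <- utils::relist(net$params, net$skeleton)
  p$fc2_W[] <- 0; p$fc2_b[] <- 0
  net$params <- unlist(p, use.names = FALSE)
  pr3 <- predict_stages(net, X)
  expect_equal(unname(pr3$probs), matrix(0.2, 4, 5), tolerance = 1e-6)
  expect_identical(unique(pr3$stage), "WAKE")
  expect_error(predict_stages(net, X[, 1:30, drop = FALSE]), "input length")
})

test_that("inference is permutation-equivariant across the batch", {
  cfg <- model_config(n_kernels = 6, n_conv_layers = 3,
                      stride_pattern = c(1, 2, 2), fc_hidden = 4,
                      num_classes = 3, input_len = 60)
  net <- build_network(cfg, seed = 3)
  set.seed(2)
  X <- matrix(rnorm(6 * 60), 6)
  perm <- c(4, 1, 6, 2, 5, 3)
  p1 <- predict_stages(net, X)$probs
  p2 <- predict_stages(net, X[perm, ])$probs
  expect_equal(p2, p1[perm, ], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences (double precision)", {
  cfg <- model_config(precision = "double", n_kernels = 4, kernel_len = 3,
                      n_conv_layers = 2, stride_pattern = c(1, 2),
                      p_dropout = 0, fc_hidden = 5, num_classes = 3,
                      input_len = 24)
  net <- build_network(cfg, seed = 42)
  set.seed(7)
  X <- matrix(rnorm(3 * cfg$input_len), 3)
  y <- c(1L, 2L, 3L)
  loss_at <- function(par) {
    net2 <- net; net2$params <- par
    fwd <- premscore:::nn_forward(net2, X, training = TRUE)
    classifier_loss(fwd$probs, y)
  }
  fwd <- premscore:::nn_forward(net, X, training = TRUE)
  g <- premscore:::nn_backward(net, fwd$cache, y)
  eps <- 1e-6
  num <- vapply(seq_along(net$params), function(i) {
    p1 <- net$params; p1[i] <- p1[i] + eps
    p2 <- net$params; p2[i] <- p2[i] - eps
    (loss_at(p1) - loss_at(p2)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g - num)), 1e-6)
  big <- abs(num) > 1e-6
  rel <- abs(g[big] - num[big]) / (abs(g[big]) + abs(num[big]))
  expect_lt(max(rel), 1e-5)
})

test_that("single- and double-precision forwards agree closely", {
  cfg_s <- model_config(precision = "single", n_kernels = 8,
                        n_conv_layers = 2, stride_pattern = c(1, 2),
                        fc_hidden = 6, num_classes = 3, input_len = 64)
  cfg_d <- cfg_s; cfg_d$precision <- "double"
  net <- build_network(cfg_s, seed = 4)
  net_d <- net; net_d$cfg <- cfg_d
  set.seed(3)
  X <- matrix(rnorm(5 * 64), 5)
  ps <- predict_stages(net, X)$probs
  pd <- predict_stages(net_d, X)$probs
  expect_equal(ps, pd, tolerance = 1e-4)
})

test_that("a 256-window batch runs through the full network quickly", {
  net <- build_network(model_config(num_classes = 5), seed = 1)
  set.seed(5)
  X <- matrix(rnorm(256 * 1920), 256)
  elapsed <- system.time(predict_stages(net, X, batch_size = 256))[["elapsed"]]
  expect_lt(elapsed, 5)
})
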