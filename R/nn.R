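# Network definition: config, construction, forward/backward glue ----------

#' Network architecture configuration
#'
#' The default architecture is a feature extractor of 8 valid (no-padding)
#' 1-D convolutional layers, each with 96 kernels of length 5, alternating
#' strides 1 and 2, every block being conv -> ReLU -> batch norm with
#' dropout on every second block; the flattened features (113 * 96 = 10848
#' under the defaults) pass through dropout, a fully connected hidden layer
#' of 80 ReLU units with dropout, and a softmax output layer of
#' `num_classes` units. The input is batch normalized before the first
#' convolution.
#'
#' @param n_kernels kernels per convolutional layer (default 96).
#' @param kernel_len kernel length (default 5).
#' @param n_conv_layers number of convolutional layers (default 8).
#' @param stride_pattern per-layer strides (default `c(1,2,1,2,1,2,1,2)`).
#' @param p_dropout dropout probability in `[0, 1)` (default 0.2).
#' @param fc_hidden hidden fully-connected width (default 80).
#' @param num_classes 3 or 5 output classes.
#' @param input_len window length in samples (default 1920).
#' @param precision `"single"` (default; the standard choice for
#'   convolutional networks) or `"double"` for the feature-extractor
#'   arithmetic. Parameters, the optimizer, and the classifier head always
#'   use double precision.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_kernels = 96, kernel_len = 5, n_conv_layers = 8,
                         stride_pattern = c(1, 2, 1, 2, 1, 2, 1, 2),
                         p_dropout = 0.2, fc_hidden = 80, num_classes = 5,
                         input_len = 1920, precision = c("single", "double")) {
  stopifnot(length(stride_pattern) == n_conv_layers,
            num_classes %in% c(3, 5),
            p_dropout >= 0, p_dropout < 1,
            n_kernels >= 1, kernel_len >= 1, fc_hidden >= 1, input_len >= kernel_len)
  structure(list(n_kernels = as.integer(n_kernels),
                 kernel_len = as.integer(kernel_len),
                 n_conv_layers = as.integer(n_conv_layers),
                 stride_pattern = as.integer(stride_pattern),
                 p_dropout = p_dropout, fc_hidden = as.integer(fc_hidden),
                 num_classes = as.integer(num_classes),
                 input_len = as.integer(input_len),
                 precision = match.arg(precision)),
            class = "model_config")
}

#' Per-layer output lengths of the convolutional chain
#'
#' Valid (no-padding) convolutions: `L_out = floor((L_in - kernel_len) /
#' stride) + 1` per layer. Under the default configuration on inputs of
#' 1920 samples the chain is 1916, 956, 952, 474, 470, 233, 229, 113, and
#' the flattened feature width is `113 * 96 = 10848`.
#'
#' @param input_len input length in samples.
#' @param kernel_len kernel length.
#' @param stride_pattern vector of per-layer strides.
#' @return Integer vector of per-layer output lengths.
#' @export
conv_output_lengths <- function(input_len, kernel_len, stride_pattern) {
  L <- as.integer(input_len)
  kernel_len <- as.integer(kernel_len)
  stride_pattern <- as.integer(stride_pattern)
  out <- integer(length(stride_pattern))
  for (i in seq_along(stride_pattern)) {
    if (L < kernel_len) {
      stop("intermediate length ", L, " shorter than kernel at layer ", i,
           call. = FALSE)
    }
    L <- (L - kernel_len) %/% stride_pattern[i] + 1L
    out[i] <- L
  }
  out
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Build an untrained network
#'
#' Weights use He initialization (`sd = sqrt(2 / fan_in)`) for convolutional
#' and fully connected layers; biases start at zero, batch-norm scale/shift
#' at 1/0.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the weight draw; `NULL` uses the current
#'   RNG stream.
#' @return An object of class `premscore_net` holding the trainable
#'   parameters (flat vector + skeleton), batch-norm running statistics,
#'   and the configuration.
#' @export
build_network <- function(cfg = model_config(), seed = NULL) {
  lens <- conv_output_lengths(cfg$input_len, cfg$kernel_len, cfg$stride_pattern)
  flat_width <- lens[length(lens)] * cfg$n_kernels
  with_seed(seed, {
    conv <- vector("list", cfg$n_conv_layers)
    for (l in seq_len(cfg$n_conv_layers)) {
      c_in <- if (l == 1) 1L else cfg$n_kernels
      fan_in <- c_in * cfg$kernel_len
      conv[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * cfg$n_kernels, 0, sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = cfg$n_kernels),
        b = numeric(cfg$n_kernels),
        gamma = rep(1, cfg$n_kernels),
        beta = numeric(cfg$n_kernels))
    }
    params <- list(
      bn0_gamma = 1, bn0_beta = 0,
      conv = conv,
      fc1_W = matrix(stats::rnorm(flat_width * cfg$fc_hidden, 0,
                                  sqrt(2 / flat_width)),
                     nrow = flat_width, ncol = cfg$fc_hidden),
      fc1_b = numeric(cfg$fc_hidden),
      fc2_W = matrix(stats::rnorm(cfg$fc_hidden * cfg$num_classes, 0,
                                  sqrt(2 / cfg$fc_hidden)),
                     nrow = cfg$fc_hidden, ncol = cfg$num_classes),
      fc2_b = numeric(cfg$num_classes))
    state <- list(
      bn0_rm = 0, bn0_rv = 1,
      conv_rm = rep(list(numeric(cfg$n_kernels)), cfg$n_conv_layers),
      conv_rv = rep(list(rep(1, cfg$n_kernels)), cfg$n_conv_layers))
    skeleton <- utils::as.relistable(params)
    flat <- unlist(skeleton, use.names = FALSE)
    structure(list(cfg = cfg, params = flat, skeleton = skeleton,
                   state = state, flat_width = flat_width,
                   l2_mask = l2_weight_mask(params)),
              class = "premscore_net")
  })
}

# TRUE for entries of connection-weight matrices (conv W, fc W): the L2
# penalty excludes biases and batch-norm parameters.
l2_weight_mask <- function(params) {
  mask <- utils::as.relistable(params)
  mask$bn0_gamma <- FALSE
  mask$bn0_beta <- FALSE
  for (l in seq_along(mask$conv)) {
    mask$conv[[l]]$W[] <- TRUE
    mask$conv[[l]]$b[] <- FALSE
    mask$conv[[l]]$gamma[] <- FALSE
    mask$conv[[l]]$beta[] <- FALSE
  }
  mask$fc1_W[] <- TRUE
  mask$fc1_b[] <- FALSE
  mask$fc2_W[] <- TRUE
  mask$fc2_b[] <- FALSE
  as.logical(unlist(mask, use.names = FALSE))
}

#' @export
print.premscore_net <- function(x, ...) {
  lens <- conv_output_lengths(x$cfg$input_len, x$cfg$kernel_len,
                              x$cfg$stride_pattern)
  cat(sprintf("<premscore_net> %d-class, input %d samples\n",
              x$cfg$num_classes, x$cfg$input_len))
  cat(sprintf("  %d conv layers x %d kernels (len %d), lengths: %s\n",
              x$cfg$n_conv_layers, x$cfg$n_kernels, x$cfg$kernel_len,
              paste(lens, collapse = " ")))
  cat(sprintf("  flatten %d -> fc %d -> softmax %d; %d parameters\n",
              x$flat_width, x$cfg$fc_hidden, x$cfg$num_classes,
              length(x$params)))
  invisible(x)
}

drop_layer_flags <- function(cfg) {
  # dropout on every second conv block (2, 4, 6, 8 under the defaults)
  as.integer(seq_len(cfg$n_conv_layers) %% 2 == 0)
}

# Forward pass. X: (N x input_len) matrix of windows. Returns class
# probabilities (N x num_classes) and, when training, the caches needed by
# nn_backward plus updated batch-norm running statistics.
nn_forward <- function(net, X, training = FALSE) {
  cfg <- net$cfg
  if (ncol(X) != cfg$input_len) {
    stop("wrong input length: ", ncol(X), " != ", cfg$input_len, call. = FALSE)
  }
  p <- utils::relist(net$params, net$skeleton)
  fe <- feat_forward(t(X), p, net$state, cfg$stride_pattern, cfg$kernel_len,
                     cfg$p_dropout, drop_layer_flags(cfg), training,
                     BN_EPS, BN_MOMENTUM,
                     identical(cfg$precision, "single"))
  Feat <- fe$out                       # (flat_width x N)
  N <- ncol(Feat)
  pd <- cfg$p_dropout
  if (training && pd > 0) {
    mF <- matrix((stats::runif(length(Feat)) >= pd) / (1 - pd), nrow(Feat), N)
    Fd <- Feat * mF
  } else {
    mF <- NULL
    Fd <- Feat
  }
  Z1 <- crossprod(p$fc1_W, Fd) + p$fc1_b   # (hidden x N)
  H1 <- pmax(Z1, 0)
  if (training && pd > 0) {
    m1 <- matrix((stats::runif(length(H1)) >= pd) / (1 - pd), nrow(H1), N)
    H1d <- H1 * m1
  } else {
    m1 <- NULL
    H1d <- H1
  }
  Z2 <- crossprod(p$fc2_W, H1d) + p$fc2_b  # (classes x N)
  Z2 <- sweep(Z2, 2, apply(Z2, 2, max))
  E <- exp(Z2)
  probs <- sweep(E, 2, colSums(E), "/")
  res <- list(probs = t(probs))
  if (training) {
    res$cache <- list(fe = fe$cache, X = X, p = p, Feat = Feat, mF = mF,
                      Fd = Fd, Z1 = Z1, H1 = H1, m1 = m1, H1d = H1d,
                      probs = probs)
    res$new_state <- fe$new_state
  }
  res
}

# Backward pass for the mean negative log-likelihood over the batch.
# labels_idx: integer class indices (1-based) per row of X.
# Returns the flat gradient vector (without the L2 term).
nn_backward <- function(net, cache, labels_idx) {
  cfg <- net$cfg
  N <- length(labels_idx)
  Y <- matrix(0, cfg$num_classes, N)
  Y[cbind(labels_idx, seq_len(N))] <- 1
  dZ2 <- (cache$probs - Y) / N                 # (classes x N)
  g <- cache$p                                  # same skeleton, filled below
  g$fc2_W <- cache$H1d %*% t(dZ2)
  g$fc2_b <- rowSums(dZ2)
  dH1d <- cache$p$fc2_W %*% dZ2
  dH1 <- if (is.null(cache$m1)) dH1d else dH1d * cache$m1
  dZ1 <- dH1 * (cache$Z1 > 0)
  g$fc1_W <- cache$Fd %*% t(dZ1)
  g$fc1_b <- rowSums(dZ1)
  dFd <- cache$p$fc1_W %*% dZ1
  dFeat <- if (is.null(cache$mF)) dFd else dFd * cache$mF
  fb <- feat_backward(dFeat, t(cache$X), cache$p, cache$fe,
                      cfg$stride_pattern, cfg$kernel_len, BN_EPS,
                      identical(cfg$precision, "single"))
  g$bn0_gamma <- fb$bn0_gamma
  g$bn0_beta <- fb$bn0_beta
  for (l in seq_along(g$conv)) {
    g$conv[[l]]$W <- fb$conv[[l]]$W
    g$conv[[l]]$b <- fb$conv[[l]]$b
    g$conv[[l]]$gamma <- fb$conv[[l]]$gamma
    g$conv[[l]]$beta <- fb$conv[[l]]$beta
  }
  unlist(g, use.names = FALSE)
}

#' Predict stage probabilities for a batch of windows
#'
#' Runs the network in inference mode (dropout off, batch norm using running
#' statistics). The predicted stage is the argmax of the probability vector,
#' with ties broken towards the lowest class index.
#'
#' @param net a `premscore_net`.
#' @param X matrix of windows (one per row, `input_len` columns) or a
#'   `context_windows` object.
#' @param levels stage names corresponding to the output units; default is
#'   the 5- or 3-class vocabulary.
#' @param batch_size forward-pass batch size (memory control).
#' @return A list with `probs` (N x classes matrix) and `stage` (character).
#' @export
predict_stages <- function(net, X, levels = stage_levels(net$cfg$num_classes),
                           batch_size = 512L) {
  if (inherits(X, "context_windows")) X <- X$x
  n <- nrow(X)
  probs <- matrix(0, n, net$cfg$num_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    probs[i:j, ] <- nn_forward(net, X[i:j, , drop = FALSE])$probs
    i <- j + 1L
  }
  colnames(probs) <- levels
  stage <- levels[max.col(probs, ties.method = "first")]
  list(probs = probs, stage = stage)
}
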