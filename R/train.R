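# Training: loss, Adam, gradient clipping, LR protocol, early stopping -----

#' Training configuration
#'
#' Defaults follow the standard protocol: minibatches of 256, Adam with
#' `beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-8`, global gradient-norm
#' clipping at `theta = 0.1`, a learning rate warmed up linearly from
#' `1e-7 * N_b` to `1e-6 * N_b` over the first 12 training epochs and then
#' cooled down exponentially at rate `alpha = 0.06`, L2 strength `1e-4`,
#' training for at least 12 and at most 50 epochs with early stopping after
#' 5 epochs without improvement of the validation macro F1.
#'
#' @param batch_size minibatch size `N_b`.
#' @param l2_lambda L2 regularization strength `lambda`.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param clip_norm gradient-norm clipping threshold `theta`.
#' @param warmup_epochs warm-up length in training epochs.
#' @param lr_start_per_sample,lr_peak_per_sample per-sample learning rates
#'   at the start and peak of warm-up; the applied rate is scaled by
#'   `batch_size`.
#' @param cooldown_rate exponential cool-down rate `alpha`.
#' @param min_epochs,max_epochs epoch floor and ceiling.
#' @param patience consecutive non-improving epochs before stopping.
#' @param seed RNG seed for the whole training run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 256, l2_lambda = 1e-4, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-8, clip_norm = 0.1,
                         warmup_epochs = 12, lr_start_per_sample = 1e-7,
                         lr_peak_per_sample = 1e-6, cooldown_rate = 0.06,
                         min_epochs = 12, max_epochs = 50, patience = 5,
                         seed = 1) {
  stopifnot(batch_size >= 1, l2_lambda >= 0,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            epsilon > 0, clip_norm > 0, warmup_epochs >= 1,
            min_epochs <= max_epochs, patience >= 1)
  structure(list(batch_size = as.integer(batch_size), l2_lambda = l2_lambda,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 clip_norm = clip_norm, warmup_epochs = as.integer(warmup_epochs),
                 lr_start_per_sample = lr_start_per_sample,
                 lr_peak_per_sample = lr_peak_per_sample,
                 cooldown_rate = cooldown_rate,
                 min_epochs = as.integer(min_epochs),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = seed),
            class = "train_config")
}

#' Classification loss: negative log-likelihood with L2 penalty
#'
#' `-(1/N_b) * sum(log p_k,ck) + (lambda / (2 N_b)) * sum(w^2)`, where the
#' penalty runs over connection weights only (no biases, no batch-norm
#' parameters). Probabilities are clamped at `1e-12` before the log.
#'
#' @param probs matrix of class probabilities, one row per batch item.
#' @param classes integer true-class indices (1-based), one per row.
#' @param weights numeric vector of penalized weights (may be empty).
#' @param lambda L2 strength.
#' @param n_batch batch size `N_b`; defaults to `nrow(probs)`.
#' @return Scalar loss.
#' @export
classifier_loss <- function(probs, classes, weights = numeric(0),
                            lambda = 0, n_batch = nrow(probs)) {
  p <- pmax(probs[cbind(seq_len(nrow(probs)), classes)], 1e-12)
  -sum(log(p)) / n_batch + lambda / (2 * n_batch) * sum(weights^2)
}

#' Clip a gradient vector to a maximum norm
#'
#' Rescales `g` by `theta / ||g||` when its Euclidean norm exceeds `theta`;
#' otherwise `g` is returned unchanged.
#'
#' @param g numeric gradient vector.
#' @param theta positive clipping threshold.
#' @return Clipped gradient.
#' @export
clip_gradient <- function(g, theta) {
  nrm <- sqrt(sum(g^2))
  if (nrm > theta) g * (theta / nrm) else g
}

#' Initialize Adam optimizer state
#'
#' @param n number of parameters.
#' @return List with first/second moment vectors `m`, `v` and step count `t`.
#' @export
adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

#' One Adam update step
#'
#' Exponential moving averages of the gradient and squared gradient with
#' bias correction: `m_t = (1-b1) g + b1 m_{t-1}`, `v_t = (1-b2) g^2 +
#' b2 v_{t-1}`, `w <- w - eta * mhat / (sqrt(vhat) + epsilon)`.
#'
#' @param w parameter vector.
#' @param g gradient vector (clipping, if any, already applied).
#' @param state optimizer state from [adam_init()].
#' @param eta learning rate.
#' @param beta1,beta2,epsilon Adam constants.
#' @return List with updated `w` and `state`.
#' @export
adam_update <- function(w, g, state, eta, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8) {
  t <- state$t + 1L
  m <- (1 - beta1) * g + beta1 * state$m
  v <- (1 - beta2) * g^2 + beta2 * state$v
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(w = w - eta * mhat / (sqrt(vhat) + epsilon),
       state = list(m = m, v = v, t = t))
}

#' Learning rate at a given training epoch
#'
#' Warm-up: linear from `lr_start_per_sample * N_b` at epoch 1 to
#' `lr_peak_per_sample * N_b` at epoch `warmup_epochs`. Cool-down
#' (epochs beyond warm-up): `peak * exp(-alpha * (i - warmup_epochs))`.
#'
#' @param epoch training epoch index (1-based).
#' @param cfg a [train_config()].
#' @return Scalar learning rate `eta`.
#' @export
learning_rate <- function(epoch, cfg) {
  stopifnot(epoch >= 1)
  nb <- cfg$batch_size
  peak <- cfg$lr_peak_per_sample * nb
  if (epoch <= cfg$warmup_epochs) {
    start <- cfg$lr_start_per_sample * nb
    if (cfg$warmup_epochs == 1) return(peak)
    start + (peak - start) * (epoch - 1) / (cfg$warmup_epochs - 1)
  } else {
    peak * exp(-cfg$cooldown_rate * (epoch - cfg$warmup_epochs))
  }
}

#' Early-stopping decision
#'
#' Training stops at the end of epoch `length(f1_history)` when the epoch
#' ceiling is reached, or when at least `min_epochs` have run and the best
#' validation macro F1 has not strictly improved for `patience` consecutive
#' epochs (counted from the best epoch).
#'
#' @param f1_history validation macro-F1 values, one per completed epoch.
#' @param patience consecutive non-improving epochs tolerated.
#' @param min_epochs epoch floor.
#' @param max_epochs epoch ceiling.
#' @return Logical: stop now?
#' @export
stop_training <- function(f1_history, patience, min_epochs, max_epochs) {
  n <- length(f1_history)
  if (n >= max_epochs) return(TRUE)
  if (n < min_epochs) return(FALSE)
  (n - which.max(f1_history)) >= patience
}

#' Train a network on labeled context windows
#'
#' Implements the full protocol: per-epoch rebalanced training views (fresh
#' multiset each epoch), optional stochastic augmentation of every window
#' entering the network, minibatch Adam with global gradient-norm clipping,
#' the warm-up/cool-down learning-rate schedule, per-epoch validation macro
#' F1, and early stopping returning the weights of the best epoch.
#'
#' @param net a `premscore_net` from [build_network()].
#' @param windows training `context_windows` (or matrix via `labels`).
#' @param labels training stage labels (default `windows$labels`).
#' @param valid_windows,valid_labels validation set (never rebalanced or
#'   augmented).
#' @param cfg a [train_config()].
#' @param rebalance a [rebalance_spec()], profile name (`"reb1"`, `"reb2"`),
#'   or `NULL` for no rebalancing.
#' @param augment an [augmentation_params()] or `NULL`; all-zero strengths
#'   disable augmentation.
#' @param verbose print one line per epoch.
#' @return A list with `net` (best-epoch weights and state), `history`
#'   (data.frame: epoch, lr, train_loss, per-class validation F1, macro F1)
#'   and `best_epoch`.
#' @export
train_network <- function(net, windows, labels = NULL,
                          valid_windows, valid_labels = NULL,
                          cfg = train_config(), rebalance = NULL,
                          augment = NULL, verbose = FALSE) {
  if (is.null(labels)) labels <- windows$labels
  if (is.null(valid_labels)) valid_labels <- valid_windows$labels
  if (length(labels) == 0) stop("empty training set", call. = FALSE)
  if (length(valid_labels) == 0) stop("empty validation set", call. = FALSE)
  levels <- stage_levels(net$cfg$num_classes)
  lab_idx <- match(labels, levels)
  if (anyNA(lab_idx)) stop("training labels outside the model vocabulary",
                           call. = FALSE)
  if (is.character(rebalance)) rebalance <- rebalance_profile(rebalance)
  use_aug <- !is.null(augment) &&
    any(unlist(augment[c("a_a", "a_f", "a_s", "a_t")]) > 0)

  set.seed(cfg$seed)
  view <- make_training_view(labels, rebalance)
  opt <- adam_init(length(net$params))
  history <- NULL
  best_f1 <- -Inf
  best_params <- net$params
  best_state <- net$state
  best_epoch <- 0L
  f1_hist <- numeric(0)

  repeat {
    epoch <- length(f1_hist) + 1L
    eta <- learning_rate(epoch, cfg)
    idx <- view()
    losses <- numeric(0)
    i <- 1L
    while (i <= length(idx)) {
      j <- min(i + cfg$batch_size - 1L, length(idx))
      bidx <- idx[i:j]
      X <- if (use_aug) {
        t(vapply(bidx, function(k) augment_window(windows, k, augment),
                 numeric(net$cfg$input_len)))
      } else {
        windows$x[bidx, , drop = FALSE]
      }
      fwd <- nn_forward(net, X, training = TRUE)
      net$state <- fwd$new_state
      w <- net$params
      losses <- c(losses, classifier_loss(fwd$probs, lab_idx[bidx],
                                          weights = w[net$l2_mask],
                                          lambda = cfg$l2_lambda,
                                          n_batch = length(bidx)))
      g <- nn_backward(net, fwd$cache, lab_idx[bidx])
      g[net$l2_mask] <- g[net$l2_mask] +
        (cfg$l2_lambda / length(bidx)) * w[net$l2_mask]
      g <- clip_gradient(g, cfg$clip_norm)
      upd <- adam_update(w, g, opt, eta, cfg$beta1, cfg$beta2, cfg$epsilon)
      net$params <- upd$w
      opt <- upd$state
      i <- j + 1L
    }

    pred <- predict_stages(net, valid_windows, levels = levels)
    ev <- confusion(valid_labels, pred$stage, levels = levels)
    f1_hist <- c(f1_hist, ev$f1_mean)
    row <- data.frame(epoch = epoch, lr = eta, train_loss = mean(losses),
                      t(ev$f1), f1_mean = ev$f1_mean)
    names(row)[4:(3 + length(levels))] <- paste0("f1_", levels)
    history <- rbind(history, row)
    if (verbose) {
      message(sprintf("epoch %d: lr %.3g, loss %.4f, valid macro F1 %.4f",
                      epoch, eta, mean(losses), ev$f1_mean))
    }
    if (ev$f1_mean > best_f1) {
      best_f1 <- ev$f1_mean
      best_params <- net$params
      best_state <- net$state
      best_epoch <- epoch
    }
    if (stop_training(f1_hist, cfg$patience, cfg$min_epochs, cfg$max_epochs)) {
      break
    }
  }
  net$params <- best_params
  net$state <- best_state
  list(net = net, history = history, best_epoch = best_epoch)
}
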