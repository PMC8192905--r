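# User-facing fitting interface --------------------------------------------

#' Fit a sleep-stage classifier
#'
#' The main modelling entry point: trains the convolutional sleep-stage
#' classifier on labeled context windows and returns a fitted-model object
#' with the usual methods (`print`, `summary`, `predict`, `plot`).
#'
#' In `"extended5"` mode all five stages (Wake, NREM, pre-REM, REM,
#' artifact) are scored and the `"reb1"` rebalancing profile is the default;
#' in `"standard3"` mode pre-REM windows are relabeled NREM, artifact
#' windows are dropped from both sets, the output layer has three units and
#' `"reb2"` is the default profile.
#'
#' @param windows training `context_windows` (from [make_windows()] /
#'   [bind_windows()]).
#' @param valid_windows held-out validation `context_windows` used for
#'   model selection (macro F1); never rebalanced or augmented.
#' @param mode `"extended5"` or `"standard3"`.
#' @param model a [model_config()]; `num_classes` is forced to match `mode`.
#' @param train a [train_config()].
#' @param augment an [augmentation_params()] or `NULL` (off).
#' @param rebalance a [rebalance_spec()], a profile name, `NULL` for the
#'   mode's default profile, or `NA` to disable rebalancing.
#' @param verbose print one line per training epoch.
#' @return An object of class `premscore` with components `net`, `levels`,
#'   `mode`, `history`, `best_epoch`, and the configurations used.
#' @export
premscore_fit <- function(windows, valid_windows,
                          mode = c("extended5", "standard3"),
                          model = model_config(), train = train_config(),
                          augment = NULL, rebalance = NULL,
                          verbose = FALSE) {
  mode <- match.arg(mode)
  num_classes <- if (mode == "standard3") 3L else 5L
  model$num_classes <- num_classes
  if (is.null(rebalance)) {
    rebalance <- if (mode == "standard3") "reb2" else "reb1"
  } else if (length(rebalance) == 1 && is.na(rebalance)) {
    rebalance <- NULL
  }
  if (mode == "standard3") {
    windows <- reduce_windows(windows)
    valid_windows <- reduce_windows(valid_windows)
  }
  if (ncol(windows$x) != model$input_len) {
    stop("window length ", ncol(windows$x), " does not match input_len ",
         model$input_len, call. = FALSE)
  }
  net <- build_network(model, seed = train$seed)
  res <- train_network(net, windows, valid_windows = valid_windows,
                       cfg = train, rebalance = rebalance, augment = augment,
                       verbose = verbose)
  structure(list(net = res$net, levels = stage_levels(num_classes),
                 mode = mode, history = res$history,
                 best_epoch = res$best_epoch, model_config = model,
                 train_config = train, augment = augment,
                 call = match.call()),
            class = "premscore")
}

# Apply the 3-class reduction to a window set: PREREM -> NREM, ARTIFACT
# windows removed.
reduce_windows <- function(cw) {
  keep <- cw$labels != "ARTIFACT"
  cw$x <- cw$x[keep, , drop = FALSE]
  cw$labels <- cw$labels[keep]
  cw$labels[cw$labels == "PREREM"] <- "NREM"
  cw$starts <- cw$starts[keep]
  if (!is.null(cw$source_index)) cw$source_index <- cw$source_index[keep]
  cw
}

#' @export
print.premscore <- function(x, ...) {
  cat(sprintf("Sleep-stage classifier (%s, %d classes)\n",
              x$mode, length(x$levels)))
  print(x$net)
  cat(sprintf("  trained %d epochs; best validation macro F1 %.4f at epoch %d\n",
              nrow(x$history), max(x$history$f1_mean), x$best_epoch))
  invisible(x)
}

#' @export
summary.premscore <- function(object, ...) {
  best <- object$history[object$best_epoch, , drop = FALSE]
  out <- list(mode = object$mode, levels = object$levels,
              n_epochs = nrow(object$history),
              best_epoch = object$best_epoch,
              best_f1 = best$f1_mean,
              best_per_class = unlist(best[grep("^f1_", names(best))]),
              history = object$history)
  class(out) <- "summary.premscore"
  out
}

#' @export
print.summary.premscore <- function(x, ...) {
  cat(sprintf("Sleep-stage classifier, %s mode (%s)\n", x$mode,
              paste(x$levels, collapse = ", ")))
  cat(sprintf("Trained for %d epochs; best epoch %d (validation macro F1 %.4f)\n",
              x$n_epochs, x$best_epoch, x$best_f1))
  cat("Per-class validation F1 at the best epoch:\n")
  print(round(x$best_per_class, 4))
  invisible(x)
}

#' Predict sleep stages with a fitted classifier
#'
#' @param object a fitted `premscore` model.
#' @param newdata a `context_windows` object, a window matrix, or an
#'   `eeg_recording` (which is preprocessed and windowed first, using
#'   `preprocess`).
#' @param type `"class"` for stage labels, `"prob"` for the probability
#'   matrix, `"both"` for a data.frame with `epoch_index`, `label` and one
#'   probability column per stage.
#' @param preprocess a [preprocess_config()] used when `newdata` is a raw
#'   recording.
#' @param ... unused.
#' @return See `type`.
#' @export
predict.premscore <- function(object, newdata, type = c("class", "prob", "both"),
                              preprocess = preprocess_config(), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "eeg_recording")) {
    rec <- if (abs(newdata$fs - preprocess$target_fs) > 1e-9) {
      preprocess_recording(newdata, preprocess)
    } else newdata
    n_ep <- n_epochs(rec, preprocess$epoch_len_s)
    hyp <- hypnogram(rep("WAKE", n_ep), preprocess$epoch_len_s)  # placeholder
    newdata <- make_windows(rec, hyp, preprocess)
  }
  pr <- predict_stages(object$net, newdata, levels = object$levels)
  switch(type,
         class = pr$stage,
         prob = pr$probs,
         both = data.frame(epoch_index = seq_along(pr$stage) - 1L,
                           label = pr$stage,
                           stats::setNames(as.data.frame(pr$probs),
                                           paste0("p_", object$levels))))
}

#' Plot training history of a fitted classifier
#'
#' Two panels: the learning-rate protocol and the validation F1 curves
#' (per class and macro) over training epochs.
#'
#' @param x a fitted `premscore` model.
#' @param ... unused.
#' @export
plot.premscore <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$lr, type = "b", log = "y", xlab = "epoch",
                 ylab = "learning rate", main = "learning-rate protocol")
  f1_cols <- grep("^f1_", names(h), value = TRUE)
  graphics::matplot(h$epoch, as.matrix(h[c(f1_cols, "f1_mean")]),
                    type = "l", lty = c(rep(2, length(f1_cols)), 1),
                    lwd = c(rep(1, length(f1_cols)), 2),
                    xlab = "epoch", ylab = "validation F1",
                    main = "validation F1", ylim = c(0, 1))
  graphics::legend("bottomright", legend = c(sub("^f1_", "", f1_cols), "macro"),
                   lty = c(rep(2, length(f1_cols)), 1),
                   lwd = c(rep(1, length(f1_cols)), 2),
                   col = seq_len(length(f1_cols) + 1), cex = 0.7)
  invisible(x)
}
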