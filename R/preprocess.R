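# Preprocessing: anti-alias filter, resampling, context windows ------------

#' Preprocessing configuration
#'
#' Defaults implement the standard pipeline: a 4th-order Butterworth low-pass
#' at 25.6 Hz applied forward and backward (zero phase), linear-interpolation
#' downsampling to 64 Hz, 10-s epochs, and 3-epoch context windows, giving
#' windows of `3 * 10 * 64 = 1920` samples.
#'
#' @param filter_order Butterworth order (default 4).
#' @param critical_hz low-pass critical frequency in Hz (default 25.6).
#' @param target_fs output sampling rate in Hz (default 64).
#' @param epoch_len_s epoch length in seconds (default 10).
#' @param context_epochs odd number of consecutive epochs per window
#'   (default 3).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(filter_order = 4, critical_hz = 25.6,
                              target_fs = 64, epoch_len_s = 10,
                              context_epochs = 3) {
  stopifnot(filter_order > 0, critical_hz > 0, target_fs > 0,
            epoch_len_s > 0, context_epochs > 0, context_epochs %% 2 == 1)
  structure(list(filter_order = as.integer(filter_order),
                 critical_hz = critical_hz, target_fs = target_fs,
                 epoch_len_s = epoch_len_s,
                 context_epochs = as.integer(context_epochs)),
            class = "preprocess_config")
}

#' Zero-phase Butterworth anti-alias filter
#'
#' Applies the low-pass filter in a forward and a backward pass, so the net
#' phase response is zero and the effective magnitude response is the squared
#' single-pass Butterworth magnitude. Edges are padded with odd reflection of
#' length `3 * (filter_order + 1)` before filtering; the contract on the
#' magnitude response holds on interior samples (edge transients decay over a
#' few filter time constants).
#'
#' @param x numeric signal.
#' @param fs sampling rate of `x` in Hz.
#' @param cfg a [preprocess_config()].
#' @return Filtered signal, same length as `x`.
#' @export
antialias_filter <- function(x, fs, cfg = preprocess_config()) {
  np <- 3L * (cfg$filter_order + 1L)
  if (length(x) <= np) {
    stop("signal too short for edge padding (need > ", np, " samples)",
         call. = FALSE)
  }
  bf <- signal::butter(cfg$filter_order, 2 * cfg$critical_hz / fs, type = "low")
  n <- length(x)
  front <- 2 * x[1] - x[(np + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - np)]
  xp <- c(front, x, back)
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(np + 1L):(np + n)]
}

#' Linear-interpolation resampling
#'
#' Output sample `k` (0-based) is the linear interpolant of `x` at time
#' `k / fs_out`, with the grid anchored at `t = 0`. The output length is
#' `floor((length(x) - 1) * fs_out / fs_in) + 1`, i.e. the number of output
#' grid points that fall inside the input's time span.
#'
#' @param x numeric signal (non-empty).
#' @param fs_in input sampling rate in Hz.
#' @param fs_out output sampling rate in Hz.
#' @return Resampled signal.
#' @export
resample_linear <- function(x, fs_in, fs_out) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  stopifnot(fs_in > 0, fs_out > 0)
  if (length(x) == 1) return(x)
  n_out <- floor((length(x) - 1) * fs_out / fs_in) + 1
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Preprocess a recording for the classifier
#'
#' Filters at the native rate, then resamples to `target_fs`. Filtering
#' before resampling prevents aliasing; epoching afterwards (see
#' [make_windows()]) sidesteps non-integer epoch lengths at native rates
#' such as 992.06 Hz.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [preprocess_config()].
#' @return An `eeg_recording` at `cfg$target_fs`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  y <- antialias_filter(rec$samples, rec$fs, cfg)
  z <- resample_linear(y, rec$fs, cfg$target_fs)
  recording(z, cfg$target_fs, subject_id = rec$subject_id,
            channel = rec$channel)
}

#' Build 3-epoch context windows from a preprocessed recording
#'
#' One window per scored epoch: the window for epoch `k` covers epochs
#' `k - 1, k, k + 1` (under the default 3-epoch context), and its target is
#' the middle epoch's label. At the recording boundaries the missing
#' neighbour epoch is replaced by a replicate of the edge epoch, so that
#' predictions cover every scored epoch.
#'
#' @param rec an `eeg_recording` already filtered and resampled to
#'   `cfg$target_fs`.
#' @param hyp the aligned `hypnogram`.
#' @param cfg a [preprocess_config()].
#' @return An object of class `context_windows`: a list with `x` (matrix,
#'   one window per row, `T = context_epochs * epoch_len_s * target_fs`
#'   columns), `labels`, `starts` (1-based sample index of each window's
#'   first sample in the source signal; may be non-positive at the left
#'   edge), `signal` (the full preprocessed signal, kept for augmentation),
#'   `fs`, `samples_per_epoch`, and `subject_id`.
#' @export
make_windows <- function(rec, hyp, cfg = preprocess_config()) {
  if (abs(rec$fs - cfg$target_fs) > 1e-9) {
    stop("recording must be resampled to target_fs first", call. = FALSE)
  }
  spe <- as.integer(round(cfg$epoch_len_s * cfg$target_fs))
  n_ep <- length(hyp$labels)
  if (floor(length(rec$samples) / spe) != n_ep) {
    stop(sprintf(
      "misalignment: %d whole epochs in recording but %d labels",
      floor(length(rec$samples) / spe), n_ep), call. = FALSE)
  }
  half <- (cfg$context_epochs - 1L) %/% 2L
  T_len <- cfg$context_epochs * spe
  x <- matrix(0, nrow = n_ep, ncol = T_len)
  starts <- integer(n_ep)
  sig <- rec$samples
  for (k in seq_len(n_ep)) {
    eps <- pmin(pmax((k - half):(k + half), 1L), n_ep)  # edge replication
    idx <- unlist(lapply(eps, function(e) ((e - 1L) * spe + 1L):(e * spe)),
                  use.names = FALSE)
    x[k, ] <- sig[idx]
    starts[k] <- (k - 1L - half) * spe + 1L
  }
  structure(list(x = x, labels = hyp$labels, starts = starts, signal = sig,
                 fs = cfg$target_fs, samples_per_epoch = spe,
                 subject_id = rec$subject_id),
            class = "context_windows")
}

#' @export
print.context_windows <- function(x, ...) {
  cat(sprintf("<context_windows> %d windows of %d samples (%g Hz), subject %s\n",
              nrow(x$x), ncol(x$x), x$fs, x$subject_id))
  invisible(x)
}

#' Concatenate context-window sets from several recordings
#'
#' Used to pool training subjects. Window provenance (per-window source
#' signal) is preserved for augmentation.
#'
#' @param ... `context_windows` objects.
#' @return A `context_windows` object whose `signal` field is a list of
#'   source signals with a per-window source index.
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1L && is.list(ws[[1]]) && !inherits(ws[[1]], "context_windows")) {
    ws <- ws[[1]]
  }
  stopifnot(length(ws) >= 1)
  sigs <- lapply(ws, function(w) if (is.list(w$signal)) w$signal else list(w$signal))
  src_of <- unlist(lapply(seq_along(ws), function(i) {
    base <- if (i == 1) 0L else sum(vapply(sigs[seq_len(i - 1)], length, 1L))
    s <- if (!is.null(ws[[i]]$source_index)) ws[[i]]$source_index else
      rep(1L, nrow(ws[[i]]$x))
    base + s
  }))
  structure(list(
    x = do.call(rbind, lapply(ws, `[[`, "x")),
    labels = unlist(lapply(ws, `[[`, "labels"), use.names = FALSE),
    starts = unlist(lapply(ws, `[[`, "starts"), use.names = FALSE),
    signal = do.call(c, sigs),
    source_index = src_of,
    fs = ws[[1]]$fs,
    samples_per_epoch = ws[[1]]$samples_per_epoch,
    subject_id = paste(vapply(ws, `[[`, "", "subject_id"), collapse = "+")),
    class = "context_windows")
}

# Source signal for window i (handles single- and multi-source sets).
window_source <- function(cw, i) {
  if (is.list(cw$signal)) {
    j <- if (!is.null(cw$source_index)) cw$source_index[i] else 1L
    cw$signal[[j]]
  } else {
    cw$signal
  }
}
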