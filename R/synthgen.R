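# Synthetic stage-labeled EEG generator ------------------------------------

# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Per-stage synthetic signal model
#'
#' Parameters of the oscillatory caricature used for one sleep stage:
#' a band-limited oscillation over pink (1/f) background noise, optionally
#' decorated with transient bursts (spindle-like events for pre-REM, clipped
#' spikes for artifact epochs).
#'
#' @param band_hz length-2 numeric, oscillation band (Hz), `0 < low < high`.
#' @param osc_amp oscillation amplitude (microvolts, peak), >= 0.
#' @param noise_amp pink-noise RMS amplitude (microvolts), >= 0.
#' @param burst_rate expected bursts per 10-s epoch, >= 0.
#' @param burst_len_s burst duration (s), < 10.
#' @param burst_amp burst amplitude (microvolts, peak), >= 0.
#' @return An object of class `stage_signal_model`.
#' @export
stage_signal_model <- function(band_hz, osc_amp, noise_amp,
                               burst_rate = 0, burst_len_s = 1.5,
                               burst_amp = 0) {
  stopifnot(length(band_hz) == 2, band_hz[1] > 0, band_hz[2] > band_hz[1],
            osc_amp >= 0, noise_amp >= 0, burst_rate >= 0,
            burst_len_s > 0, burst_len_s < 10, burst_amp >= 0)
  structure(list(band_hz = as.numeric(band_hz), osc_amp = osc_amp,
                 noise_amp = noise_amp, burst_rate = burst_rate,
                 burst_len_s = burst_len_s, burst_amp = burst_amp),
            class = "stage_signal_model")
}

#' Default per-stage signal models
#'
#' Spectral targets follow the scoring conventions for mice: NREM is
#' dominated by 0.5--4 Hz delta waves, REM by 7--8 Hz theta, pre-REM shows
#' spindle-like 10--15 Hz bursts over emerging theta, Wake is low-amplitude
#' broadband activity, and artifact epochs carry clipped spike transients.
#' Amplitudes are synthetic choices in a plausible microvolt range.
#'
#' @return Named list of [stage_signal_model()] objects, one per stage.
#' @export
default_signal_models <- function() {
  list(
    WAKE     = stage_signal_model(c(4, 16), osc_amp = 8,  noise_amp = 22),
    NREM     = stage_signal_model(c(0.5, 4), osc_amp = 90, noise_amp = 25),
    PREREM   = stage_signal_model(c(7, 8),  osc_amp = 45, noise_amp = 25,
                                  burst_rate = 3, burst_len_s = 1.5,
                                  burst_amp = 140),
    REM      = stage_signal_model(c(7, 8),  osc_amp = 60, noise_amp = 15),
    ARTIFACT = stage_signal_model(c(4, 16), osc_amp = 8,  noise_amp = 22,
                                  burst_rate = 2, burst_len_s = 0.15,
                                  burst_amp = 600)
  )
}

#' Markov hypnogram model
#'
#' Row-stochastic transition matrix and initial distribution over the 5-class
#' stage vocabulary, used generatively to sample synthetic hypnograms.
#'
#' @param transition_matrix 5x5 row-stochastic matrix, rows/columns in the
#'   order `stage_levels(5)`.
#' @param initial_distribution probability vector over the five stages;
#'   default is the chain's stationary distribution.
#' @return An object of class `hypnogram_model`.
#' @export
hypnogram_model <- function(transition_matrix, initial_distribution = NULL) {
  P <- as.matrix(transition_matrix)
  if (!all(dim(P) == c(5L, 5L))) stop("transition_matrix must be 5x5", call. = FALSE)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("model error: transition matrix rows must be stochastic", call. = FALSE)
  }
  dimnames(P) <- list(STAGES5, STAGES5)
  if (is.null(initial_distribution)) {
    initial_distribution <- stationary_distribution(P)
  }
  pi0 <- as.numeric(initial_distribution)
  if (length(pi0) != 5L || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-9) {
    stop("model error: initial distribution must be a probability vector",
         call. = FALSE)
  }
  names(pi0) <- STAGES5
  structure(list(transition_matrix = P, initial_distribution = pi0),
            class = "hypnogram_model")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P square row-stochastic matrix.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  stats::setNames(v, rownames(P))
}

#' Default hypnogram model
#'
#' The transition structure enforces the physiological sleep cycle: sleep
#' onset Wake -> NREM, REM entered almost exclusively through pre-REM
#' (direct NREM -> REM is nearly zero), REM exiting mostly to Wake, and rare
#' artifact epochs from any state. Entries are synthetic design values whose
#' stationary distribution approximates the typical laboratory class
#' frequencies (Wake ~55 %, NREM ~38 %, REM ~5 %, pre-REM ~2 %,
#' artifact ~0.3 %).
#'
#' @return A [hypnogram_model()].
#' @export
default_hypnogram_model <- function() {
  P <- rbind(
    WAKE     = c(0.9590, 0.0360, 0.0000, 0.0020, 0.0030),
    NREM     = c(0.0350, 0.9260, 0.0360, 0.0010, 0.0020),
    PREREM   = c(0.0500, 0.2500, 0.3000, 0.4000, 0.0000),
    REM      = c(0.1350, 0.0300, 0.0050, 0.8280, 0.0020),
    ARTIFACT = c(0.5500, 0.3800, 0.0200, 0.0500, 0.0000))
  colnames(P) <- STAGES5
  hypnogram_model(P)
}

#' Sample a hypnogram from a Markov model
#'
#' @param model a [hypnogram_model()].
#' @param n_epochs number of epochs to sample (>= 0).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#'   `NULL` draws from the current stream.
#' @param epoch_len_s epoch length in seconds.
#' @return A `hypnogram` of length `n_epochs`.
#' @export
generate_hypnogram <- function(model, n_epochs, seed = NULL, epoch_len_s = 10) {
  stopifnot(inherits(model, "hypnogram_model"), n_epochs >= 0)
  with_seed(seed, {
    if (n_epochs == 0) return(hypnogram(character(0), epoch_len_s))
    P <- model$transition_matrix
    states <- integer(n_epochs)
    states[1] <- sample.int(5L, 1L, prob = model$initial_distribution)
    if (n_epochs > 1) {
      for (k in 2:n_epochs) {
        states[k] <- sample.int(5L, 1L, prob = P[states[k - 1L], ])
      }
    }
    hypnogram(STAGES5[states], epoch_len_s)
  })
}

# Pink (1/f) noise with RMS `amp`, via spectral shaping of white noise.
pink_noise <- function(n, amp) {
  if (amp == 0 || n == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmax(pmin(k, n - k), 1)         # symmetric shaping, no DC blow-up
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  r <- sqrt(mean(x^2))
  if (r == 0) numeric(n) else x * (amp / r)
}

# Band-limited oscillation: sine at a frequency drawn uniformly from the
# band, random phase, slow sinusoidal amplitude modulation.
oscillation <- function(n, fs, band, amp) {
  if (amp == 0 || n == 0) return(numeric(n))
  f0 <- stats::runif(1, band[1], band[2])
  ph <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  am <- 1 + 0.2 * sin(2 * pi * 0.08 * t + stats::runif(1, 0, 2 * pi))
  amp * am * sin(2 * pi * f0 * t + ph)
}

# Hann-windowed burst of a 10-15 Hz carrier at a random onset.
spindle_burst <- function(n, fs, len_s, amp) {
  m <- max(2L, round(len_s * fs))
  if (m >= n) m <- n
  f0 <- stats::runif(1, 10, 15)
  ph <- stats::runif(1, 0, 2 * pi)
  onset <- sample.int(n - m + 1L, 1L)
  t <- (seq_len(m) - 1) / fs
  env <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
  out <- numeric(n)
  out[onset:(onset + m - 1L)] <- amp * env * sin(2 * pi * f0 * t + ph)
  out
}

# One clipped biphasic spike transient.
spike_transient <- function(n, fs, len_s, amp) {
  m <- max(4L, round(len_s * fs))
  if (m >= n) m <- n
  onset <- sample.int(n - m + 1L, 1L)
  t <- seq(-1, 1, length.out = m)
  shape <- amp * sign(t) * exp(-8 * t^2) * sample(c(-1, 1), 1)
  out <- numeric(n)
  out[onset:(onset + m - 1L)] <- shape
  out
}

synth_epoch_impl <- function(stage, model, fs, duration_s) {
  n <- as.integer(round(fs * duration_s))
  x <- pink_noise(n, model$noise_amp)
  if (stage == "NREM" || stage == "REM" || stage == "WAKE") {
    x <- x + oscillation(n, fs, model$band_hz, model$osc_amp)
  } else if (stage == "PREREM") {
    # NREM-like delta background with emerging theta and spindle bursts
    x <- x + oscillation(n, fs, c(0.5, 4), 0.8 * model$osc_amp)
    x <- x + oscillation(n, fs, model$band_hz, model$osc_amp)
    n_burst <- max(1L, stats::rpois(1, model$burst_rate))
    for (b in seq_len(n_burst)) {
      x <- x + spindle_burst(n, fs, model$burst_len_s, model$burst_amp)
    }
  } else if (stage == "ARTIFACT") {
    x <- x + oscillation(n, fs, model$band_hz, model$osc_amp)
    if (model$burst_amp > 0) {
      base_rms <- max(sqrt(mean(x^2)), 1e-12)
      n_spk <- max(1L, stats::rpois(1, model$burst_rate))
      for (b in seq_len(n_spk)) {
        x <- x + spike_transient(n, fs, model$burst_len_s, model$burst_amp)
      }
      clip <- max(model$burst_amp / 2, 8 * base_rms)
      x <- pmax(pmin(x, clip), -clip)
    }
  }
  x
}

#' Synthesize one stage-labeled EEG epoch
#'
#' Generates a 10-s (by default) caricature of the requested stage: a
#' band-limited oscillation over pink background noise, with spindle-like
#' bursts for pre-REM and clipped spike transients for artifact epochs.
#' With all amplitudes zero the output is the all-zero signal.
#'
#' @param stage stage name (any token accepted by [normalize_stage()]).
#' @param model a [stage_signal_model()]; default is the stage's entry in
#'   [default_signal_models()].
#' @param fs sampling rate in Hz; must exceed twice the model's upper band
#'   edge (Nyquist).
#' @param duration_s epoch duration in seconds.
#' @param seed integer seed for reproducibility; `NULL` draws from the
#'   current RNG stream.
#' @return Numeric vector of `round(fs * duration_s)` samples (microvolts).
#' @export
synthesize_epoch <- function(stage, model = NULL, fs = 992, duration_s = 10,
                             seed = NULL) {
  stage <- normalize_stage(stage)
  if (is.null(model)) model <- default_signal_models()[[stage]]
  if (fs <= 2 * model$band_hz[2]) {
    stop("fs must exceed twice the upper band edge (Nyquist)", call. = FALSE)
  }
  with_seed(seed, synth_epoch_impl(stage, model, fs, duration_s))
}

#' Generate a synthetic multi-subject dataset on disk
#'
#' Samples one Markov hypnogram per subject and synthesizes the matching
#' stage-labeled recording, written through the package's writers (raw
#' float32 dialect by default). Subject streams are decorrelated
#' deterministically from the single seed, so a fixed seed reproduces the
#' dataset byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param n_subjects number of subjects (>= 1).
#' @param n_epochs epochs per subject; a vector is recycled across subjects,
#'   so training subjects can be longer than validation/test subjects.
#' @param fs native sampling rate in Hz (default 992, an integer stand-in
#'   for amplifier rates near 1 kHz, exercising the resampling path).
#' @param hyp_model a [hypnogram_model()]; default [default_hypnogram_model()].
#' @param sig_models named list of [stage_signal_model()]s; default
#'   [default_signal_models()].
#' @param seed integer seed.
#' @param epoch_len_s epoch length in seconds.
#' @param format recording format, `"raw"` or `"edf"`.
#' @return A data.frame manifest with columns `subject_id`, `recording`,
#'   `hypnogram` (file paths), invisibly written as `manifest.csv`.
#' @export
generate_dataset <- function(out_dir, n_subjects, n_epochs, fs = 992,
                             hyp_model = default_hypnogram_model(),
                             sig_models = default_signal_models(),
                             seed = 1, epoch_len_s = 10, format = "raw") {
  stopifnot(n_subjects >= 1, all(n_epochs >= 1))
  n_epochs <- rep_len(as.integer(n_epochs), n_subjects)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "edf") ".edf" else ".f32"
  manifest <- data.frame(subject_id = character(0), recording = character(0),
                         hypnogram = character(0))
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("synth%02d", s)
    sseed <- (as.integer(seed) + 100003L * s) %% .Machine$integer.max
    rec_path <- file.path(out_dir, paste0(sid, ext))
    hyp_path <- file.path(out_dir, paste0(sid, "_hypnogram.csv"))
    with_seed(sseed, {
      hyp <- generate_hypnogram(hyp_model, n_epochs[s], epoch_len_s = epoch_len_s)
      x <- unlist(lapply(hyp$labels, function(st) {
        synth_epoch_impl(st, sig_models[[st]], fs, epoch_len_s)
      }), use.names = FALSE)
      write_recording(recording(x, fs, subject_id = sid), rec_path,
                      format = format)
      write_hypnogram(hyp, hyp_path)
    })
    manifest <- rbind(manifest, data.frame(subject_id = sid,
                                           recording = rec_path,
                                           hypnogram = hyp_path))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
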