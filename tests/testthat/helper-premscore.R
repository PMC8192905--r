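# Shared helpers for the test suite ---------------------------------------

# A context_windows object built directly from a source signal, without the
# preprocessing pipeline (for augmentation and training unit tests).
windows_from_signal <- function(signal, n_windows, T_len, fs = 64,
                                labels = rep("WAKE", n_windows),
                                spacing = T_len) {
  starts <- 1L + (seq_len(n_windows) - 1L) * as.integer(spacing)
  x <- t(vapply(starts, function(s) signal[s:(s + T_len - 1L)],
                numeric(T_len)))
  structure(list(x = x, labels = labels, starts = starts, signal = signal,
                 fs = fs, samples_per_epoch = T_len %/% 3L,
                 subject_id = "testsubj"),
            class = "context_windows")
}

# Least-squares amplitude of a sinusoid at frequency f in a signal segment.
fitted_amplitude <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  b <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(b[2]^2 + b[3]^2)
}

# Tiny separable window set: three "stages" as pure tones at distinct
# frequencies plus noise; used for fast learning tests.
tone_windows <- function(n_per_class, T_len = 64, fs = 64,
                         freqs = c(WAKE = 2, NREM = 8, REM = 20),
                         noise = 0.1) {
  labels <- rep(names(freqs), each = n_per_class)
  x <- t(vapply(seq_along(labels), function(i) {
    f <- freqs[[labels[i]]]
    t <- (seq_len(T_len) - 1) / fs
    sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi)) +
      noise * stats::rnorm(T_len)
  }, numeric(T_len)))
  structure(list(x = x, labels = labels, starts = rep(1L, length(labels)),
                 signal = numeric(T_len), fs = fs,
                 samples_per_epoch = T_len %/% 3L, subject_id = "tones"),
            class = "context_windows")
}
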