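# Small spectral helpers used by the synthetic generator and its checks ----

#' Periodogram of a signal
#'
#' Plain FFT periodogram (no tapering), returned on the one-sided frequency
#' grid. Adequate for locating dominant oscillations in synthetic epochs.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @return A list with `freq` (Hz) and `power` (arbitrary units).
#' @export
periodogram <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop("signal too short", call. = FALSE)
  sp <- abs(stats::fft(x - mean(x)))^2 / n
  half <- seq_len(floor(n / 2) + 1L)
  list(freq = (half - 1) * fs / n, power = sp[half])
}

#' Band power of a signal
#'
#' Sum of periodogram power over `band[1] <= f <= band[2]`.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz.
#' @return Scalar band power.
#' @export
bandpower <- function(x, fs, band) {
  p <- periodogram(x, fs)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  sum(p$power[sel])
}

#' Frequency of the dominant spectral peak
#'
#' @inheritParams bandpower
#' @param fmin ignore frequencies below this value (default drops DC).
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(x, fs, fmin = 0.25) {
  p <- periodogram(x, fs)
  sel <- p$freq >= fmin
  p$freq[sel][which.max(p$power[sel])]
}
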