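# Training-time data augmentation ------------------------------------------

#' Augmentation strengths
#'
#' Four stochastic training-time transforms, each controlled by a strength
#' in `[0, 1]` (0 disables the transform, the default): amplitude scaling
#' `a_a`, window warping `a_f`, sign flip probability `a_s`, and time shift
#' `a_t`. Fresh random draws are made every time a window enters the
#' network; augmentation is never applied at evaluation time.
#'
#' @param a_a amplitude strength.
#' @param a_f frequency (window warping) strength.
#' @param a_s sign-flip probability.
#' @param a_t time-shift strength.
#' @return An object of class `augmentation_params`.
#' @export
augmentation_params <- function(a_a = 0, a_f = 0, a_s = 0, a_t = 0) {
  v <- c(a_a = a_a, a_f = a_f, a_s = a_s, a_t = a_t)
  if (any(v < 0 | v > 1)) stop("augmentation strengths must be in [0, 1]",
                               call. = FALSE)
  structure(as.list(v), class = "augmentation_params")
}

#' Amplitude augmentation
#'
#' Pointwise scaling `s * (1 + a_a * u)` with `u` drawn from U\[-1, 1).
#' Mean-preserving in expectation over `u`.
#'
#' @param s numeric signal.
#' @param a_a strength in `[0, 1]`.
#' @param u the uniform draw, `|u| <= 1`.
#' @return Scaled signal, same length.
#' @export
augment_amplitude <- function(s, a_a, u) {
  stopifnot(abs(u) <= 1)
  s * (1 + a_a * u)
}

#' Sign-flip augmentation
#'
#' Negates the signal iff `u < a_s`, emulating an EEG montage change
#' (polarity reversal) that leaves the underlying dynamics unchanged.
#'
#' @param s numeric signal.
#' @param a_s flip probability in `[0, 1]`.
#' @param u the uniform draw from U\[0, 1).
#' @return Possibly negated signal.
#' @export
augment_signflip <- function(s, a_s, u) {
  stopifnot(u >= 0, u < 1)
  if (u < a_s) -s else s
}

# Fetch source samples at (possibly out-of-range) indices, replicating the
# edge sample beyond the recording bounds.
source_slice <- function(source, idx) {
  source[pmin(pmax(idx, 1L), length(source))]
}

#' Frequency augmentation (window warping)
#'
#' A temporary series of length `T* = floor(T * (1 + a_f * u))`, centred on
#' the window's central sample and fed from the source recording (edge
#' samples replicated beyond the recording bounds), is linearly resampled
#' back to length `T`. `T* > T` contracts time, shifting frequencies up by
#' the factor `T*/T`; `T* < T` stretches it, shifting them down.
#'
#' @param s the window's samples (length `T`).
#' @param a_f strength in `[0, 1]`.
#' @param u the uniform draw from U\[-1, 1).
#' @param source the full source signal the window was cut from.
#' @param start 1-based index of `s[1]` within `source` (may be
#'   non-positive for windows at the left edge).
#' @return Warped signal of length `T`.
#' @export
augment_frequency <- function(s, a_f, u, source = s, start = 1L) {
  T_len <- length(s)
  T_star <- floor(T_len * (1 + a_f * u))
  if (T_star == T_len) return(s)
  if (T_star < 2) T_star <- 2L
  centre <- start + T_len %/% 2L
  j <- seq_len(T_star) - 1L
  tmp <- source_slice(source, centre + (j - T_star %/% 2L))
  stats::approx(seq(0, 1, length.out = T_star), tmp,
                xout = seq(0, 1, length.out = T_len))$y
}

#' Time-shift augmentation
#'
#' Returns samples `s[(1 + dt):(T + dt)]` of the source recording with
#' `dt = floor(T * a_t * u)`, i.e. the window slid by up to `a_t * T`
#' samples while its label stays fixed. Out-of-recording samples are edge
#' replicated.
#'
#' @inheritParams augment_frequency
#' @param a_t strength in `[0, 1]`.
#' @return Shifted signal of length `T`.
#' @export
augment_timeshift <- function(s, a_t, u, source = s, start = 1L) {
  T_len <- length(s)
  dt <- floor(T_len * a_t * u)
  if (dt == 0) return(s)
  source_slice(source, (start + dt):(start + dt + T_len - 1L))
}

#' Apply the full augmentation pipeline to one window
#'
#' Transforms are composed in the order amplitude, sign flip, window
#' warping, time shift, with four fresh uniform draws per call (or draws
#' injected through `u` for deterministic testing). The pointwise amplitude
#' and sign-flip factors commute with warping and shifting, so the
#' composite is evaluated as a single fetch-warp of the (scaled) source:
#' the time shift moves the window within the recording, warping resamples
#' around the shifted centre, and the scalar factor is applied last.
#'
#' @param cw a `context_windows` object.
#' @param i window (row) index.
#' @param params an [augmentation_params()].
#' @param u optional numeric vector `c(u_a, u_s, u_f, u_t)` of draws; when
#'   `NULL` they are drawn from the current RNG stream (`u_a, u_f, u_t`
#'   from U\[-1, 1), `u_s` from U\[0, 1)).
#' @return Augmented window of length `T`.
#' @export
augment_window <- function(cw, i, params, u = NULL) {
  s <- cw$x[i, ]
  if (is.null(u)) {
    u <- c(stats::runif(1, -1, 1), stats::runif(1),
           stats::runif(1, -1, 1), stats::runif(1, -1, 1))
  }
  mfac <- (1 + params$a_a * u[1]) * (if (u[2] < params$a_s) -1 else 1)
  T_len <- length(s)
  dt <- floor(T_len * params$a_t * u[4])
  T_star <- floor(T_len * (1 + params$a_f * u[3]))
  if (dt == 0L && T_star == T_len) return(mfac * s)
  source <- window_source(cw, i)
  start <- cw$starts[i] + dt
  out <- if (T_star == T_len) {
    source_slice(source, start:(start + T_len - 1L))
  } else {
    augment_frequency(s, params$a_f, u[3], source = source, start = start)
  }
  mfac * out
}
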