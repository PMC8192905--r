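# Recording and hypnogram containers, readers and writers -----------------

#' Single-channel EEG recording
#'
#' A uniformly sampled single-channel EEG signal in microvolts with its
#' sampling rate and subject/channel metadata.
#'
#' @param samples numeric vector of samples (microvolts); must be finite.
#' @param fs sampling rate in Hz, > 0.
#' @param subject_id subject identifier.
#' @param channel channel name.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(samples, fs, subject_id = "unknown", channel = "EEG") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  fs <- as.numeric(fs)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs,
         subject_id = as.character(subject_id), channel = as.character(channel)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject=%s channel=%s\n", x$subject_id, x$channel))
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Per-epoch stage labels aligned to a recording
#'
#' @param labels stage labels (any token accepted by [normalize_stage()]),
#'   one per epoch, in temporal order.
#' @param epoch_len_s epoch length in seconds (> 0); 10 s by convention.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len_s = 10) {
  if (!is.numeric(epoch_len_s) || epoch_len_s <= 0) {
    stop("epoch_len_s must be > 0", call. = FALSE)
  }
  labels <- if (length(labels)) normalize_stage(labels) else character(0)
  structure(list(labels = labels, epoch_len_s = epoch_len_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs of %g s\n", length(x$labels), x$epoch_len_s))
  if (length(x$labels)) print(table(factor(x$labels, levels = STAGES5)))
  invisible(x)
}

#' Number of whole epochs a recording spans
#'
#' Epoch `k` (1-based) covers samples `[(k-1)*epoch_len_s*fs, k*epoch_len_s*fs)`;
#' a trailing partial epoch is dropped.
#'
#' @param rec an `eeg_recording`.
#' @param epoch_len_s epoch length in seconds.
#' @return Integer epoch count.
#' @export
n_epochs <- function(rec, epoch_len_s = 10) {
  as.integer(floor(length(rec$samples) / rec$fs / epoch_len_s))
}

# Raw float32 dialect ------------------------------------------------------

#' Write a recording to disk
#'
#' Two dialects are supported. `"raw"` writes little-endian float32 samples
#' with a JSON sidecar `<path>.json` holding
#' `{"fs_hz": ..., "unit": "uV", "subject_id": ..., "channel": ...}`; it
#' round-trips losslessly (any float32-representable sample is recovered
#' bit-exactly). `"edf"` writes a minimal single-channel EDF (European Data
#' Format) file: 16-bit quantization applies, and the sampling rate must be
#' expressible as an integer number of samples over an integer record
#' duration of at most 60 s (992.06 Hz = 49603 samples / 50 s works).
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param format `"raw"` or `"edf"`; default guesses from the file extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "raw"
  }
  format <- match.arg(format, c("raw", "edf"))
  if (format == "raw") write_recording_raw(rec, path) else write_edf(rec, path)
  invisible(path)
}

#' Read a recording from disk
#'
#' Dialect is sniffed: `.edf` extension (or an EDF magic header) selects EDF,
#' anything else the raw float32 + JSON sidecar dialect.
#'
#' @param path input file path.
#' @return An `eeg_recording` with samples in microvolts.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
  else read_recording_raw(path)
}

write_recording_raw <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rec$samples, con, size = 4L, endian = "little")
  meta <- list(fs_hz = rec$fs, unit = "uV",
               subject_id = rec$subject_id, channel = rec$channel)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_recording_raw <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("format error: missing sidecar ", sidecar,
         " (sampling rate unknown)", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs_hz) || !is.finite(meta$fs_hz) || meta$fs_hz <= 0) {
    stop("format error: missing or invalid fs_hz in sidecar", call. = FALSE)
  }
  n <- file.size(path) %/% 4L
  con <- file(path, "rb")
  on.exit(close(con))
  samples <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("data error: non-finite samples in ", path, call. = FALSE)
  }
  recording(samples, meta$fs_hz,
            subject_id = if (is.null(meta$subject_id)) "unknown" else meta$subject_id,
            channel = if (is.null(meta$channel)) "EEG" else meta$channel)
}

# Minimal EDF (European Data Format) support -------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF field too wide: ", x, call. = FALSE)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 8)
  if (nchar(s) > width) s <- substr(format(x, scientific = FALSE), 1, width)
  edf_pad(s, width)
}

# smallest record duration (1..60 s) for which fs*d is an integer sample count
edf_record_duration <- function(fs) {
  for (d in 1:60) {
    if (abs(fs * d - round(fs * d)) < 1e-6) return(d)
  }
  stop("format error: sampling rate ", fs,
       " Hz not representable in EDF records of <= 60 s; use the raw dialect",
       call. = FALSE)
}

write_edf <- function(rec, path) {
  dur <- edf_record_duration(rec$fs)
  spr <- as.integer(round(rec$fs * dur))
  n_rec <- as.integer(ceiling(length(rec$samples) / spr))
  x <- c(rec$samples, numeric(n_rec * spr - length(rec$samples)))
  pmax_ <- max(1, ceiling(max(abs(x))))
  dig <- as.integer(round((x + pmax_) / (2 * pmax_) * 65535 - 32768))
  dig <- pmax(pmin(dig, 32767L), -32768L)

  header <- paste0(
    edf_pad("0", 8),                       # version
    edf_pad(rec$subject_id, 80),           # patient id
    edf_pad(rec$channel, 80),              # recording id
    edf_pad("01.01.00", 8),                # start date
    edf_pad("00.00.00", 8),                # start time
    edf_num(256 + 256, 8),                 # header bytes (1 signal)
    edf_pad("", 44),                       # reserved
    edf_num(n_rec, 8),                     # number of data records
    edf_num(dur, 8),                       # record duration (s)
    edf_num(1, 4),                         # number of signals
    edf_pad(rec$channel, 16),              # label
    edf_pad("", 80),                       # transducer
    edf_pad("uV", 8),                      # physical dimension
    edf_num(-pmax_, 8),                    # physical minimum
    edf_num(pmax_, 8),                     # physical maximum
    edf_num(-32768, 8),                    # digital minimum
    edf_num(32767, 8),                     # digital maximum
    edf_pad("", 80),                       # prefiltering
    edf_num(spr, 8),                       # samples per record
    edf_pad("", 32))                       # reserved
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  field <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  subject_id <- field(9, 80)
  n_rec <- as.integer(field(237, 8))
  dur <- as.numeric(field(245, 8))
  ns <- as.integer(field(253, 4))
  if (is.na(ns) || ns < 1L) stop("format error: bad EDF signal count", call. = FALSE)
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  sfield <- function(block_from, len, i) {
    off <- (block_from - 1L) * ns + (i - 1L) * len
    trimws(substr(sig, off + 1L, off + len))
  }
  label <- sfield(1, 16, 1)
  pmin_ <- as.numeric(sfield(105, 8, 1))
  pmax_ <- as.numeric(sfield(113, 8, 1))
  dmin <- as.numeric(sfield(121, 8, 1))
  dmax <- as.numeric(sfield(129, 8, 1))
  spr <- as.integer(vapply(seq_len(ns), function(i) as.numeric(sfield(217, 8, i)),
                           numeric(1)))
  if (is.na(dur) || dur <= 0 || any(is.na(spr)) || spr[1] <= 0) {
    stop("format error: missing or ambiguous sampling rate in EDF header",
         call. = FALSE)
  }
  fs <- spr[1] / dur
  dig <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec_raw <- readBin(con, what = "integer", n = sum(spr), size = 2L,
                       signed = TRUE, endian = "little")
    dig[[r]] <- rec_raw[seq_len(spr[1])]   # first signal only
  }
  d <- as.numeric(unlist(dig))
  x <- (d - dmin) / (dmax - dmin) * (pmax_ - pmin_) + pmin_
  recording(x, fs, subject_id = subject_id, channel = label)
}

# Hypnogram CSV ------------------------------------------------------------

#' Write a hypnogram as CSV
#'
#' Format: header `epoch_index,label`, 0-based epoch indices, canonical stage
#' names, UTF-8.
#'
#' @param h a `hypnogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  df <- data.frame(epoch_index = seq_along(h$labels) - 1L, label = h$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' Rows may appear in any order; they are sorted by `epoch_index`. Duplicate
#' or missing indices, unknown label tokens, and a row count different from
#' `n_epochs` are errors.
#'
#' @param path CSV file with columns `epoch_index` (0-based) and `label`.
#' @param n_epochs expected number of epochs (from the aligned recording);
#'   `NULL` skips the length check.
#' @param epoch_len_s epoch length in seconds.
#' @return A `hypnogram`.
#' @export
read_hypnogram <- function(path, n_epochs = NULL, epoch_len_s = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "label") %in% names(df))) {
    stop("format error: hypnogram CSV needs columns epoch_index,label",
         call. = FALSE)
  }
  df <- df[order(df$epoch_index), , drop = FALSE]
  idx <- as.integer(df$epoch_index)
  if (anyNA(idx) || !identical(idx, seq_len(nrow(df)) - 1L)) {
    stop("duplicate or missing epoch_index in ", path, call. = FALSE)
  }
  if (!is.null(n_epochs) && nrow(df) != n_epochs) {
    stop(sprintf("length error: %d labels but %d epochs expected",
                 nrow(df), n_epochs), call. = FALSE)
  }
  hypnogram(df$label, epoch_len_s = epoch_len_s)
}

#' Reduce a 5-class hypnogram to the standard stages
#'
#' Pre-REM epochs are reinterpreted as NREM and artifact epochs are removed,
#' leaving the standard vocabulary WAKE, NREM, REM.
#'
#' @param h a `hypnogram` over the 5-class vocabulary.
#' @return A list with `hypnogram` (the reduced hypnogram) and `kept_indices`,
#'   the 1-based original epoch positions that survive artifact removal.
#' @export
reduce_to_standard_stages <- function(h) {
  labels <- h$labels
  kept <- which(labels != "ARTIFACT")
  out <- labels[kept]
  out[out == "PREREM"] <- "NREM"
  list(hypnogram = hypnogram(out, epoch_len_s = h$epoch_len_s),
       kept_indices = kept)
}
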