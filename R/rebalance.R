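# Class rebalancing by per-epoch resampling with replacement ---------------

#' Rebalancing target frequencies
#'
#' A rebalanced training set keeps the total number of segments but draws,
#' with replacement, `round(target_freq[c] * N)` segments from each class
#' `c` (rounding half away from zero). A fresh multiset is drawn before
#' every training epoch.
#'
#' @param target_freq named numeric vector of target class proportions
#'   (names from the stage vocabulary); must be non-negative and sum to 1.
#' @param preserve_total kept for interface completeness; the per-class
#'   rounding rule preserves the total up to one unit per class.
#' @return An object of class `rebalance_spec`.
#' @export
rebalance_spec <- function(target_freq, preserve_total = TRUE) {
  target_freq <- unlist(target_freq)
  if (is.null(names(target_freq))) {
    stop("target_freq must be named by stage", call. = FALSE)
  }
  names(target_freq) <- normalize_stage(names(target_freq))
  if (any(target_freq < 0) || abs(sum(target_freq) - 1) > 1e-9) {
    stop("target frequencies must be >= 0 and sum to 1", call. = FALSE)
  }
  structure(list(target_freq = target_freq, preserve_total = preserve_total),
            class = "rebalance_spec")
}

#' Named rebalancing profiles
#'
#' `"reb1"` is the 5-class profile (Wake 30 %, REM 18 %, NREM 24 %,
#' pre-REM 14 %, artifact 14 %) that oversamples the rare classes while
#' retaining some of the natural imbalance; `"reb2"` is the 3-class profile
#' (Wake 41 %, REM 25 %, NREM 34 %) used when only the standard stages are
#' scored.
#'
#' @param name `"reb1"` or `"reb2"`.
#' @return A [rebalance_spec()].
#' @export
rebalance_profile <- function(name = c("reb1", "reb2")) {
  name <- match.arg(name)
  if (name == "reb1") {
    rebalance_spec(c(WAKE = 0.30, REM = 0.18, NREM = 0.24,
                     PREREM = 0.14, ARTIFACT = 0.14))
  } else {
    rebalance_spec(c(WAKE = 0.41, REM = 0.25, NREM = 0.34))
  }
}

round_half_away <- function(x) floor(x + 0.5)

#' Draw one rebalanced index multiset
#'
#' For each class `c` with positive target, draws exactly
#' `round_half_away(target_freq[c] * N)` indices with replacement from the
#' positions of class `c` in `labels` (`N = length(labels)`). A positive
#' target for a class with no support is an error. Classes present in the
#' data but absent from the spec contribute no indices.
#'
#' @param labels stage labels of the training windows.
#' @param spec a [rebalance_spec()].
#' @return Integer vector of (1-based) window indices; class histogram of
#'   `labels[result]` equals the per-class counts above.
#' @export
rebalance_indices <- function(labels, spec) {
  N <- length(labels)
  tf <- spec$target_freq[spec$target_freq > 0]
  out <- vector("list", length(tf))
  for (j in seq_along(tf)) {
    cls <- names(tf)[j]
    pos <- which(labels == cls)
    if (length(pos) == 0) {
      stop("class ", cls, " has positive target but no segments", call. = FALSE)
    }
    cnt <- round_half_away(tf[[j]] * N)
    out[[j]] <- pos[sample.int(length(pos), cnt, replace = TRUE)]
  }
  unlist(out, use.names = FALSE)
}

#' Training-view generator
#'
#' Returns a function that, on each call (one call per training epoch),
#' yields a freshly drawn, shuffled index multiset: rebalanced per `spec`,
#' or a plain permutation of all windows when `spec` is `NULL`.
#'
#' @param labels stage labels of the training windows.
#' @param spec a [rebalance_spec()] or `NULL` for no rebalancing.
#' @return A zero-argument function returning integer indices.
#' @export
make_training_view <- function(labels, spec = NULL) {
  N <- length(labels)
  if (is.null(spec)) {
    function() sample.int(N)
  } else {
    function() {
      idx <- rebalance_indices(labels, spec)
      idx[sample.int(length(idx))]
    }
  }
}
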