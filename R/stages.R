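# Stage vocabulary --------------------------------------------------------

#' Sleep-stage vocabulary
#'
#' Five stages are scored on 10-s epochs: `WAKE` (low-amplitude broadband
#' activity with high muscle tone), `NREM` (slow delta waves, 0.5--4 Hz),
#' `PREREM` (transitional sleep with spindle-like bursts and emerging theta),
#' `REM` (rhythmic 7--8 Hz theta), and `ARTIFACT` (contaminated epochs).
#' Internal integer codes are 0..4 in the order WAKE, NREM, PREREM, REM,
#' ARTIFACT. Reports and matrices use the conventional column order
#' WAKE, REM, NREM, PREREM, ARTIFACT.
#'
#' @param num_classes 3 or 5. The 3-class vocabulary is `WAKE`, `NREM`, `REM`
#'   (pre-REM folded into NREM, artifacts removed).
#' @return Character vector of stage names.
#' @export
stage_levels <- function(num_classes = 5) {
  if (num_classes == 5) STAGES5
  else if (num_classes == 3) STAGES3
  else stop("num_classes must be 3 or 5", call. = FALSE)
}

STAGES5 <- c("WAKE", "NREM", "PREREM", "REM", "ARTIFACT")
STAGES3 <- c("WAKE", "NREM", "REM")

#' @rdname stage_levels
#' @export
stage_report_levels <- function(num_classes = 5) {
  if (num_classes == 5) c("WAKE", "REM", "NREM", "PREREM", "ARTIFACT")
  else if (num_classes == 3) c("WAKE", "REM", "NREM")
  else stop("num_classes must be 3 or 5", call. = FALSE)
}

#' Normalize stage label tokens
#'
#' Accepts full stage names in any case, the hyphenated form `PRE-REM`, and
#' the single-letter aliases `W`, `N`, `P`, `R`, `A`.
#'
#' @param x character vector of raw tokens.
#' @return Character vector over the canonical vocabulary.
#' @export
normalize_stage <- function(x) {
  up <- toupper(trimws(as.character(x)))
  up[up %in% c("PRE-REM", "PRE_REM", "IS", "TS")] <- "PREREM"
  alias <- c(W = "WAKE", N = "NREM", P = "PREREM", R = "REM", A = "ARTIFACT")
  one <- up %in% names(alias)
  up[one] <- alias[up[one]]
  bad <- !(up %in% STAGES5)
  if (any(bad)) {
    stop("unknown stage label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  up
}

#' Integer codes of stage labels
#'
#' @param x character vector of canonical stage names.
#' @return Integer codes, 0 (WAKE) through 4 (ARTIFACT).
#' @export
stage_code <- function(x) {
  match(normalize_stage(x), STAGES5) - 1L
}
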