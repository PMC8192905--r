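# Evaluation: confusion matrices, F1, Markov transition matrices -----------

#' F1 score from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`, defined as 0 when `p + r = 0`.
#'
#' @param precision,recall values in `[0, 1]` (vectorized).
#' @return F1 values in `[0, 1]`.
#' @export
f1_from_pr <- function(precision, recall) {
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Macro F1 over present classes
#'
#' Unweighted mean of per-class F1 scores, restricted to classes present in
#' the true labels (absent classes have undefined recall and are excluded).
#'
#' @param f1 per-class F1 vector.
#' @param present logical vector, which classes occur in the true labels.
#' @return Scalar macro F1.
#' @export
macro_f1 <- function(f1, present = rep(TRUE, length(f1))) {
  if (!any(present)) stop("no present classes", call. = FALSE)
  mean(f1[present])
}

#' Confusion matrix and per-class scores
#'
#' Builds the raw count matrix (rows = true stage, columns = predicted
#' stage) and its two normalizations: by the actual label frequency (rows;
#' the diagonal is per-class recall) and by the predicted label frequency
#' (columns; the diagonal is per-class precision). Per-class F1 is the
#' harmonic mean of precision and recall; macro F1 averages over classes
#' present in the true labels.
#'
#' @param true,pred equal-length stage label vectors.
#' @param levels stage vocabulary and report order; default
#'   [stage_report_levels()] for the number of distinct classes involved.
#' @return An object of class `premscore_eval` with fields `cm_counts`,
#'   `cm_recall_norm`, `cm_precision_norm`, `precision`, `recall`, `f1`,
#'   `present`, `f1_mean`, `n`.
#' @export
confusion <- function(true, pred, levels = NULL) {
  if (length(true) != length(pred)) stop("length mismatch", call. = FALSE)
  if (length(true) == 0) stop("empty input", call. = FALSE)
  true <- normalize_stage(true)
  pred <- normalize_stage(pred)
  if (is.null(levels)) {
    k <- if (any(c(true, pred) %in% c("PREREM", "ARTIFACT"))) 5 else 3
    levels <- stage_report_levels(k)
  }
  tf <- factor(true, levels = levels)
  pf <- factor(pred, levels = levels)
  if (anyNA(tf) || anyNA(pf)) stop("labels outside the vocabulary", call. = FALSE)
  cm <- unclass(table(tf, pf))
  dimnames(cm) <- list(true = levels, predicted = levels)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  rown <- sweep(cm, 1, ifelse(rs == 0, 1, rs), "/")
  coln <- sweep(cm, 2, ifelse(cs == 0, 1, cs), "/")
  recall <- diag(rown)
  precision <- diag(coln)
  f1 <- f1_from_pr(precision, recall)
  present <- rs > 0
  structure(list(cm_counts = cm, cm_recall_norm = rown,
                 cm_precision_norm = coln, precision = precision,
                 recall = recall, f1 = f1, present = present,
                 f1_mean = macro_f1(f1, present), n = length(true)),
            class = "premscore_eval")
}

#' @export
print.premscore_eval <- function(x, digits = 3, ...) {
  cat(sprintf("<premscore_eval> %d epochs, macro F1 %.3f\n", x$n, x$f1_mean))
  tab <- rbind(precision = x$precision, recall = x$recall, F1 = x$f1)
  print(round(tab, digits))
  invisible(x)
}

#' Markov transition matrix of a stage sequence
#'
#' Entry `(i, j)` counts occurrences of stage `i` immediately followed by
#' stage `j` (self-transitions included). With `groups`, transitions are
#' counted within each group only (e.g. per recording), never across
#' boundaries. The normalized matrix divides each row by its sum (all-zero
#' rows stay zero).
#'
#' @param labels stage label sequence.
#' @param levels stage vocabulary and matrix order.
#' @param groups optional grouping vector (same length as `labels`).
#' @return List with `counts` and `probs` (both K x K matrices).
#' @export
markov_matrix <- function(labels, levels = NULL, groups = NULL) {
  if (length(labels) == 0) stop("empty sequence", call. = FALSE)
  labels <- normalize_stage(labels)
  if (is.null(levels)) {
    k <- if (any(labels %in% c("PREREM", "ARTIFACT"))) 5 else 3
    levels <- stage_report_levels(k)
  }
  K <- length(levels)
  counts <- matrix(0L, K, K, dimnames = list(from = levels, to = levels))
  if (is.null(groups)) groups <- rep(1L, length(labels))
  for (gr in unique(groups)) {
    seq_g <- labels[groups == gr]
    if (length(seq_g) < 2) next
    from <- match(seq_g[-length(seq_g)], levels)
    to <- match(seq_g[-1], levels)
    for (t in seq_along(from)) {
      counts[from[t], to[t]] <- counts[from[t], to[t]] + 1L
    }
  }
  rs <- rowSums(counts)
  probs <- sweep(counts, 1, ifelse(rs == 0, 1, rs), "/")
  list(counts = counts, probs = probs)
}

#' Full evaluation report
#'
#' Confusion matrices under both normalizations, per-class
#' precision/recall/F1, macro F1, and Markov transition matrices for the
#' true and the predicted stage sequences.
#'
#' @param true,pred stage label sequences (equal length).
#' @param levels stage vocabulary and report order.
#' @param groups optional per-epoch recording identifiers; transitions are
#'   never counted across recordings.
#' @return An object of class `premscore_report`: the `premscore_eval`
#'   fields plus `transition_true` and `transition_pred`.
#' @export
eval_report <- function(true, pred, levels = NULL, groups = NULL) {
  ev <- confusion(true, pred, levels = levels)
  lv <- rownames(ev$cm_counts)
  rep <- unclass(ev)
  rep$transition_true <- markov_matrix(true, levels = lv, groups = groups)
  rep$transition_pred <- markov_matrix(pred, levels = lv, groups = groups)
  structure(rep, class = c("premscore_report", "premscore_eval"))
}

#' Write an evaluation report to disk
#'
#' CSV files for each matrix plus a JSON summary of the scalar metrics.
#'
#' @param report a `premscore_report` (or `premscore_eval`).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(m, name) {
    utils::write.csv(as.data.frame(m), file.path(dir, paste0(name, ".csv")))
  }
  wcsv(report$cm_counts, "confusion_counts")
  wcsv(report$cm_recall_norm, "confusion_recall_norm")
  wcsv(report$cm_precision_norm, "confusion_precision_norm")
  if (!is.null(report$transition_true)) {
    wcsv(report$transition_true$probs, "transition_true")
    wcsv(report$transition_pred$probs, "transition_pred")
  }
  metrics <- list(n = report$n, f1_mean = report$f1_mean,
                  precision = as.list(report$precision),
                  recall = as.list(report$recall),
                  f1 = as.list(report$f1))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
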