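# Experiment orchestration --------------------------------------------------

#' Default run configuration
#'
#' One structured configuration tree is the single source of truth for an
#' experiment: paths, the seed, the class mode, the split assignment
#' (subject -> role), and the preprocessing / augmentation / rebalancing /
#' model / training blocks. Values can be loaded from a YAML file and
#' overridden programmatically.
#'
#' @param ... named overrides of the default tree (nested lists are merged
#'   shallowly per block).
#' @return A named list of class `premscore_config`.
#' @export
premscore_config <- function(...) {
  base <- list(
    seed = 1,
    mode = "extended5",
    paths = list(data = "data", out = "out"),
    generate = list(enabled = FALSE, n_subjects = 4, n_epochs = 400, fs = 992),
    split = list(),                      # subject_id -> "train"/"validation"/"test"
    preprocess = as.list(preprocess_config()),
    augmentation = list(a_a = 0, a_f = 0, a_s = 0, a_t = 0),
    rebalance = list(profile = NULL),    # NULL = mode default, "none" disables
    model = list(),                      # overrides of model_config()
    train = list()                       # overrides of train_config()
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  structure(base, class = "premscore_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [premscore_config()].
#' @return A `premscore_config`.
#' @export
read_config <- function(path) {
  do.call(premscore_config, yaml::read_yaml(path))
}

#' Switch an experiment between class modes
#'
#' `"standard3"` scores only Wake, NREM, REM (pre-REM folded into NREM,
#' artifacts removed) with the `"reb2"` rebalancing profile; `"extended5"`
#' keeps all five stages with `"reb1"`. Raw signal files are never altered;
#' the reduction is applied to hypnograms at window-building time.
#'
#' @param cfg a `premscore_config`.
#' @param mode `"standard3"` or `"extended5"`.
#' @return The updated configuration.
#' @export
mode_switch <- function(cfg, mode = c("standard3", "extended5")) {
  mode <- match.arg(mode)
  cfg$mode <- mode
  if (is.null(cfg$rebalance$profile)) {
    cfg$rebalance$profile <- if (mode == "standard3") "reb2" else "reb1"
  }
  cfg
}

validate_split <- function(split, subjects) {
  roles <- unlist(split)
  bad <- setdiff(unique(roles), c("train", "validation", "test"))
  if (length(bad)) {
    stop("validation error: unknown split role(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(split))) {
    stop("validation error: subject assigned to more than one role",
         call. = FALSE)
  }
  missing <- setdiff(subjects, names(split))
  if (length(missing)) {
    stop("validation error: subjects without split role: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (r in c("train", "validation", "test")) {
    if (!any(roles == r)) {
      stop("validation error: no subject assigned to ", r, call. = FALSE)
    }
  }
  invisible(TRUE)
}

load_subject_windows <- function(rec_path, hyp_path, pcfg, mode) {
  rec <- read_recording(rec_path)
  n_ep <- n_epochs(rec, pcfg$epoch_len_s)
  hyp <- read_hypnogram(hyp_path, n_epochs = n_ep,
                        epoch_len_s = pcfg$epoch_len_s)
  rec64 <- preprocess_recording(rec, pcfg)
  if (mode == "standard3") {
    red <- reduce_to_standard_stages(hyp)
    spe <- as.integer(round(pcfg$epoch_len_s * pcfg$target_fs))
    # keep only surviving epochs' samples so windows stay aligned
    keep_idx <- unlist(lapply(red$kept_indices, function(k) {
      ((k - 1L) * spe + 1L):(k * spe)
    }), use.names = FALSE)
    rec64 <- recording(rec64$samples[keep_idx], rec64$fs,
                       subject_id = rec64$subject_id, channel = rec64$channel)
    hyp <- red$hypnogram
  }
  make_windows(rec64, hyp, pcfg)
}

#' Run a full experiment from one configuration
#'
#' generate (optional) -> preprocess -> window -> fit -> predict ->
#' evaluate, with every random draw governed by the single seed. Writes the
#' effective configuration, the fitted model checkpoint, the per-epoch
#' training log, and the test-set evaluation report under `cfg$paths$out`.
#' Training never sees validation or test subjects.
#'
#' @param cfg a `premscore_config`.
#' @param verbose print per-epoch progress.
#' @return Invisibly, a list with `fit`, `report`, `manifest`, and the
#'   output paths.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "premscore_config"))
  mode <- match.arg(cfg$mode, c("extended5", "standard3"))
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$paths$out, "config.yaml"))

  if (isTRUE(cfg$generate$enabled)) {
    generate_dataset(cfg$paths$data, n_subjects = cfg$generate$n_subjects,
                     n_epochs = cfg$generate$n_epochs, fs = cfg$generate$fs,
                     seed = cfg$seed)
  }
  manifest <- utils::read.csv(file.path(cfg$paths$data, "manifest.csv"),
                              stringsAsFactors = FALSE)
  split <- cfg$split
  if (length(split) == 0) {   # default round-robin assignment
    n <- nrow(manifest)
    if (n < 3) stop("validation error: need >= 3 subjects", call. = FALSE)
    roles <- c(rep("train", n - 2), "validation", "test")
    split <- stats::setNames(as.list(roles), manifest$subject_id)
  }
  validate_split(split, manifest$subject_id)

  pcfg <- do.call(preprocess_config, cfg$preprocess)
  role_of <- unlist(split)[manifest$subject_id]
  ws <- lapply(seq_len(nrow(manifest)), function(i) {
    load_subject_windows(manifest$recording[i], manifest$hypnogram[i],
                         pcfg, mode)
  })
  train_w <- bind_windows(ws[role_of == "train"])
  valid_w <- bind_windows(ws[role_of == "validation"])
  test_ws <- ws[role_of == "test"]
  test_w <- bind_windows(test_ws)

  mcfg <- do.call(model_config, c(cfg$model, list(
    num_classes = if (mode == "standard3") 3 else 5,
    input_len = ncol(train_w$x))))
  tcfg <- do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  aug <- do.call(augmentation_params, cfg$augmentation)
  reb <- cfg$rebalance$profile
  if (!is.null(reb) && identical(reb, "none")) reb <- NA

  fit <- premscore_fit(train_w, valid_w, mode = mode, model = mcfg,
                       train = tcfg, augment = aug, rebalance = reb,
                       verbose = verbose)

  utils::write.csv(fit$history, file.path(cfg$paths$out, "training_log.csv"),
                   row.names = FALSE)
  saveRDS(fit, file.path(cfg$paths$out, "checkpoint.rds"))

  pred <- unlist(lapply(test_ws, function(w) predict(fit, w)), use.names = FALSE)
  groups <- rep(seq_along(test_ws), vapply(test_ws, function(w) nrow(w$x), 1L))
  report <- eval_report(test_w$labels, pred,
                        levels = stage_report_levels(length(fit$levels)),
                        groups = groups)
  write_eval_report(report, file.path(cfg$paths$out, "report"))

  # per-epoch predictions with full probability vectors, one file per subject
  for (w in test_ws) {
    df <- predict(fit, w, type = "both")
    utils::write.csv(df, file.path(cfg$paths$out,
                                   paste0("pred_", w$subject_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(fit = fit, report = report, manifest = manifest,
                 out = cfg$paths$out))
}
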