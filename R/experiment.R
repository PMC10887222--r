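# End-to-end experiment orchestration: preprocess -> segment & label ->
# train per fold -> evaluate.

#' Preprocess every recording of a study once
#'
#' @param study A `study_bundle` with in-memory recordings.
#' @param pp_config A [preprocess_config()].
#' @return Named list of preprocessed `eeg_recording`s, keyed by session id.
#' @export
preprocess_study <- function(study, pp_config = preprocess_config()) {
  if (is.null(study$recordings)) {
    stop("study bundle has no recordings (generate with make_eeg = TRUE)")
  }
  out <- lapply(study$manifest$session_id, function(sid) {
    preprocess_eeg(study$recordings[[sid]], pp_config)
  })
  names(out) <- study$manifest$session_id
  out
}

#' Preprocess and segment every session of a study
#'
#' Runs the preprocessing chain on each recording and cuts labeled segments
#' for the requested task, concatenating all sessions into one array.
#'
#' @param study A `study_bundle` with in-memory recordings
#'   (`make_eeg = TRUE`).
#' @param task `"tl"` or `"subtask"` (selects the window preset).
#' @param pp_config A [preprocess_config()].
#' @param min_engagement Threshold passed to [label_subtasks()].
#' @param preprocessed Optional named list of already-preprocessed
#'   recordings from [preprocess_study()]; lets the two tasks share one
#'   preprocessing pass.
#' @return A segment set: list with `x` (25 x samples x n array) and
#'   `index` (tibble with session ids and both label schemes).
#' @export
study_segments <- function(study, task = c("tl", "subtask"),
                           pp_config = preprocess_config(),
                           min_engagement = 2, preprocessed = NULL) {
  task <- match.arg(task)
  if (is.null(study$recordings) && is.null(preprocessed)) {
    stop("study bundle has no recordings (generate with make_eeg = TRUE)")
  }
  spec <- if (task == "tl") tl_window_spec() else subtask_window_spec()
  ids <- study$manifest$session_id
  xs <- vector("list", length(ids)); idxs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sid <- ids[i]
    rec <- preprocessed[[sid]] %||%
      preprocess_eeg(study$recordings[[sid]], pp_config)
    idx <- segment_index(study$configs[[sid]], spec,
                         study$events[[sid]], study$responses[[sid]],
                         min_engagement)
    seg <- extract_segments(rec, idx)
    xs[[i]] <- seg$x; idxs[[i]] <- idx
  }
  n_tot <- sum(vapply(xs, function(a) dim(a)[3], 0))
  d1 <- dim(xs[[1]])
  x <- array(0, c(d1[1], d1[2], n_tot))
  at <- 0L
  for (i in seq_along(xs)) {
    n_i <- dim(xs[[i]])[3]
    x[, , at + seq_len(n_i)] <- xs[[i]]
    at <- at + n_i
    xs[[i]] <- NA  # release
  }
  index <- do.call(rbind, idxs)
  attr(index, "window_spec") <- spec
  list(x = x, index = index)
}

#' ML-vs-HL restricted accuracy
#'
#' Among segments whose true class is ML or HL, the fraction correctly
#' decided when the classifier's choice is restricted to those two classes
#' (argmax over the ML and HL scores). Near 0.5 means the two highest load
#' levels are indistinguishable.
#'
#' @param truth Character true labels.
#' @param scores Score matrix with columns named by class.
#' @return Accuracy in `[0, 1]`, or `NA` if no ML/HL segments.
#' @export
ml_hl_accuracy <- function(truth, scores) {
  sel <- truth %in% c("ML", "HL")
  if (!any(sel)) return(NA_real_)
  pick <- ifelse(scores[sel, "ML"] >= scores[sel, "HL"], "ML", "HL")
  mean(pick == truth[sel])
}

#' Run a cross-validated classification experiment
#'
#' For each fold: build a fresh model, train on the fold's training
#' sessions, predict the held-out sessions, and score. Task-load folds
#' report the confusion matrix, accuracy and the ML-vs-HL restricted
#' accuracy; subtask folds report the detection table.
#'
#' @param study A `study_bundle` with recordings.
#' @param task `"tl"` or `"subtask"`.
#' @param folds List of `split_plan`s (or a single plan).
#' @param enc An [encoder_config()].
#' @param train_cfg A [train_config()].
#' @param pp_config A [preprocess_config()].
#' @param segments Optional precomputed [study_segments()] output (skips
#'   preprocessing).
#' @param rng_seed Seed stream for model initialization.
#' @param verbose Print fold progress?
#' @return A `metrics_report` list: `task`, `per_fold`, and aggregate
#'   `summary` (mean over folds).
#' @export
run_experiment <- function(study, task = c("tl", "subtask"), folds,
                           enc = encoder_config(),
                           train_cfg = train_config(),
                           pp_config = preprocess_config(),
                           segments = NULL, rng_seed = 0L, verbose = FALSE) {
  task <- match.arg(task)
  if (inherits(folds, "split_plan")) folds <- list(folds)
  segs <- segments %||% study_segments(study, task, pp_config)
  dec <- decoder_config(task)
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    split <- folds[[f]]
    model <- build_model(enc, dec, rng_seed = child_seed(rng_seed, f))
    model <- train_model(model, segs, split, train_cfg, verbose = verbose)
    test_sel <- which(segs$index$session_id %in% split$test)
    if (!length(test_sel)) stop("fold has no test segments")
    pred <- predict_model(model, segs$x[, , test_sel, drop = FALSE])
    if (task == "tl") {
      truth <- segs$index$tl_label[test_sel]
      cm <- tl_confusion_matrix(truth, pred$labels)
      per_fold[[f]] <- list(
        confusion = cm, accuracy = attr(cm, "accuracy"),
        ml_hl_accuracy = ml_hl_accuracy(truth, pred$scores),
        history = model$history)
    } else {
      truth <- as.matrix(segs$index[test_sel, DETECTION_LABELS])
      per_fold[[f]] <- list(
        detection = detection_metrics(truth, pred$scores),
        history = model$history)
    }
    if (verbose) message(sprintf("fold %d/%d done", f, length(folds)))
  }
  summary <- if (task == "tl") {
    tibble::tibble(
      accuracy = mean(vapply(per_fold, `[[`, 0, "accuracy")),
      ml_hl_accuracy = mean(vapply(per_fold, `[[`, 0, "ml_hl_accuracy")))
  } else {
    det <- lapply(per_fold, `[[`, "detection")
    agg <- det[[1]]
    for (col in c("precision", "recall", "f1", "accuracy", "auc")) {
      agg[[col]] <- rowMeans(vapply(det, `[[`, numeric(nrow(agg)), col))
    }
    agg
  }
  structure(list(task = task, per_fold = per_fold, summary = summary,
                 n_segments = dim(segs$x)[3]),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> task '%s', %d fold(s), %d segments\n",
              x$task, length(x$per_fold), x$n_segments))
  print(x$summary)
  invisible(x)
}
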