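# Windowing, the two labeling schemes, and session-exclusive splits.
#
# Task-load classification uses 10 s windows with 5 s overlap; subtask
# detection uses 15 s windows with 10 s overlap (both hop 5 s). A window is
# labeled with the task-load class of the block containing its midpoint
# (ties go to the earlier block), so straddling windows are kept and the
# canonical per-session totals (611 and 610 windows over 3060 s) are
# preserved. Subtask labels are a 3-bit vector over SYSM/COMM/RMAN driven by
# operator activity: SYSM fires if a responded SYSM event starts in the
# window; COMM/RMAN fire if the engaged time inside the window totals at
# least 2 s; TRCK is never labeled (its engagement is unobservable in the
# logs).

#' Window specification
#'
#' @param length Window length, seconds.
#' @param overlap Overlap between consecutive windows, seconds
#'   (`0 < overlap < length`); the hop is `length - overlap`.
#' @return A `window_spec` list with `length`, `overlap`, `hop`.
#' @export
window_spec <- function(length, overlap) {
  if (!(overlap >= 0 && overlap < length)) {
    stop("need 0 <= overlap < length")
  }
  structure(list(length = length, overlap = overlap, hop = length - overlap),
            class = "window_spec")
}

#' Preset window specs for the two tasks
#' @return A `window_spec`.
#' @export
tl_window_spec <- function() window_spec(10, 5)

#' @rdname tl_window_spec
#' @export
subtask_window_spec <- function() window_spec(15, 10)

#' Window start times over a session
#'
#' Starts at 0 and advances by the hop; every window lies fully inside the
#' session, giving `floor((duration - length) / hop) + 1` windows.
#'
#' @param session_duration_s Session duration, seconds.
#' @param spec A [window_spec()].
#' @return Numeric vector of start times, seconds.
#' @export
make_windows <- function(session_duration_s, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (session_duration_s < spec$length) {
    stop("session shorter than one window")
  }
  n <- floor((session_duration_s - spec$length) / spec$hop) + 1
  (seq_len(n) - 1) * spec$hop
}

#' Task-load label of a window
#'
#' The label is the block type of the block containing the window midpoint;
#' a midpoint falling exactly on a block boundary belongs to the earlier
#' block.
#'
#' @param start Window start, seconds.
#' @param spec A [window_spec()].
#' @param config The session's `session_config`.
#' @return One of `"PW"`, `"LL"`, `"ML"`, `"HL"`.
#' @export
label_tl <- function(start, spec, config) {
  bt <- block_table(config)
  mid <- start + spec$length / 2
  idx <- findInterval(mid, bt$end, left.open = TRUE) + 1
  idx <- pmin(idx, nrow(bt))
  bt$block_type[idx]
}

# Time inside [w0, w1] covered by the union of a set of intervals.
# Overlapping engagements are not double-counted: an operator engaged with
# two calls at once is still engaged for the elapsed time only.
interval_overlap <- function(w0, w1, starts, ends) {
  s <- pmax(starts, w0); e <- pmin(ends, w1)
  keep <- e > s
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  total <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Subtask activity labels of a window
#'
#' @param start Window start, seconds.
#' @param spec A [window_spec()].
#' @param events The session's `event_log`.
#' @param responses The session's `response_log`.
#' @param min_engagement Engagement threshold for the continuous subtasks
#'   (COMM, RMAN), seconds.
#' @return Named integer vector (`SYSM`, `COMM`, `RMAN`) of 0/1 bits.
#' @export
label_subtasks <- function(start, spec, events, responses, min_engagement = 2) {
  w1 <- start + spec$length
  resp <- responses[responses$responded, ]
  sysm <- any(resp$subtask == "SYSM" & resp$onset >= start & resp$onset < w1)
  bits <- c(SYSM = as.integer(sysm), COMM = 0L, RMAN = 0L)
  for (task in c("COMM", "RMAN")) {
    iv <- resp[resp$subtask == task, ]
    ov <- interval_overlap(start, w1, iv$engage_start, iv$engage_end)
    bits[task] <- as.integer(ov >= min_engagement)
  }
  bits
}

#' Labeled segment index for a session
#'
#' Enumerates all windows of a session and attaches both label schemes
#' (task-load label always; subtask bits when logs are given).
#'
#' @param config A `session_config`.
#' @param spec A [window_spec()].
#' @param events,responses Optional logs for subtask labeling.
#' @param min_engagement Threshold passed to [label_subtasks()].
#' @return A tibble: `subject_id`, `session_id`, `start`, `tl_label`, and
#'   (with logs) `SYSM`, `COMM`, `RMAN` bit columns.
#' @export
segment_index <- function(config, spec, events = NULL, responses = NULL,
                          min_engagement = 2) {
  starts <- make_windows(session_duration(config), spec)
  out <- tibble::tibble(subject_id = config$subject_id,
                        session_id = config$session_id,
                        start = starts,
                        tl_label = label_tl(starts, spec, config))
  if (!is.null(events) && !is.null(responses)) {
    bits <- t(vapply(starts, label_subtasks, integer(3), spec = spec,
                     events = events, responses = responses,
                     min_engagement = min_engagement))
    out$SYSM <- bits[, "SYSM"]; out$COMM <- bits[, "COMM"]; out$RMAN <- bits[, "RMAN"]
  }
  attr(out, "window_spec") <- spec
  out
}

#' Session-exclusive train/test split
#'
#' Assigns whole sessions to train or test so that overlapping windows from
#' one session can never leak across the split; about `test_fraction` of the
#' sessions (at least one) form the test set.
#'
#' @param manifest Study manifest (tibble with `session_id`).
#' @param test_fraction Fraction of sessions held out (default 0.05).
#' @param rng_seed Integer seed.
#' @return A `split_plan`: list with `train` and `test` session-id vectors.
#' @export
split_sessions <- function(manifest, test_fraction = 0.05, rng_seed = 0L) {
  ids <- unique(manifest$session_id)
  if (length(ids) < 2) stop("need at least 2 sessions to split")
  n_test <- max(1L, round(test_fraction * length(ids)))
  with_rng(rng_seed, {
    test <- sample(ids, n_test)
    structure(list(train = setdiff(ids, test), test = test),
              class = "split_plan")
  })
}

#' Grouped cross-validation folds over sessions
#'
#' Randomly partitions the sessions into `n_folds` test sets of near-equal
#' size; each fold's complement is its training set, so the union of the
#' test sets covers every session exactly once.
#'
#' @param manifest Study manifest.
#' @param n_folds Number of folds (default 20, i.e. 5% test shares).
#' @param rng_seed Integer seed.
#' @return List of `split_plan`s.
#' @export
make_cv_folds <- function(manifest, n_folds = 20, rng_seed = 0L) {
  ids <- unique(manifest$session_id)
  if (n_folds > length(ids)) stop("more folds than sessions")
  with_rng(rng_seed, {
    perm <- sample(ids)
    grp <- sort(rep(seq_len(n_folds), length.out = length(ids)))
    lapply(seq_len(n_folds), function(f) {
      test <- perm[grp == f]
      structure(list(train = setdiff(ids, test), test = test),
                class = "split_plan")
    })
  })
}

#' Extract preprocessed, labeled segment arrays for one session
#'
#' Cuts a preprocessed recording into windows and returns the data as a
#' 3-D array together with the label index.
#'
#' @param recording The session's preprocessed `eeg_recording` (25 ch,
#'   125 Hz).
#' @param index Segment index tibble from [segment_index()] for the same
#'   session.
#' @return List: `x` array (channels x samples x n_segments), `index`.
#' @export
extract_segments <- function(recording, index) {
  fs <- recording$sample_rate
  starts <- index$start
  spec <- attr(index, "window_spec")
  if (is.null(spec)) stop("index lacks its window_spec attribute")
  n_samp <- round(spec$length * fs)
  n_seg <- nrow(index)
  x <- array(0, dim = c(nrow(recording$data), n_samp, n_seg))
  for (k in seq_len(n_seg)) {
    i0 <- round(starts[k] * fs) + 1L
    x[, , k] <- recording$data[, i0:(i0 + n_samp - 1L)]
  }
  list(x = x, index = index)
}
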