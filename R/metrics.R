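# Evaluation: confusion matrices, detection metrics (precision / recall /
# F1 / accuracy / ROC AUC), and the operator error-rate report.

#' Confusion matrix for task-load classification
#'
#' @param true_labels,predicted_labels Character vectors over the class
#'   order PW, LL, ML, HL (rows = true class).
#' @return A `confusion_matrix` object: 4 x 4 integer matrix with an
#'   `accuracy` attribute (trace / total).
#' @export
tl_confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length")
  }
  m <- table(factor(true_labels, levels = TL_LEVELS),
             factor(predicted_labels, levels = TL_LEVELS))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("true", "predicted")
  structure(m, class = c("confusion_matrix", "matrix"),
            accuracy = sum(diag(m)) / sum(m))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  cat(sprintf("accuracy: %.4f\n", attr(x, "accuracy")))
  invisible(x)
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation with midranks for ties; equals the probability
#' that a random positive outscores a random negative (ties counted half).
#'
#' @param truth 0/1 vector.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`; `NA` if one class is absent.
#' @export
auc_score <- function(truth, scores) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.binary_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0); tn <- sum(truth == 0 & pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / (tp + fp + fn + tn), tp = tp, fp = fp, fn = fn,
    tn = tn)
}

#' Multi-label detection metrics
#'
#' Per-label precision/recall/F1/accuracy and AUC, plus two "overall" rows:
#' `micro` pools all label-instances before computing the metrics (AUC pools
#' the scores into one ROC), `macro` averages the per-label metrics.
#'
#' @param true_bits n x 3 0/1 matrix (columns SYSM, COMM, RMAN).
#' @param scores n x 3 score matrix in `[0, 1]`.
#' @param threshold Hard-decision threshold (score >= threshold is a 1).
#' @return A `detection_report` tibble: one row per label plus `micro` and
#'   `macro`.
#' @export
detection_metrics <- function(true_bits, scores, threshold = 0.5) {
  true_bits <- as.matrix(true_bits); scores <- as.matrix(scores)
  stopifnot(ncol(true_bits) == ncol(scores), nrow(true_bits) == nrow(scores))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  labels <- colnames(true_bits) %||% DETECTION_LABELS
  pred <- (scores >= threshold) * 1L
  rows <- lapply(seq_along(labels), function(j) {
    m <- unname(.binary_metrics(true_bits[, j], pred[, j]))
    tibble::tibble(label = labels[j], precision = m[1], recall = m[2],
                   f1 = m[3], accuracy = m[4],
                   auc = auc_score(true_bits[, j], scores[, j]))
  })
  per <- do.call(rbind, rows)
  mi <- unname(.binary_metrics(as.vector(true_bits), as.vector(pred)))
  micro <- tibble::tibble(label = "micro", precision = mi[1], recall = mi[2],
                          f1 = mi[3], accuracy = mi[4],
                          auc = auc_score(as.vector(true_bits), as.vector(scores)))
  macro <- tibble::tibble(label = "macro",
                          precision = mean(per$precision),
                          recall = mean(per$recall), f1 = mean(per$f1),
                          accuracy = mean(per$accuracy), auc = mean(per$auc))
  out <- rbind(per, micro, macro)
  class(out) <- c("detection_report", class(out))
  out
}

#' Operator error rates per subject and subtask
#'
#' The four error definitions of the study protocol: SYSM and COMM are the
#' ratio of unsuccessful responses to total calls; TRCK is the fraction of
#' ML+HL time the tracking circle was out of bounds; RMAN is the fraction of
#' non-PW time the tank levels were out of bounds.
#'
#' @param events Named list of `event_log`s (one per session).
#' @param responses Named list of matching `response_log`s.
#' @param configs Named list of matching `session_config`s.
#' @return A tibble: `subject_id`, `subtask`, `error_rate`.
#' @export
error_rates <- function(events, responses, configs) {
  ids <- names(configs)
  if (!all(ids %in% names(responses)) || !all(ids %in% names(events))) {
    stop("missing logs for session(s): ",
         paste(setdiff(ids, intersect(names(responses), names(events))),
               collapse = ", "))
  }
  per_session <- lapply(ids, function(sid) {
    cfg <- configs[[sid]]; rs <- responses[[sid]]
    bt <- block_table(cfg)
    oob <- attr(rs, "oob")
    calls <- function(task) {
      r <- rs[rs$subtask == task, ]
      c(err = sum(r$error), tot = nrow(r))
    }
    oob_time <- function(task) {
      o <- oob[oob$subtask == task, ]
      if (!nrow(o)) 0 else sum(o$end - o$start)
    }
    tibble::tibble(
      subject_id = cfg$subject_id,
      sysm_err = calls("SYSM")["err"], sysm_tot = calls("SYSM")["tot"],
      comm_err = calls("COMM")["err"], comm_tot = calls("COMM")["tot"],
      trck_oob = oob_time("TRCK"),
      trck_time = sum(bt$duration[bt$block_type %in% c("ML", "HL")]),
      rman_oob = oob_time("RMAN"),
      rman_time = sum(bt$duration[bt$block_type != "PW"]))
  })
  d <- do.call(rbind, per_session)
  agg <- function(num, den) {
    s <- rowsum(cbind(num, den), d$subject_id)
    unname(s[, 1] / s[, 2])
  }
  subjects <- sort(unique(d$subject_id))
  out <- rbind(
    tibble::tibble(subject_id = subjects, subtask = "SYSM",
                   error_rate = agg(d$sysm_err, d$sysm_tot)),
    tibble::tibble(subject_id = subjects, subtask = "TRCK",
                   error_rate = agg(d$trck_oob, d$trck_time)),
    tibble::tibble(subject_id = subjects, subtask = "COMM",
                   error_rate = agg(d$comm_err, d$comm_tot)),
    tibble::tibble(subject_id = subjects, subtask = "RMAN",
                   error_rate = agg(d$rman_oob, d$rman_time)))
  out
}
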