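# Training configuration, the warmup/constant/cosine learning-rate schedule,
# the AdamW training loop, and batched prediction.

#' Training configuration
#'
#' The full-scale schedule of the study design: 35 epochs, learning rate rising
#' linearly to 0.05 over the first 5 epochs, constant to epoch 20, then
#' cosine-decaying to 0.005 at epoch 35. The schedule steps per epoch.
#' Scaled-down validation runs may override the epoch count and rates.
#'
#' @param epochs Training epochs.
#' @param peak_lr,warmup_epochs,constant_until_epoch,final_lr Schedule
#'   parameters (see above).
#' @param batch_size Minibatch size.
#' @param weight_decay AdamW decoupled weight decay (weight matrices only).
#' @param rng_seed Seed for shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 35, peak_lr = 0.05, warmup_epochs = 5,
                         constant_until_epoch = 20, final_lr = 0.005,
                         batch_size = 64, weight_decay = 0.01, rng_seed = 0L) {
  if (!(warmup_epochs < constant_until_epoch && constant_until_epoch < epochs)) {
    stop("need warmup_epochs < constant_until_epoch < epochs")
  }
  if (final_lr >= peak_lr) stop("final_lr must be below peak_lr")
  structure(list(epochs = epochs, peak_lr = peak_lr,
                 warmup_epochs = warmup_epochs,
                 constant_until_epoch = constant_until_epoch,
                 final_lr = final_lr, batch_size = batch_size,
                 weight_decay = weight_decay, rng_seed = rng_seed),
            class = "train_config")
}

#' Learning rate at a (possibly fractional) epoch
#'
#' Piecewise schedule: linear from 0 to the peak over `(0, warmup]`, the
#' peak over `(warmup, constant_until]`, then a cosine decay from peak to
#' final over `(constant_until, epochs]`.
#'
#' @param e Epoch in `(0, epochs]`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_at_epoch <- function(e, cfg = train_config()) {
  if (any(e <= 0 | e > cfg$epochs)) stop("epoch out of range (0, epochs]")
  ifelse(e <= cfg$warmup_epochs,
         cfg$peak_lr * e / cfg$warmup_epochs,
         ifelse(e <= cfg$constant_until_epoch,
                cfg$peak_lr,
                cfg$final_lr + (cfg$peak_lr - cfg$final_lr) * 0.5 *
                  (1 + cos(pi * (e - cfg$constant_until_epoch) /
                             (cfg$epochs - cfg$constant_until_epoch)))))
}

# Targets for a model head from a segment index tibble.
.targets_for <- function(task, index) {
  if (task == "tl") {
    if (!"tl_label" %in% names(index)) stop("segments lack tl_label")
    y <- match(index$tl_label, TL_LEVELS)
    if (anyNA(y)) stop("unknown task-load label")
    y
  } else {
    if (!all(DETECTION_LABELS %in% names(index))) {
      stop("segments lack subtask bit columns")
    }
    t(as.matrix(index[, DETECTION_LABELS]))  # (3, N)
  }
}

#' Train a model on labeled segments
#'
#' Trains with AdamW under the scheduled learning rate, using only segments
#' whose session is in the split's training set. Passing `train_ids` that
#' intersect the split's test sessions is an error (leakage guard).
#'
#' @param model An untrained `matb_model` from [build_model()].
#' @param segments A list with `x` (channels x samples x n array) and
#'   `index` (tibble with `session_id` and labels), e.g. from
#'   [study_segments()].
#' @param split A `split_plan`.
#' @param cfg A [train_config()].
#' @param train_ids Session ids to train on; defaults to `split$train`.
#' @param verbose Print per-epoch loss?
#' @return The trained `matb_model` with a `history` tibble (`epoch`, `lr`,
#'   `loss`).
#' @export
train_model <- function(model, segments, split, cfg = train_config(),
                        train_ids = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "matb_model"), inherits(split, "split_plan"))
  train_ids <- train_ids %||% split$train
  leak <- intersect(train_ids, split$test)
  if (length(leak)) {
    stop("leakage: session(s) in both training set and test set: ",
         paste(head(leak, 3), collapse = ", "))
  }
  sel <- which(segments$index$session_id %in% train_ids)
  if (!length(sel)) stop("empty training set")
  y_all <- .targets_for(model$dec$task, segments$index)
  state <- adamw_init(model$params)
  history <- vector("list", cfg$epochs)
  with_rng(cfg$rng_seed, {
    for (e in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(e, cfg)
      ord <- sample(sel)
      losses <- numeric(0)
      for (i0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[i0:min(i0 + cfg$batch_size - 1, length(ord))]
        X <- segments$x[, , idx, drop = FALSE]
        fw <- model_forward(model, X, training = TRUE)
        ls <- if (model$dec$task == "tl") {
          softmax_ce(fw$logits, y_all[idx])
        } else {
          sigmoid_bce(fw$logits, y_all[, idx, drop = FALSE])
        }
        grads <- model_backward(model, ls$dlogits, fw)
        st <- adamw_step(model$params, grads, state, lr, cfg$weight_decay,
                         model$decay)
        model$params <- st$params
        state <- st$state
        losses <- c(losses, ls$loss)
      }
      history[[e]] <- tibble::tibble(epoch = e, lr = lr, loss = mean(losses))
      if (verbose) {
        message(sprintf("epoch %2d  lr %.4g  loss %.4f", e, lr, mean(losses)))
      }
    }
  })
  model$history <- do.call(rbind, history)
  model$train_cfg <- cfg
  model
}

#' Predict scores and hard labels for segments
#'
#' Batched forward pass in evaluation mode (no dropout). Per-sample
#' normalization makes outputs independent of batch composition and order.
#'
#' @param model A trained `matb_model`.
#' @param segments A segment list (`x`, `index`) or a bare 3-D array.
#' @param batch_size Forward batch size.
#' @param threshold Hard-decision threshold for the sigmoid head; a score
#'   exactly at the threshold is labeled 1.
#' @return A list: `scores` (n x out_dim matrix) and `labels` (character
#'   task-load labels, or an n x 3 0/1 matrix).
#' @export
predict_model <- function(model, segments, batch_size = 256, threshold = 0.5) {
  X_all <- if (is.list(segments)) segments$x else segments
  if (dim(X_all)[1] != model$enc$input_channels) {
    stop(sprintf("segment channel count %d does not match the model input (%d)",
                 dim(X_all)[1], model$enc$input_channels))
  }
  n <- dim(X_all)[3]
  scores <- matrix(NA_real_, n, model$dec$out_dim)
  for (i0 in seq(1, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1, n)
    fw <- model_forward(model, X_all[, , idx, drop = FALSE], training = FALSE)
    scores[idx, ] <- t(fw$probs)
  }
  if (model$dec$task == "tl") {
    colnames(scores) <- TL_LEVELS
    labels <- TL_LEVELS[max.col(scores, ties.method = "first")]
  } else {
    colnames(scores) <- DETECTION_LABELS
    labels <- (scores >= threshold) * 1L
  }
  list(scores = scores, labels = labels)
}
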