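# The encoder-decoder model. The encoder is a 10-layer 1-D CNN over time
# (wav2vec-style feature encoder): kernel sizes (3, 2, 2, 3, 4, 5, 6, 7, 8,
# 9) and strides (2, 1, 1, 1, 2, 2, 2, 1, 2, 1), valid convolutions, group
# normalization + GELU + dropout between layers, and residual skip
# connections over the second and third layers (each kernel 2 / stride 1;
# the identity path is cropped by its trailing frame before addition). The
# decoder pools encoder frames over time (concatenated mean and max
# pooling, so sustained spectral shifts and brief event-locked bursts both
# survive the temporal collapse) and applies a 2-layer fully connected
# network: a softmax head with 4 classes for task-load classification or an
# elementwise-sigmoid head with 3 outputs for subtask detection.

#' Encoder configuration
#'
#' @param n_layers Number of convolutional layers.
#' @param conv_channels Channels per convolutional layer.
#' @param kernel_sizes,strides Per-layer kernel sizes and strides.
#' @param skip_layers Indices of layers wrapped with a residual connection.
#' @param input_channels Input channel count (25 after re-referencing).
#' @param dropout_p Dropout probability between layers.
#' @param n_groups Groups for the per-sample group normalization; the
#'   default (1) normalizes each sample over all channels and frames, which
#'   keeps outputs batch-size independent at minimal cost.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(n_layers = 10, conv_channels = 128,
                           kernel_sizes = c(3, 2, 2, 3, 4, 5, 6, 7, 8, 9),
                           strides = c(2, 1, 1, 1, 2, 2, 2, 1, 2, 1),
                           skip_layers = c(2, 3), input_channels = 25,
                           dropout_p = 0.1, n_groups = 1) {
  if (length(kernel_sizes) != n_layers || length(strides) != n_layers) {
    stop("kernel_sizes and strides must have length n_layers")
  }
  if (any(skip_layers > n_layers | skip_layers < 1)) stop("invalid skip layer")
  if (conv_channels %% n_groups != 0) {
    stop("conv_channels must be divisible by n_groups")
  }
  for (l in skip_layers) {
    if (strides[l] != 1) stop("skip connections require stride-1 layers")
  }
  structure(list(n_layers = n_layers, conv_channels = conv_channels,
                 kernel_sizes = kernel_sizes, strides = strides,
                 skip_layers = skip_layers, input_channels = input_channels,
                 dropout_p = dropout_p, n_groups = n_groups),
            class = "encoder_config")
}

#' Decoder configuration
#'
#' @param task `"tl"` (4-class softmax head) or `"subtask"` (3-label
#'   sigmoid head).
#' @param hidden_units Width of the hidden fully connected layer.
#' @return A `decoder_config` list with `out_dim` and `output_map` set from
#'   the task.
#' @export
decoder_config <- function(task = c("tl", "subtask"), hidden_units = 128) {
  task <- match.arg(task)
  structure(list(task = task, hidden_units = hidden_units,
                 out_dim = if (task == "tl") 4L else 3L,
                 output_map = if (task == "tl") "softmax" else "sigmoid"),
            class = "decoder_config")
}

#' Encoder output length in frames
#'
#' Applies the valid-convolution length recurrence
#' `L <- floor((L - k) / s) + 1` per layer. A 10 s segment at 125 Hz (1250
#' samples) yields 23 frames; a 15 s segment (1875 samples) yields 42.
#'
#' @param input_samples Input length in samples (>= 1).
#' @param config An [encoder_config()].
#' @return Integer number of frames; errors if any layer exhausts the
#'   sequence.
#' @export
encoder_output_length <- function(input_samples, config = encoder_config()) {
  stopifnot(input_samples >= 1)
  L <- input_samples
  for (l in seq_len(config$n_layers)) {
    L <- floor((L - config$kernel_sizes[l]) / config$strides[l]) + 1
    if (L < 1) {
      stop(sprintf("input of %d samples is exhausted at encoder layer %d",
                   input_samples, l))
    }
  }
  as.integer(L)
}

#' Build an untrained encoder-decoder model
#'
#' Weights are He-initialized; the construction is a pure function of the
#' configs and `rng_seed`.
#'
#' @param enc An [encoder_config()].
#' @param dec A [decoder_config()].
#' @param rng_seed Integer seed for the initialization.
#' @return A `matb_model` list with `params` (named list of arrays),
#'   `enc`, `dec`.
#' @export
build_model <- function(enc = encoder_config(), dec = decoder_config("tl"),
                        rng_seed = 0L) {
  stopifnot(inherits(enc, "encoder_config"), inherits(dec, "decoder_config"))
  with_rng(rng_seed, {
    params <- list()
    decay <- logical(0)
    in_ch <- enc$input_channels
    for (l in seq_len(enc$n_layers)) {
      k <- enc$kernel_sizes[l]
      fan_in <- in_ch * k
      params[[sprintf("conv%d_W", l)]] <-
        matrix(rnorm(enc$conv_channels * fan_in, 0, sqrt(2 / fan_in)),
               enc$conv_channels, fan_in)
      params[[sprintf("conv%d_b", l)]] <- rep(0, enc$conv_channels)
      params[[sprintf("norm%d_gamma", l)]] <- rep(1, enc$conv_channels)
      params[[sprintf("norm%d_beta", l)]] <- rep(0, enc$conv_channels)
      decay <- c(decay, TRUE, FALSE, FALSE, FALSE)
      in_ch <- enc$conv_channels
    }
    pooled_dim <- 2L * enc$conv_channels  # mean + max pooling, concatenated
    # per-sample normalization of the pooled vector stabilizes the FC stack
    # (the max branch has a different scale than the mean branch)
    params$dnorm_gamma <- rep(1, pooled_dim)
    params$dnorm_beta <- rep(0, pooled_dim)
    decay <- c(decay, FALSE, FALSE)
    params$fc1_W <- matrix(rnorm(dec$hidden_units * pooled_dim, 0,
                                 sqrt(2 / pooled_dim)),
                           dec$hidden_units, pooled_dim)
    params$fc1_b <- rep(0, dec$hidden_units)
    params$fc2_W <- matrix(rnorm(dec$out_dim * dec$hidden_units, 0,
                                 sqrt(2 / dec$hidden_units)),
                           dec$out_dim, dec$hidden_units)
    params$fc2_b <- rep(0, dec$out_dim)
    decay <- c(decay, TRUE, FALSE, TRUE, FALSE)
    structure(list(params = params, decay = decay, enc = enc, dec = dec),
              class = "matb_model")
  })
}

#' @export
print.matb_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<matb_model> %s head, %d conv layers x %d ch, %s parameters\n",
              x$dec$task, x$enc$n_layers, x$enc$conv_channels,
              format(n_par, big.mark = ",")))
  invisible(x)
}

# Full forward pass. X: (input_channels, samples, batch). Returns logits
# (out_dim, batch), probabilities, and (when training) the caches needed for
# the backward pass.
model_forward <- function(model, X, training = FALSE) {
  enc <- model$enc; P <- model$params
  caches <- if (training) vector("list", enc$n_layers) else NULL
  skip_scale <- if (is.null(model$skip_scale)) 1 else model$skip_scale
  for (l in seq_len(enc$n_layers)) {
    X_in <- X
    cf <- conv1d_forward(X, P[[sprintf("conv%d_W", l)]],
                         P[[sprintf("conv%d_b", l)]], enc$strides[l])
    gf <- groupnorm_forward(cf$Y, P[[sprintf("norm%d_gamma", l)]],
                            P[[sprintf("norm%d_beta", l)]], enc$n_groups)
    act <- gelu_forward(gf$Y)
    df <- dropout_forward(act$Y, enc$dropout_p, training)
    X <- df$Y
    is_skip <- l %in% enc$skip_layers && dim(X_in)[1] == dim(X)[1]
    if (is_skip && skip_scale != 0) {
      # identity path cropped to the conv output length
      X <- X + skip_scale * X_in[, seq_len(dim(X)[2]), , drop = FALSE]
    }
    if (training) {
      caches[[l]] <- list(conv = cf$cache, norm = gf$cache, pre_act = gf$Y,
                          gate = act$gate, mask = df$mask, is_skip = is_skip)
    }
  }
  d <- dim(X); L_frames <- d[2]
  Xp <- aperm(X, c(2, 1, 3))          # (frames, channels, batch)
  dim(Xp) <- c(L_frames, d[1] * d[3])
  mean_pool <- matrix(colSums(Xp) / L_frames, d[1], d[3])
  max_idx <- max.col(t(Xp), ties.method = "first")
  max_pool <- matrix(Xp[cbind(max_idx, seq_along(max_idx))], d[1], d[3])
  pooled_raw <- rbind(mean_pool, max_pool)    # (2 * channels, batch)
  pn <- groupnorm_forward(array(pooled_raw, c(2L * d[1], 1L, d[3])),
                          P$dnorm_gamma, P$dnorm_beta, G = 1)
  pooled <- matrix(pn$Y, 2L * d[1], d[3])
  H_pre <- P$fc1_W %*% pooled + P$fc1_b
  H <- relu_forward(H_pre)
  logits <- P$fc2_W %*% H + P$fc2_b
  probs <- if (model$dec$output_map == "softmax") {
    ex <- exp(sweep(logits, 2, apply(logits, 2, max)))
    sweep(ex, 2, colSums(ex), "/")
  } else {
    1 / (1 + exp(-logits))
  }
  list(logits = logits, probs = probs,
       cache = if (training) list(layers = caches, enc_out = X,
                                  pooled = pooled, H_pre = H_pre, H = H,
                                  L_frames = L_frames,
                                  max_idx = max_idx,
                                  dnorm = pn$cache) else NULL)
}

# Backward pass from dlogits; returns gradients named like params.
model_backward <- function(model, dlogits, fw) {
  P <- model$params; enc <- model$enc; cache <- fw$cache
  grads <- list()
  grads$fc2_W <- tcrossprod(dlogits, cache$H)
  grads$fc2_b <- rowSums(dlogits)
  dH <- crossprod(P$fc2_W, dlogits)
  dH_pre <- relu_backward(dH, cache$H_pre)
  grads$fc1_W <- tcrossprod(dH_pre, cache$pooled)
  grads$fc1_b <- rowSums(dH_pre)
  dpooled_n <- crossprod(P$fc1_W, dH_pre)        # (2 * channels, batch)
  d <- dim(cache$enc_out)
  nb <- groupnorm_backward(array(dpooled_n, c(2L * d[1], 1L, d[3])),
                           P$dnorm_gamma, cache$dnorm)
  grads$dnorm_gamma <- as.vector(nb$dgamma)
  grads$dnorm_beta <- as.vector(nb$dbeta)
  dpooled <- matrix(nb$dX, 2L * d[1], d[3])
  dmean <- dpooled[seq_len(d[1]), , drop = FALSE]
  dmax <- dpooled[d[1] + seq_len(d[1]), , drop = FALSE]
  # mean-pool backward: spread evenly over frames
  dX <- aperm(array(rep(t(dmean) / cache$L_frames, each = d[2]),
                    c(d[2], d[3], d[1])), c(3, 1, 2))
  # max-pool backward: route to the argmax frame of each (channel, sample)
  cb_grid <- cbind(rep(seq_len(d[1]), d[3]),          # channel
                   cache$max_idx,                     # frame
                   rep(seq_len(d[3]), each = d[1]))   # sample
  flat <- cb_grid[, 1] + (cb_grid[, 2] - 1) * d[1] +
    (cb_grid[, 3] - 1) * d[1] * d[2]
  dX[flat] <- dX[flat] + as.vector(dmax)
  skip_scale <- if (is.null(model$skip_scale)) 1 else model$skip_scale
  for (l in rev(seq_len(enc$n_layers))) {
    cl <- cache$layers[[l]]
    d_after <- dX
    d_drop <- dropout_backward(d_after, cl$mask)
    dA <- gelu_backward(d_drop, cl$pre_act, cl$gate)
    gb <- groupnorm_backward(dA, P[[sprintf("norm%d_gamma", l)]], cl$norm)
    grads[[sprintf("norm%d_gamma", l)]] <- gb$dgamma
    grads[[sprintf("norm%d_beta", l)]] <- gb$dbeta
    cb <- conv1d_backward(gb$dX, P[[sprintf("conv%d_W", l)]], cl$conv,
                          need_dx = l > 1)
    grads[[sprintf("conv%d_W", l)]] <- cb$dW
    grads[[sprintf("conv%d_b", l)]] <- cb$db
    dX <- cb$dX
    if (cl$is_skip && skip_scale != 0) {
      L_out <- dim(d_after)[2]
      dX[, seq_len(L_out), ] <- dX[, seq_len(L_out), , drop = FALSE] +
        skip_scale * d_after
    }
  }
  grads[names(P)]
}
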