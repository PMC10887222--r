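# Forward-modeled EEG.
#
# Each channel is a sum of: 1/f background noise; a frontal theta (4-7 Hz)
# source whose gain is a nondecreasing step function of the block's task
# load; a parietal alpha (8-12 Hz) source with nonincreasing gain; one
# narrowband spatially weighted signature per subtask, active only while the
# operator is engaged with that subtask (TRCK: continuously during ML/HL
# blocks); and stereotyped frontal blink transients at a Poisson rate.
# This encodes, as generator ground truth, the classical workload spectral
# facts (frontal theta rises and parietal alpha falls with task demands)
# plus subtask-specific activity the detection head is meant to find.

#' EEG generator parameters
#'
#' @param n_channels,sample_rate Fixed acquisition geometry: 24 channels at
#'   500 Hz.
#' @param channel_names 10-20 montage labels.
#' @param theta_band,alpha_band,beta_band Band edges in Hz.
#' @param theta_gain Per-class frontal theta source amplitude (uV RMS),
#'   nondecreasing over PW, LL, ML, HL.
#' @param alpha_gain Per-class parietal alpha source amplitude (uV RMS),
#'   nonincreasing.
#' @param signature_gain Named per-subtask signature amplitudes (uV RMS).
#' @param background_scale 1/f background RMS per channel (uV).
#' @param background_exponent Spectral exponent of the background
#'   (power ~ 1/f^exponent).
#' @param blink_rate Blinks per minute.
#' @param blink_scale Peak blink amplitude at Fp1/Fp2 (uV).
#' @param ml_hl_confusable When `TRUE`, ML and HL share identical source
#'   statistics (their class gains are averaged), so the two classes differ
#'   only in event-locked signature counts.
#' @return An `eeg_gen_params` list.
#' @export
eeg_gen_params <- function(n_channels = 24, sample_rate = 500,
                           channel_names = matb_channels(),
                           theta_band = c(4, 7), alpha_band = c(8, 12),
                           beta_band = c(13, 30),
                           theta_gain = c(PW = 2, LL = 5, ML = 8, HL = 11),
                           alpha_gain = c(PW = 11, LL = 8, ML = 5, HL = 2),
                           signature_gain = c(SYSM = 4, COMM = 4, RMAN = 4, TRCK = 3),
                           background_scale = 10,
                           background_exponent = 1,
                           blink_rate = 15, blink_scale = 80,
                           ml_hl_confusable = FALSE) {
  stopifnot(n_channels == 24, length(channel_names) == n_channels,
            all(theta_gain >= 0), all(alpha_gain >= 0), all(signature_gain >= 0),
            background_scale >= 0, blink_rate >= 0)
  if (ml_hl_confusable) {
    theta_gain[c("ML", "HL")] <- mean(theta_gain[c("ML", "HL")])
    alpha_gain[c("ML", "HL")] <- mean(alpha_gain[c("ML", "HL")])
  } else {
    if (is.unsorted(theta_gain[TL_LEVELS])) {
      stop("theta_gain must be nondecreasing over PW, LL, ML, HL")
    }
    if (is.unsorted(rev(alpha_gain[TL_LEVELS]))) {
      stop("alpha_gain must be nonincreasing over PW, LL, ML, HL")
    }
  }
  structure(list(n_channels = n_channels, sample_rate = sample_rate,
                 channel_names = channel_names, theta_band = theta_band,
                 alpha_band = alpha_band, beta_band = beta_band,
                 theta_gain = theta_gain, alpha_gain = alpha_gain,
                 signature_gain = signature_gain,
                 background_scale = background_scale,
                 background_exponent = background_exponent,
                 blink_rate = blink_rate, blink_scale = blink_scale,
                 ml_hl_confusable = ml_hl_confusable),
            class = "eeg_gen_params")
}

#' High-contrast generator preset for desk-scale validation runs
#'
#' The default parameters emulate realistically subtle workload effects; this
#' preset raises source-to-background contrast so that scaled-down training
#' experiments (few subjects, few epochs) have learnable structure.
#'
#' @param ... Overrides passed to [eeg_gen_params()].
#' @return An `eeg_gen_params` list.
#' @export
eeg_params_strong <- function(...) {
  # Brief engagements (a SYSM click lasts under a second of a 15 s window)
  # need proportionally stronger bursts to remain detectable after temporal
  # pooling, hence the graded per-subtask gains.
  args <- list(theta_gain = c(PW = 1, LL = 5, ML = 9, HL = 13),
               alpha_gain = c(PW = 13, LL = 9, ML = 5, HL = 1),
               signature_gain = c(SYSM = 16, COMM = 16, RMAN = 10, TRCK = 6),
               background_scale = 8)
  override <- list(...)
  args[names(override)] <- override
  do.call(eeg_gen_params, args)
}

# Spatial weight vectors (length 24, sum of squares normalized to 1).
.spatial_weights <- function(channel_names, focus, spread = 0.25) {
  w <- rep(spread, length(channel_names))
  w[channel_names %in% focus] <- 1
  w / sqrt(sum(w^2))
}

signature_topographies <- function(channel_names) {
  list(
    SYSM = list(band = c(18, 28),
                w = .spatial_weights(channel_names, c("Cz", "C3", "C4", "CPz"))),
    COMM = list(band = c(5, 9),
                w = .spatial_weights(channel_names, c("T7", "T8", "F7", "F8"))),
    RMAN = list(band = c(9, 13),
                w = .spatial_weights(channel_names, c("Fz", "AFz", "F3", "F4"))),
    TRCK = list(band = c(13, 18),
                w = .spatial_weights(channel_names, c("Pz", "CPz", "P3", "P4")))
  )
}

# Unit-RMS narrowband Gaussian noise via frequency-domain shaping with
# raised-cosine band edges (0.5 Hz roll-off).
.band_noise <- function(n, fs, band, roll = 0.5) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  g <- rep(0, n)
  inside <- f >= band[1] & f <= band[2]
  g[inside] <- 1
  lo <- f >= band[1] - roll & f < band[1]
  g[lo] <- 0.5 * (1 + cos(pi * (band[1] - f[lo]) / roll))
  hi <- f > band[2] & f <= band[2] + roll
  g[hi] <- 0.5 * (1 + cos(pi * (f[hi] - band[2]) / roll))
  x <- Re(fft(fft(rnorm(n)) * g, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Unit-RMS 1/f^(exponent/2)-amplitude background noise, one column per
# channel (single FFT pair over all channels).
.pink_noise_mat <- function(n, fs, exponent, nch) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  g <- c(0, pmax(f[-1], 0.5)^(-exponent / 2))
  W <- matrix(rnorm(n * nch), n, nch)
  X <- Re(stats::mvfft(stats::mvfft(W) * g, inverse = TRUE)) / n
  rms <- sqrt(colMeans(X^2))
  sweep(X, 2, rms, "/")
}

.pink_noise <- function(n, fs, exponent) drop(.pink_noise_mat(n, fs, exponent, 1))

# Biphasic blink template (Gaussian derivative, ~400 ms support), peak 1.
.blink_template <- function(fs) {
  t <- seq(-0.2, 0.2, by = 1 / fs)
  v <- -t * exp(-t^2 / (2 * 0.06^2))
  v / max(abs(v))
}

# 0/1 indicator over [0, dur) sampled at fs from a set of intervals.
.interval_indicator <- function(n, fs, starts, ends) {
  ind <- numeric(n)
  for (k in seq_along(starts)) {
    i0 <- max(1L, floor(starts[k] * fs) + 1L)
    i1 <- min(n, ceiling(ends[k] * fs))
    if (i1 >= i0) ind[i0:i1] <- 1
  }
  ind
}

new_eeg_recording <- function(data, sample_rate, channel_names,
                              subject_id = NA_character_,
                              session_id = NA_character_) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names))
  structure(list(data = data, sample_rate = sample_rate,
                 channel_names = channel_names, subject_id = subject_id,
                 session_id = session_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s / %s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session_id, nrow(x$data), ncol(x$data),
              x$sample_rate, ncol(x$data) / x$sample_rate))
  invisible(x)
}

#' Synthesize a session's EEG recording
#'
#' @param config A `session_config`.
#' @param events The session's `event_log`.
#' @param responses The session's `response_log`.
#' @param params An [eeg_gen_params()] list.
#' @param rng_seed Integer seed; the recording is a pure (bit-reproducible)
#'   function of its inputs and this seed.
#' @return An `eeg_recording`: 24 x (duration x 500) matrix of microvolt
#'   samples plus metadata.
#' @export
synthesize_eeg <- function(config, events, responses, params = eeg_gen_params(),
                           rng_seed = 0L) {
  stopifnot(inherits(params, "eeg_gen_params"))
  if (!identical(attr(events, "session_id"), config$session_id) ||
      !identical(attr(responses, "session_id"), config$session_id)) {
    stop("events/responses do not belong to this session config")
  }
  fs <- params$sample_rate
  dur <- session_duration(config)
  n <- as.integer(round(dur * fs))
  bt <- block_table(config)
  ch <- params$channel_names

  with_rng(rng_seed, {
    # Work in (samples x channels) orientation: channel updates are then
    # contiguous column writes. Transposed once at the end.
    X <- params$background_scale *
      .pink_noise_mat(n, fs, params$background_exponent, params$n_channels)

    # Per-sample class gain steps (integer-coded block types).
    type_code <- rep(match(bt$block_type, TL_LEVELS),
                     times = round(bt$duration * fs))[seq_len(n)]
    g_theta <- unname(params$theta_gain[TL_LEVELS])[type_code]
    g_alpha <- unname(params$alpha_gain[TL_LEVELS])[type_code]

    add_source <- function(src, w) {
      idx <- which(w > 0)
      X[, idx] <<- X[, idx] + tcrossprod(src, w[idx])
    }
    w_f <- .spatial_weights(ch, frontal_channels(), spread = 0.15)
    w_p <- .spatial_weights(ch, parietal_channels(), spread = 0.15)
    add_source(.band_noise(n, fs, params$theta_band) * g_theta, w_f)
    add_source(.band_noise(n, fs, params$alpha_band) * g_alpha, w_p)

    # Subtask signatures, gated by engagement.
    topo <- signature_topographies(ch)
    for (task in c("SYSM", "COMM", "RMAN")) {
      gain <- params$signature_gain[[task]]
      if (gain <= 0) next
      iv <- engagement_intervals(responses, task)
      if (!nrow(iv)) next
      ind <- .interval_indicator(n, fs, iv$start, iv$end)
      if (!any(ind > 0)) next
      add_source(.band_noise(n, fs, topo[[task]]$band) * ind * gain,
                 topo[[task]]$w)
    }
    # TRCK: continuous during ML (normal) and HL (faster drift -> stronger).
    if (params$signature_gain[["TRCK"]] > 0) {
      tb <- bt[bt$block_type %in% c("ML", "HL"), ]
      if (nrow(tb)) {
        scale_f <- ifelse(tb$block_type == "HL" & !params$ml_hl_confusable, 1.3, 1)
        ind <- numeric(n)
        for (k in seq_len(nrow(tb))) {
          i0 <- floor(tb$start[k] * fs) + 1L
          i1 <- min(n, ceiling(tb$end[k] * fs))
          ind[i0:i1] <- scale_f[k]
        }
        add_source(.band_noise(n, fs, topo$TRCK$band) * ind *
                     params$signature_gain[["TRCK"]], topo$TRCK$w)
      }
    }

    # Blinks: frontal-weighted stereotyped transients.
    n_blinks <- rpois(1, params$blink_rate * dur / 60)
    if (n_blinks > 0 && params$blink_scale > 0) {
      tpl <- .blink_template(fs)
      # Blink potentials fall off steeply with distance from the eyes.
      w_b <- rep(0, params$n_channels)
      w_b[ch %in% c("Fp1", "Fp2")] <- 1
      w_b[ch %in% c("AFz", "F3", "F4", "Fz")] <- 0.25
      w_b[ch %in% c("F7", "F8")] <- 0.15
      onsets <- sort(runif(n_blinks, 0, dur - 0.5))
      amps <- params$blink_scale * runif(n_blinks, 0.7, 1.3)
      blink_tr <- numeric(n)
      for (k in seq_len(n_blinks)) {
        i0 <- floor(onsets[k] * fs) + 1L
        idx <- i0:(i0 + length(tpl) - 1L)
        keep <- idx <= n
        blink_tr[idx[keep]] <- blink_tr[idx[keep]] + amps[k] * tpl[keep]
      }
      add_source(blink_tr, w_b)
    }
    data <- t(X)
    rownames(data) <- ch
    new_eeg_recording(data, fs, ch, config$subject_id, config$session_id)
  })
}
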