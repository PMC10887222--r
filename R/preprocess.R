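# Four-step raw-EEG preparation: (1) 1-40 Hz band-pass, (2) average
# re-referencing with the mean appended as a 25th channel, (3) per-channel
# standardization over the session, (4) downsampling 500 -> 125 Hz.
# Artifacts are deliberately NOT removed: the models train end-to-end on
# raw (filtered) data, blinks included.
#
# Filters are linear-phase FIR (windowed sinc via signal::fir1) applied in a
# single pass with reflection padding and exact group-delay compensation, so
# the chain is zero-phase and deterministic.

#' Preprocessing configuration
#'
#' @param band Band-pass edges, Hz.
#' @param target_rate Output sampling rate, Hz.
#' @param bandpass_order,antialias_order FIR filter orders (taps - 1).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(band = c(1, 40), target_rate = 125,
                              bandpass_order = 1500, antialias_order = 600) {
  structure(list(band = band, target_rate = target_rate,
                 bandpass_order = bandpass_order,
                 antialias_order = antialias_order),
            class = "preprocess_config")
}

# Zero-phase application of a symmetric odd-length FIR filter to every
# channel at once: anti-symmetric reflection padding + exact group-delay
# removal (no forward-backward double pass needed for a linear-phase FIR).
# The convolution runs as one FFT product over all channels.
.fir_zerophase_mat <- function(X, b) {
  n <- ncol(X); nch <- nrow(X)
  delay <- (length(b) - 1) / 2
  p <- delay
  if (n <= p + 1) stop("signal too short for this filter order")
  left <- 2 * X[, 1] - X[, seq(p + 1, 2), drop = FALSE]
  right <- 2 * X[, n] - X[, seq(n - 1, n - p), drop = FALSE]
  Xp <- cbind(left, X, right)                    # nch x (n + 2p)
  lin <- ncol(Xp) + length(b) - 1                # linear convolution length
  npad <- stats::nextn(lin, c(2, 3, 5))
  P <- matrix(0, npad, nch)
  P[seq_len(ncol(Xp)), ] <- t(Xp)
  B <- fft(c(b, rep(0, npad - length(b))))
  Y <- Re(stats::mvfft(stats::mvfft(P) * B, inverse = TRUE)) / npad
  # centered output for sample i of x sits at row p + delay + i
  t(Y[(p + delay + 1):(p + delay + n), , drop = FALSE])
}

.fir_zerophase <- function(x, b) {
  drop(.fir_zerophase_mat(matrix(x, nrow = 1), b))
}

apply_fir <- function(recording, b) {
  out <- recording
  dn <- dimnames(out$data)
  out$data <- .fir_zerophase_mat(out$data, b)
  dimnames(out$data) <- dn
  out
}

#' Band-pass filter a recording
#'
#' Zero-phase FIR band-pass retaining the brain-activity band. On a
#' white-noise probe the stopbands (0.2 Hz, 60 Hz) are attenuated by more
#' than 20 dB while the 5-35 Hz passband is flat to well within 1 dB.
#'
#' @param recording An `eeg_recording` (500 Hz input).
#' @param low,high Band edges in Hz; must lie inside (0, Nyquist).
#' @param order FIR order.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(recording, low = 1, high = 40, order = 1500) {
  fs <- recording$sample_rate
  if (low <= 0 || high <= low || high >= fs / 2) {
    stop("band edges must satisfy 0 < low < high < Nyquist")
  }
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  apply_fir(recording, b)
}

#' Average re-reference, appending the mean as a 25th channel
#'
#' Subtracts the cross-channel mean from each of the 24 channels and appends
#' that mean series as channel 25 (label `"AVG"`), compensating the rank
#' reduction of average re-referencing. At every sample the 24 re-referenced
#' channels sum to zero.
#'
#' @param recording A 24-channel `eeg_recording`.
#' @return A 25-channel `eeg_recording`.
#' @export
average_rereference <- function(recording) {
  if (nrow(recording$data) != 24) {
    stop("average_rereference expects 24 channels, got ", nrow(recording$data))
  }
  avg <- colMeans(recording$data)
  data <- rbind(sweep(recording$data, 2, avg), AVG = avg)
  new_eeg_recording(data, recording$sample_rate,
                    c(recording$channel_names, "AVG"),
                    recording$subject_id, recording$session_id)
}

#' Standardize each channel over the session
#'
#' Subtracts the channel mean and divides by the channel standard deviation
#' (population convention, i.e. divisor n), so each channel has mean 0 and
#' population sd 1 over the whole session.
#'
#' @param recording An `eeg_recording`; every channel must have nonzero
#'   variance.
#' @return The standardized `eeg_recording`.
#' @export
standardize_channels <- function(recording) {
  x <- recording$data
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  zero <- sd_pop < 1e-12
  if (any(zero)) {
    stop("zero-variance channel(s): ",
         paste(recording$channel_names[zero], collapse = ", "))
  }
  out <- recording
  out$data <- (x - mu) / sd_pop
  out
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase FIR anti-alias low-pass (cutoff just above the 40 Hz
#' band of interest) and keeps every `factor`-th sample, so content above
#' the retained band is suppressed by more than 20 dB while in-band
#' components (e.g. a 10 Hz sinusoid) survive within 2%.
#'
#' @param recording An `eeg_recording`.
#' @param factor Integer decimation factor; the input rate must be divisible
#'   by it.
#' @param order Anti-alias FIR order.
#' @param antialias Apply the anti-alias low-pass before decimating. Keep
#'   the default unless the input is already band-limited below the output
#'   Nyquist (as it is inside [preprocess_eeg()], where the 1-40 Hz
#'   band-pass precedes this step).
#' @return An `eeg_recording` at `sample_rate / factor` with
#'   `floor(n / factor)` samples.
#' @export
downsample_eeg <- function(recording, factor = 4, order = 600,
                           antialias = TRUE) {
  fs <- recording$sample_rate
  if (factor != as.integer(factor) || factor < 1) stop("factor must be a positive integer")
  if (fs %% factor != 0) {
    stop(sprintf("sample rate %g Hz is not divisible by factor %d", fs, factor))
  }
  if (factor == 1) return(recording)
  out <- if (antialias) {
    b <- signal::fir1(order, 43 / (fs / 2), type = "low")
    apply_fir(recording, b)
  } else recording
  n_keep <- floor(ncol(out$data) / factor)
  idx <- seq(1L, by = factor, length.out = n_keep)
  out$data <- out$data[, idx, drop = FALSE]
  out$sample_rate <- fs / factor
  out
}

#' Full preprocessing chain
#'
#' Band-pass (1-40 Hz) -> average re-reference (24 -> 25 channels) ->
#' per-channel standardization -> downsample to 125 Hz, in exactly this
#' order.
#'
#' @param recording A 24-channel 500 Hz `eeg_recording`.
#' @param config A [preprocess_config()].
#' @return A 25-channel `eeg_recording` at `config$target_rate`.
#' @export
preprocess_eeg <- function(recording, config = preprocess_config()) {
  factor <- recording$sample_rate / config$target_rate
  if (factor != as.integer(factor)) {
    stop("target rate must divide the input sample rate")
  }
  rec <- bandpass_filter(recording, config$band[1], config$band[2],
                         config$bandpass_order)
  rec <- average_rereference(rec)
  rec <- standardize_channels(rec)
  # The band-pass already confines the signal well below the output Nyquist
  # (40 Hz < 62.5 Hz), so plain decimation is alias-free here.
  downsample_eeg(rec, as.integer(factor),
                 antialias = config$band[2] > config$target_rate / 2 * 0.8)
}
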