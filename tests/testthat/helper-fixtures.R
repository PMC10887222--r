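# Shared fixtures, built in code. Tiny hand-rolled session configs let unit
# tests avoid the full 51-minute protocol where it is not the point.

# A minimal custom session: one block of each type (PW 60 s + 3 x 150 s).
tiny_config <- function(subject_id = "S01", session_id = "S01_R1",
                        types = c("PW", "LL", "ML", "HL"),
                        durations = c(60, 150, 150, 150)) {
  blocks <- Map(matbeeg:::block_spec, types, durations)
  names(blocks) <- NULL
  matbeeg:::new_session_config(session_id, subject_id, NULL, blocks,
                               integer(0))
}

# A small random recording.
tiny_recording <- function(n_ch = 24, n_samp = 1000, fs = 500, seed = 1) {
  set.seed(seed)
  data <- matrix(rnorm(n_ch * n_samp, sd = 20), n_ch)
  matbeeg:::new_eeg_recording(data, fs, matb_channels()[seq_len(n_ch)],
                              "S01", "S01_R1")
}

# Single-channel sine probe as a recording.
sine_recording <- function(freq, dur = 60, fs = 500, amp = 1) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  matbeeg:::new_eeg_recording(matrix(amp * sin(2 * pi * freq * t), 1), fs,
                              "Cz")
}

# RMS of the central portion (avoids filter edge effects).
central_rms <- function(x, trim = 0.2) {
  n <- length(x)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  sqrt(mean(x[i]^2))
}

# Mean band power of a signal via the raw periodogram.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  mean(p[f >= lo & f <= hi])
}

# A tiny event/response pair for labeling tests: explicit intervals.
toy_logs <- function(events_df, responses_df, session_id = "S01_R1") {
  ev <- tibble::as_tibble(events_df)
  attr(ev, "session_id") <- session_id
  attr(ev, "subject_id") <- "S01"
  class(ev) <- c("event_log", class(ev))
  rs <- tibble::as_tibble(responses_df)
  attr(rs, "session_id") <- session_id
  attr(rs, "subject_id") <- "S01"
  class(rs) <- c("response_log", class(rs))
  list(events = ev, responses = rs)
}
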