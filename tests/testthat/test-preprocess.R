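test_that("band-pass passes in-band tones and attenuates stopbands >= 20 dB", {
  g <- vapply(c(0.2, 10, 60), function(f) {
    out <- bandpass_filter(sine_recording(f))
    central_rms(out$data[1, ]) / central_rms(sine_recording(f)$data[1, ])
  }, 0)
  expect_lt(abs(g[2] - 1), 0.05)          # 10 Hz survives within 5%
  expect_lt(g[1], 10^(-20 / 20))          # 0.2 Hz down >= 20 dB
  expect_lt(g[3], 10^(-20 / 20))          # 60 Hz down >= 20 dB (>= 10x)
})

test_that("band-pass is zero-phase and removes DC", {
  # symmetric pulse: the filtered peak must not move
  n <- 20000
  x <- numeric(n); x[9800:10200] <- exp(-((-200:200)^2) / 2000)
  rec <- matbeeg:::new_eeg_recording(matrix(x, 1), 500, "Cz")
  out <- bandpass_filter(rec)
  expect_equal(which.max(out$data[1, ]), which.max(x), tolerance = 0)
  # DC offset removed
  dc <- tiny_recording(n_ch = 1, n_samp = 20000)
  dc$data <- dc$data + 100
  expect_lt(abs(mean(bandpass_filter(dc)$data[1, ])), 0.5)
  expect_error(bandpass_filter(tiny_recording(), low = 0), "Nyquist")
  expect_error(bandpass_filter(tiny_recording(), high = 300), "Nyquist")
})

test_that("average re-referencing is exact and zero-sum", {
  # hand-computable toy: 3 channels would not satisfy the 24-channel
  # contract, so build 24 channels with two distinct sample columns
  x <- matrix(0, 24, 2)
  x[1, ] <- c(24, 48)  # mean over channels: 1 at t1, 2 at t2
  rec <- matbeeg:::new_eeg_recording(x, 500, matb_channels())
  out <- average_rereference(rec)
  expect_equal(nrow(out$data), 25)
  expect_equal(out$data[25, ], c(1, 2))           # appended mean channel
  expect_equal(out$data[1, ], c(23, 46))          # 24 - 1, 48 - 2
  expect_equal(out$data[2, ], c(-1, -2))          # 0 - mean
  expect_equal(colSums(out$data[1:24, ]), c(0, 0))
  # identical channels: channels 1..24 vanish, channel 25 keeps the series
  y <- matrix(rep(sin(1:100), each = 24), 24)
  rec2 <- matbeeg:::new_eeg_recording(y, 500, matb_channels())
  out2 <- average_rereference(rec2)
  expect_equal(max(abs(out2$data[1:24, ])), 0)
  expect_equal(out2$data[25, ], sin(1:100))
  expect_error(average_rereference(out2), "24 channels")
})

test_that("standardization uses the population convention and is idempotent", {
  rec <- matbeeg:::new_eeg_recording(matrix(c(1, 3), 1), 500, "Cz")
  out <- standardize_channels(rec)
  expect_equal(out$data[1, ], c(-1, 1))
  big <- tiny_recording(n_ch = 4, n_samp = 5000)
  s1 <- standardize_channels(big)
  expect_equal(rowMeans(s1$data), rep(0, 4), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(s1$data^2)), rep(1, 4), tolerance = 1e-12)
  s2 <- standardize_channels(s1)
  expect_equal(s1$data, s2$data, tolerance = 1e-10)
  flat <- big
  flat$data[2, ] <- 7
  expect_error(standardize_channels(flat), "Fp2")
})

test_that("downsampling keeps in-band content and suppresses the rest", {
  rec <- sine_recording(10, dur = 60)
  out <- downsample_eeg(rec, 4)
  expect_equal(out$sample_rate, 125)
  expect_equal(ncol(out$data), floor(ncol(rec$data) / 4))
  expect_lt(abs(central_rms(out$data[1, ]) / central_rms(rec$data[1, ]) - 1),
            0.02)
  hi <- sine_recording(50, dur = 60)
  outh <- downsample_eeg(hi, 4)
  expect_lt(central_rms(outh$data[1, ]) / central_rms(hi$data[1, ]),
            10^(-20 / 20))
  expect_error(downsample_eeg(sine_recording(10), 3), "not divisible")
})

test_that("length arithmetic: 1,530,000 samples decimate to 382,500", {
  # pure length contract; use a cheap constant-free signal
  rec <- matbeeg:::new_eeg_recording(matrix(rnorm(2 * 1530000), 2), 500,
                                     c("Fz", "Pz"))
  out <- downsample_eeg(rec, 4, antialias = FALSE)
  expect_equal(ncol(out$data), 382500)
})

test_that("the full chain yields 25 standardized channels at 125 Hz", {
  cfg <- tiny_config()
  ev <- schedule_events(cfg, rng_seed = 1)
  rs <- simulate_behavior(ev, cfg, rng_seed = 2)
  rec <- synthesize_eeg(cfg, ev, rs, rng_seed = 3)
  out <- preprocess_eeg(rec)
  expect_equal(nrow(out$data), 25)
  expect_equal(out$sample_rate, 125)
  expect_equal(ncol(out$data), session_duration(cfg) * 125)
  # standardization drifts by < 5% through the final decimation
  expect_true(all(abs(apply(out$data, 1, sd) - 1) < 0.05))
  # deterministic
  out2 <- preprocess_eeg(synthesize_eeg(cfg, ev, rs, rng_seed = 3))
  expect_identical(out$data, out2$data)
})

test_that("blink artifacts survive preprocessing by design", {
  cfg <- tiny_config()
  ev <- schedule_events(cfg, rng_seed = 1)
  rs <- simulate_behavior(ev, cfg, rng_seed = 2)
  rec <- synthesize_eeg(cfg, ev, rs, rng_seed = 3)
  out <- preprocess_eeg(rec)
  fp1 <- out$data[1, ]
  pz <- out$data[which(out$channel_names == "Pz"), ]
  # frontal channels keep heavy-tailed transients relative to parietal ones
  kurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
  expect_gt(kurt(fp1), kurt(pz) + 0.5)
  expect_gt(max(abs(fp1)), 4)  # blink peaks stand clear of unit-sd noise
})
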