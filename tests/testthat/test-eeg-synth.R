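# Periodogram oracles over short custom sessions keep these checks cheap:
# one block per type (PW 60 s + LL/ML/HL 150 s each).

synth_tiny <- function(seed, params = eeg_gen_params(), cfg = tiny_config()) {
  ev <- schedule_events(cfg, rng_seed = seed)
  rs <- simulate_behavior(ev, cfg, rng_seed = seed + 1000)
  list(cfg = cfg, ev = ev, rs = rs,
       rec = synthesize_eeg(cfg, ev, rs, params, rng_seed = seed + 2000))
}

block_band_power <- function(rec, cfg, channels, lo, hi) {
  bt <- block_table(cfg)
  fs <- rec$sample_rate
  chs <- which(rec$channel_names %in% channels)
  vapply(seq_len(nrow(bt)), function(i) {
    i0 <- round(bt$start[i] * fs) + 1; i1 <- round(bt$end[i] * fs)
    mean(vapply(chs, function(c) band_power(rec$data[c, i0:i1], fs, lo, hi), 0))
  }, 0)
}

test_that("frontal theta rises and parietal alpha falls with task load", {
  n_seeds <- 10
  theta <- matrix(NA_real_, n_seeds, 4, dimnames = list(NULL, matbeeg:::TL_LEVELS))
  alpha <- theta
  for (s in seq_len(n_seeds)) {
    sim <- synth_tiny(100 + s)
    bt <- block_table(sim$cfg)
    th <- block_band_power(sim$rec, sim$cfg, matbeeg:::frontal_channels(), 4, 7)
    al <- block_band_power(sim$rec, sim$cfg, matbeeg:::parietal_channels(), 8, 12)
    theta[s, ] <- th[match(matbeeg:::TL_LEVELS, bt$block_type)]
    alpha[s, ] <- al[match(matbeeg:::TL_LEVELS, bt$block_type)]
  }
  # paired sign test on each adjacent class pair at alpha = 0.05
  for (j in 1:3) {
    up <- sum(theta[, j + 1] > theta[, j])
    expect_lt(binom.test(up, n_seeds, 0.5, alternative = "greater")$p.value,
              0.05)
    dn <- sum(alpha[, j + 1] < alpha[, j])
    expect_lt(binom.test(dn, n_seeds, 0.5, alternative = "greater")$p.value,
              0.05)
  }
  # and the theta/alpha workload index is strictly ordered on seed averages
  ratio <- colMeans(theta) / colMeans(alpha)
  expect_true(all(diff(ratio) > 0))
})

test_that("null generator has flat spectra with no class structure", {
  params <- eeg_gen_params(theta_gain = c(PW = 0, LL = 0, ML = 0, HL = 0),
                           alpha_gain = c(PW = 0, LL = 0, ML = 0, HL = 0),
                           signature_gain = c(SYSM = 0, COMM = 0, RMAN = 0,
                                              TRCK = 0),
                           background_exponent = 0, blink_rate = 0)
  sim <- synth_tiny(7, params)
  bt <- block_table(sim$cfg)
  th <- block_band_power(sim$rec, sim$cfg, matbeeg:::frontal_channels(), 4, 7)
  al <- block_band_power(sim$rec, sim$cfg, matbeeg:::parietal_channels(), 8, 12)
  ratio <- th / al
  expect_lt(max(ratio) / min(ratio), 1.25)  # equal within estimation error
})

test_that("subtask signatures appear only during engagement", {
  params <- eeg_params_strong(blink_rate = 0)
  sim <- synth_tiny(17, params)
  fs <- sim$rec$sample_rate
  iv <- engagement_intervals(sim$rs, "COMM")
  n <- ncol(sim$rec$data)
  ind <- matbeeg:::.interval_indicator(n, fs, iv$start, iv$end) > 0
  # exclude other windows' influence: compare COMM band power on COMM
  # channels engaged vs idle within task blocks
  ch <- which(sim$rec$channel_names == "T7")
  x <- sim$rec$data[ch, ]
  bt <- block_table(sim$cfg)
  task_time <- rep(FALSE, n)
  for (i in which(bt$block_type != "PW")) {
    task_time[(round(bt$start[i] * fs) + 1):round(bt$end[i] * fs)] <- TRUE
  }
  bp <- function(sel) {
    y <- x[sel]
    band_power(y[seq_len(min(length(y), 30000))], fs, 5, 9)
  }
  expect_gt(bp(ind & task_time), 2 * bp(!ind & task_time))
})

test_that("recordings are bit-identical under a repeated seed", {
  a <- synth_tiny(3)$rec
  b <- synth_tiny(3)$rec
  expect_identical(a$data, b$data)
  c <- synth_tiny(4)$rec
  expect_false(identical(a$data, c$data))
})

test_that("confusable mode makes ML and HL band powers indistinguishable", {
  params <- eeg_gen_params(ml_hl_confusable = TRUE)
  expect_equal(unname(params$theta_gain["ML"]), unname(params$theta_gain["HL"]))
  p_vals <- c()
  for (s in 1:5) {
    cfg <- tiny_config(types = c("PW", "ML", "HL", "ML", "HL"),
                       durations = c(60, 150, 150, 150, 150))
    prof <- behavior_profile()
    prof$rman_duty_cycle[c("ML", "HL")] <- mean(prof$rman_duty_cycle[c("ML", "HL")])
    ev <- schedule_events(cfg, rng_seed = 300 + s)
    rs <- simulate_behavior(ev, cfg, prof, rng_seed = 400 + s)
    rec <- synthesize_eeg(cfg, ev, rs, params, rng_seed = 500 + s)
    bt <- block_table(cfg)
    fs <- rec$sample_rate
    # per-10 s-window band powers per class, a few representative channels
    win_pow <- function(ty, ch_name, lo, hi) {
      ch <- which(rec$channel_names == ch_name)
      unlist(lapply(which(bt$block_type == ty), function(i) {
        starts <- seq(bt$start[i], bt$end[i] - 10, by = 10)
        vapply(starts, function(s0) {
          idx <- (round(s0 * fs) + 1):round((s0 + 10) * fs)
          band_power(rec$data[ch, idx], fs, lo, hi)
        }, 0)
      }))
    }
    for (ch_name in c("Fz", "Pz", "Cz", "T7")) {
      for (band in list(c(4, 7), c(8, 12), c(13, 30))) {
        p_vals <- c(p_vals, stats::wilcox.test(
          win_pow("ML", ch_name, band[1], band[2]),
          win_pow("HL", ch_name, band[1], band[2]))$p.value)
      }
    }
  }
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("monotonicity constraints and linkage are enforced", {
  expect_error(eeg_gen_params(theta_gain = c(PW = 5, LL = 3, ML = 5, HL = 6)),
               "nondecreasing")
  expect_error(eeg_gen_params(alpha_gain = c(PW = 1, LL = 2, ML = 3, HL = 4)),
               "nonincreasing")
  cfg <- tiny_config()
  other <- tiny_config(session_id = "S99_R1")
  ev <- schedule_events(cfg, rng_seed = 1)
  rs <- simulate_behavior(ev, cfg, rng_seed = 2)
  expect_error(synthesize_eeg(other, ev, rs, rng_seed = 3),
               "do not belong")
})
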