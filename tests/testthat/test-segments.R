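test_that("window counts follow the floor formula, incl. the canonical totals", {
  expect_length(make_windows(3060, tl_window_spec()), 611)
  expect_length(make_windows(3060, subtask_window_spec()), 610)
  expect_length(make_windows(10, window_spec(10, 5)), 1)
  expect_error(make_windows(8, window_spec(10, 5)), "shorter")
  # formula equals exhaustive enumeration over random geometries
  set.seed(42)
  for (i in 1:200) {
    dur <- runif(1, 20, 500)
    len <- runif(1, 1, 19)
    ov <- runif(1, 0.1, len - 0.1)
    spec <- window_spec(len, ov)
    starts <- make_windows(dur, spec)
    brute <- 0; s <- 0
    while (s + len <= dur + 1e-9) { brute <- brute + 1; s <- s + spec$hop }
    expect_equal(length(starts), brute)
    expect_true(all(starts + len <= dur + 1e-9))
    expect_equal(diff(starts), rep(spec$hop, length(starts) - 1))
  }
})

test_that("task-load labels follow the midpoint rule", {
  cfg <- tiny_config(types = c("PW", "LL", "ML", "HL"),
                     durations = c(60, 150, 150, 150))
  spec <- tl_window_spec()
  expect_equal(label_tl(100, spec, cfg), "LL")
  # window [205, 215]: midpoint 210 -> ML block [210, 360) starts there;
  # boundary midpoints belong to the earlier block
  expect_equal(label_tl(205, spec, cfg), "LL")
  expect_equal(label_tl(206, spec, cfg), "ML")
  # fully inside a block
  expect_equal(label_tl(400, spec, cfg), "HL")
  # labeling never drops windows
  starts <- make_windows(session_duration(cfg), spec)
  labs <- label_tl(starts, spec, cfg)
  expect_length(labs, length(starts))
  expect_false(anyNA(labs))
})

test_that("class proportions over a study track the session time budget", {
  study <- generate_study(4, make_eeg = FALSE, rng_seed = 1)
  idx <- do.call(rbind, lapply(study$configs, function(cfg) {
    segment_index(cfg, tl_window_spec())
  }))
  p <- prop.table(table(idx$tl_label))
  expect_true(abs(p["PW"] - 360 / 3060) < 0.02)
  for (ty in c("LL", "ML", "HL")) {
    expect_true(abs(p[ty] - 900 / 3060) < 0.02)
  }
})

test_that("subtask bits honor activity and the 2 s engagement threshold", {
  spec <- subtask_window_spec()
  logs <- toy_logs(
    data.frame(event_id = 1:3, subtask = c("SYSM", "COMM", "RMAN"),
               onset = c(5, 20, 40), nominal_duration = c(10, 12, 15),
               requires_response = TRUE),
    data.frame(event_id = 1:3, subtask = c("SYSM", "COMM", "RMAN"),
               onset = c(5, 20, 40), responded = c(FALSE, TRUE, TRUE),
               engage_start = c(NA, 21, 41), engage_end = c(NA, 24, 44),
               error = c(TRUE, FALSE, FALSE)))
  # SYSM event present but overlooked -> 0
  bits <- label_subtasks(0, spec, logs$events, logs$responses)
  expect_equal(unname(bits["SYSM"]), 0L)
  # window [0, 15] does not reach the COMM engagement [21, 24]
  expect_equal(unname(bits["COMM"]), 0L)
  # window [10, 25] overlaps it by 3 s -> 1
  expect_equal(unname(label_subtasks(10, spec, logs$events, logs$responses)["COMM"]), 1L)
  # boundary: overlap exactly 2.0 s -> 1; 1.5 s -> 0
  b1 <- label_subtasks(22, spec, logs$events, logs$responses)  # [22,37] vs [21,24]: 2 s
  expect_equal(unname(b1["COMM"]), 1L)
  b2 <- label_subtasks(22.5, spec, logs$events, logs$responses)  # 1.5 s
  expect_equal(unname(b2["COMM"]), 0L)
  # responded SYSM onset inside window -> 1
  logs2 <- logs
  logs2$responses$responded[1] <- TRUE
  logs2$responses$engage_start[1] <- 6; logs2$responses$engage_end[1] <- 6.5
  expect_equal(unname(label_subtasks(0, spec, logs2$events, logs2$responses)["SYSM"]), 1L)
})

test_that("labels equal a brute-force interval oracle on randomized logs", {
  # oracle: overlap by 1 ms discretization; SYSM by exhaustive onset scan
  set.seed(7)
  spec <- subtask_window_spec()
  for (case in 1:100) {
    n_ev <- sample(1:6, 1)
    onset <- runif(n_ev, 0, 80)
    task <- sample(c("SYSM", "COMM", "RMAN"), n_ev, replace = TRUE)
    responded <- runif(n_ev) < 0.8
    e_start <- onset + runif(n_ev, 0.2, 1)
    e_end <- e_start + runif(n_ev, 0.3, 6)
    logs <- toy_logs(
      data.frame(event_id = seq_len(n_ev), subtask = task, onset = onset,
                 nominal_duration = 15, requires_response = TRUE),
      data.frame(event_id = seq_len(n_ev), subtask = task, onset = onset,
                 responded = responded,
                 engage_start = ifelse(responded, e_start, NA),
                 engage_end = ifelse(responded, e_end, NA),
                 error = !responded))
    w0 <- runif(1, 0, 70)
    bits <- label_subtasks(w0, spec, logs$events, logs$responses)
    grid <- seq(w0, w0 + spec$length, by = 0.001)
    for (tk in c("COMM", "RMAN")) {
      sel <- task == tk & responded
      cover <- rep(FALSE, length(grid))
      for (i in which(sel)) {
        cover <- cover | (grid >= e_start[i] & grid < e_end[i])
      }
      oracle <- as.integer(sum(cover) * 0.001 >= 2 - 0.002)
      expect_equal(unname(bits[tk]), oracle,
                   info = sprintf("case %d task %s", case, tk))
    }
    oracle_sysm <- as.integer(any(task == "SYSM" & responded &
                                    onset >= w0 & onset < w0 + spec$length))
    expect_equal(unname(bits["SYSM"]), oracle_sysm)
  }
})

test_that("labeling is invariant to log row order", {
  cfg <- generate_mini_session_config(1)
  ev <- schedule_events(cfg, rng_seed = 1)
  rs <- simulate_behavior(ev, cfg, rng_seed = 2)
  idx1 <- segment_index(cfg, subtask_window_spec(), ev, rs)
  perm <- sample(nrow(rs))
  rs2 <- rs[perm, ]
  attr(rs2, "session_id") <- attr(rs, "session_id")
  idx2 <- segment_index(cfg, subtask_window_spec(), ev, rs2)
  expect_equal(idx1$SYSM, idx2$SYSM)
  expect_equal(idx1$COMM, idx2$COMM)
  expect_equal(idx1$RMAN, idx2$RMAN)
})

test_that("session splits are exclusive, sized, and seed-dependent", {
  study <- generate_study(50, make_eeg = FALSE, rng_seed = 1)
  sp <- split_sessions(study$manifest, rng_seed = 0)
  expect_length(sp$test, 5)  # 5% of 100 sessions
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), study$manifest$session_id)
  sp2 <- split_sessions(study$manifest, rng_seed = 1)
  expect_length(sp2$test, 5)
  expect_false(setequal(sp$test, sp2$test))
  expect_error(split_sessions(study$manifest[1, ]), "at least 2")
})

test_that("cv folds partition sessions with 5% test shares", {
  study <- generate_study(50, make_eeg = FALSE, rng_seed = 2)
  folds <- make_cv_folds(study$manifest, n_folds = 20, rng_seed = 3)
  expect_length(folds, 20)
  test_sets <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(test_sets) == 5))
  all_test <- unlist(test_sets)
  expect_equal(sort(all_test), sort(study$manifest$session_id))
  for (f in folds) expect_length(intersect(f$train, f$test), 0)
  small <- make_cv_folds(study$manifest[1:4, ], n_folds = 2, rng_seed = 1)
  expect_true(all(lengths(lapply(small, `[[`, "test")) == 2))
  expect_error(make_cv_folds(study$manifest[1:4, ], n_folds = 9), "more folds")
})
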