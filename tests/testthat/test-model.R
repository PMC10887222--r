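# Small encoder used throughout: full kernel/stride stack but narrow width,
# so forward passes stay cheap.
small_enc <- function(width = 8, input_channels = 4, dropout_p = 0) {
  encoder_config(conv_channels = width, input_channels = input_channels,
                 dropout_p = dropout_p, n_groups = 4)
}

test_that("encoder output lengths match the per-layer arithmetic", {
  expect_equal(encoder_output_length(1250), 23L)
  expect_equal(encoder_output_length(1875), 42L)
  expect_error(encoder_output_length(8), "exhausted")
})

test_that("encoder length formula agrees with executed network shapes", {
  enc <- small_enc()
  dec <- decoder_config("tl", hidden_units = 4)
  m <- build_model(enc, dec, rng_seed = 1)
  set.seed(11)
  # 537 samples is the shortest input the full stack can digest
  lengths <- sample(537:2000, 50)
  for (L in lengths) {
    X <- array(rnorm(4 * L), c(4, L, 1))
    fw <- matbeeg:::model_forward(m, X, training = TRUE)
    observed <- dim(fw$cache$enc_out)[2]
    expect_equal(observed, as.integer(encoder_output_length(L, enc)),
                 info = sprintf("input length %d", L))
  }
})

test_that("heads satisfy their output contracts", {
  X <- array(rnorm(4 * 1250 * 3), c(4, 1250, 3))
  m_tl <- build_model(small_enc(), decoder_config("tl"), rng_seed = 2)
  p <- matbeeg:::model_forward(m_tl, X)$probs
  expect_equal(dim(p), c(4, 3))
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  m_st <- build_model(small_enc(), decoder_config("subtask"), rng_seed = 2)
  q <- matbeeg:::model_forward(m_st, X)$probs
  expect_equal(dim(q), c(3, 3))
  expect_true(all(q > 0 & q < 1))
})

test_that("initialization is deterministic in the seed", {
  a <- build_model(small_enc(), decoder_config("tl"), rng_seed = 5)
  b <- build_model(small_enc(), decoder_config("tl"), rng_seed = 5)
  c <- build_model(small_enc(), decoder_config("tl"), rng_seed = 6)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$conv1_W, c$params$conv1_W))
})

test_that("learning-rate schedule matches its stated anchors", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(5, cfg), 0.05)
  expect_equal(lr_at_epoch(12, cfg), 0.05)
  expect_equal(lr_at_epoch(35, cfg), 0.005)
  # cosine midpoint between constant phase end and final epoch
  expect_equal(lr_at_epoch(27.5, cfg), 0.0275)
  # warmup is linear
  expect_equal(lr_at_epoch(2.5, cfg), 0.025)
  expect_error(lr_at_epoch(0, cfg), "out of range")
  expect_error(lr_at_epoch(36, cfg), "out of range")
  expect_error(train_config(warmup_epochs = 25), "warmup")
  expect_error(train_config(final_lr = 0.1), "final_lr")
})

test_that("analytic gradients match finite differences", {
  enc <- encoder_config(n_layers = 3, conv_channels = 8,
                        kernel_sizes = c(3, 2, 2), strides = c(2, 1, 1),
                        skip_layers = c(2, 3), input_channels = 3,
                        dropout_p = 0, n_groups = 2)
  set.seed(4)
  for (task in c("tl", "subtask")) {
    dec <- decoder_config(task, hidden_units = 6)
    m <- build_model(enc, dec, rng_seed = 3)
    X <- array(rnorm(3 * 20 * 2), c(3, 20, 2))
    y <- if (task == "tl") c(2L, 4L) else matrix(rbinom(6, 1, 0.5), 3, 2)
    loss_of <- function(mm) {
      fw <- matbeeg:::model_forward(mm, X, training = TRUE)
      if (task == "tl") matbeeg:::softmax_ce(fw$logits, y)$loss
      else matbeeg:::sigmoid_bce(fw$logits, y)$loss
    }
    fw <- matbeeg:::model_forward(m, X, training = TRUE)
    ls <- if (task == "tl") matbeeg:::softmax_ce(fw$logits, y)
          else matbeeg:::sigmoid_bce(fw$logits, y)
    gr <- matbeeg:::model_backward(m, ls$dlogits, fw)
    for (pn in names(m$params)) {
      for (j in sample(seq_along(m$params[[pn]]), 3)) {
        eps <- 1e-5
        m1 <- m; m1$params[[pn]][j] <- m$params[[pn]][j] + eps
        m2 <- m; m2$params[[pn]][j] <- m$params[[pn]][j] - eps
        num <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
        expect_equal(gr[[pn]][j], num, tolerance = 1e-4,
                     info = paste(task, pn))
      }
    }
  }
})

test_that("skip connections contribute to the forward output", {
  m <- build_model(small_enc(), decoder_config("tl"), rng_seed = 7)
  X <- array(rnorm(4 * 600), c(4, 600, 1))
  full <- matbeeg:::model_forward(m, X)$logits
  m0 <- m
  m0$skip_scale <- 0
  cut <- matbeeg:::model_forward(m0, X)$logits
  expect_gt(max(abs(full - cut)), 1e-6)
})

test_that("prediction is batch-composition invariant with a 0.5 tie rule", {
  m <- build_model(small_enc(), decoder_config("subtask"), rng_seed = 8)
  set.seed(9)
  X <- array(rnorm(4 * 1250 * 7), c(4, 1250, 7))
  a <- predict_model(m, X, batch_size = 7)
  b <- predict_model(m, X, batch_size = 2)
  expect_equal(a$scores, b$scores, tolerance = 1e-12)
  # duplicated segment in one batch gets identical scores
  Xd <- X[, , c(1, 1, 2), drop = FALSE]
  d <- predict_model(m, Xd)
  expect_equal(d$scores[1, ], d$scores[2, ])
  # threshold boundary: score exactly at threshold labels 1
  fake <- matrix(c(0.5, 0.2, 0.9), 1, 3)
  expect_equal(((fake >= 0.5) * 1L)[1, ], c(1L, 0L, 1L))
  # channel mismatch guard
  expect_error(predict_model(m, X[1:3, , , drop = FALSE]), "channel count")
})

test_that("training respects the split and improves the loss", {
  set.seed(10)
  n <- 40
  X <- array(rnorm(4 * 600 * n), c(4, 600, n))
  y <- rep(c("PW", "LL", "ML", "HL"), each = 10)
  for (i in 1:n) X[2, , i] <- X[2, , i] + match(y[i], matbeeg:::TL_LEVELS)
  segs <- list(x = X, index = tibble::tibble(
    session_id = rep(c("s1", "s2", "s3", "s4"), times = 10), tl_label = y))
  split <- structure(list(train = c("s1", "s2", "s3"), test = "s4"),
                     class = "split_plan")
  cfg <- train_config(epochs = 4, peak_lr = 2e-3, warmup_epochs = 1,
                      constant_until_epoch = 2, final_lr = 2e-4,
                      batch_size = 10, rng_seed = 1)
  m <- build_model(small_enc(), decoder_config("tl"), rng_seed = 2)
  tr <- train_model(m, segs, split, cfg)
  expect_equal(nrow(tr$history), 4)
  expect_lt(tr$history$loss[4], tr$history$loss[1])
  # leakage guard
  expect_error(train_model(m, segs, split, cfg,
                           train_ids = c("s1", "s4")), "leakage")
  # empty training set
  empty_split <- structure(list(train = "zz", test = "s4"),
                           class = "split_plan")
  expect_error(train_model(m, segs, empty_split, cfg), "empty training set")
  # label/head mismatch
  m_st <- build_model(small_enc(), decoder_config("subtask"), rng_seed = 2)
  expect_error(train_model(m_st, segs, split, cfg), "subtask bit")
})

test_that("training is deterministic at a fixed seed", {
  set.seed(3)
  n <- 12
  X <- array(rnorm(4 * 600 * n), c(4, 600, n))
  segs <- list(x = X, index = tibble::tibble(
    session_id = rep(c("s1", "s2"), 6),
    tl_label = rep(c("PW", "LL", "ML", "HL"), 3)))
  split <- structure(list(train = c("s1", "s2"), test = character(0)),
                     class = "split_plan")
  cfg <- train_config(epochs = 2, peak_lr = 1e-3, warmup_epochs = 0.5,
                      constant_until_epoch = 1, final_lr = 1e-4,
                      batch_size = 4, rng_seed = 9)
  m <- build_model(small_enc(width = 8, dropout_p = 0.1),
                   decoder_config("tl"), rng_seed = 1)
  t1 <- train_model(m, segs, split, cfg)
  t2 <- train_model(m, segs, split, cfg)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$history$loss, t2$history$loss)
})
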