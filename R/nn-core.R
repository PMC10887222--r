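# Neural-network primitives for the 1-D temporal CNN, implemented on BLAS
# matrix products. Batches are arrays of shape (channels, time, batch).
# Convolutions are "valid" (no padding) along time; normalization is group
# normalization (statistics per sample, so outputs are batch-size
# invariant); activations are exact GELU (encoder) and ReLU (decoder).

# ---- conv1d ----------------------------------------------------------------

# im2col: unfold X (C_in, L, B) into M (C_in*k, L_out*B), columns ordered
# time-fastest then batch, matching a (C_out, L_out, B) output layout.
.im2col <- function(X, k, stride, L_out) {
  d <- dim(X); C_in <- d[1]; B <- d[3]
  M <- matrix(0, C_in * k, L_out * B)
  base <- (seq_len(L_out) - 1L) * stride
  for (j in seq_len(k)) {
    M[((j - 1L) * C_in + 1L):(j * C_in), ] <- X[, base + j, , drop = FALSE]
  }
  M
}

conv1d_forward <- function(X, W, b, stride) {
  d <- dim(X); C_in <- d[1]; L <- d[2]; B <- d[3]
  k <- ncol(W) / C_in
  L_out <- floor((L - k) / stride) + 1
  if (L_out < 1) {
    stop(sprintf("sequence of %d frames too short for kernel %d", L, k))
  }
  M <- .im2col(X, k, stride, L_out)
  Y <- W %*% M + b
  dim(Y) <- c(nrow(W), L_out, B)
  list(Y = Y, cache = list(M = M, in_dim = d, k = k, stride = stride,
                           L_out = L_out))
}

conv1d_backward <- function(dY, W, cache, need_dx = TRUE) {
  C_in <- cache$in_dim[1]; B <- cache$in_dim[3]
  k <- cache$k; L_out <- cache$L_out
  dY_mat <- dY; dim(dY_mat) <- c(nrow(W), L_out * B)
  dW <- tcrossprod(dY_mat, cache$M)
  db <- rowSums(dY_mat)
  if (!need_dx) return(list(dX = NULL, dW = dW, db = db))
  dM <- crossprod(W, dY_mat)
  dX <- array(0, cache$in_dim)
  base <- (seq_len(L_out) - 1L) * cache$stride
  for (j in seq_len(k)) {
    blk <- dM[((j - 1L) * C_in + 1L):(j * C_in), , drop = FALSE]
    dim(blk) <- c(C_in, L_out, B)
    dX[, base + j, ] <- dX[, base + j, , drop = FALSE] + blk
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- group normalization ---------------------------------------------------

# Permute (C, L, B) -> matrix (Cg*L, G*B) whose columns are the
# normalization cells, and back. With a single group the fold is a free
# reshape (no permutation).
.gn_fold <- function(X, G) {
  d <- dim(X)
  if (G == 1) {
    dim(X) <- c(d[1] * d[2], d[3])
    return(X)
  }
  Cg <- d[1] / G
  dim(X) <- c(Cg, G, d[2], d[3])
  Xp <- aperm(X, c(1, 3, 2, 4))
  dim(Xp) <- c(Cg * d[2], G * d[3])
  Xp
}

.gn_unfold <- function(Xp, C, L, B, G) {
  if (G == 1) {
    dim(Xp) <- c(C, L, B)
    return(Xp)
  }
  Cg <- C / G
  dim(Xp) <- c(Cg, L, G, B)
  X <- aperm(Xp, c(1, 3, 2, 4))
  dim(X) <- c(C, L, B)
  X
}

groupnorm_forward <- function(X, gamma, beta, G, eps = 1e-5) {
  d <- dim(X)
  Xp <- .gn_fold(X, G)
  mu <- colMeans(Xp)
  xc <- Xp - rep(mu, each = nrow(Xp))
  istd <- 1 / sqrt(colMeans(xc^2) + eps)
  xhat_p <- xc * rep(istd, each = nrow(Xp))
  xhat <- .gn_unfold(xhat_p, d[1], d[2], d[3], G)
  Y <- xhat * gamma + beta   # gamma/beta length C recycle along channels
  list(Y = Y, cache = list(xhat = xhat, istd = istd, G = G, dims = d))
}

groupnorm_backward <- function(dY, gamma, cache) {
  d <- cache$dims; G <- cache$G
  dgamma <- rowSums(dY * cache$xhat, dims = 1)
  dbeta <- rowSums(dY, dims = 1)
  dXh <- dY * gamma
  dXh_p <- .gn_fold(dXh, G)
  xhat_p <- .gn_fold(cache$xhat, G)
  m <- nrow(dXh_p)
  m1 <- colMeans(dXh_p)
  m2 <- colMeans(dXh_p * xhat_p)
  dX_p <- (dXh_p - rep(m1, each = m) - xhat_p * rep(m2, each = m)) *
    rep(cache$istd, each = m)
  list(dX = .gn_unfold(dX_p, d[1], d[2], d[3], G), dgamma = dgamma,
       dbeta = dbeta)
}

# ---- activations / dropout -------------------------------------------------

# GELU, sigmoid approximation (x * sigmoid(1.702 x)); the gate is cached so
# the backward pass is purely elementwise arithmetic.
gelu_forward <- function(X) {
  s <- 1 / (1 + exp(-1.702 * X))
  list(Y = X * s, gate = s)
}

gelu_backward <- function(dY, X, gate) {
  dY * gate * (1 + 1.702 * X * (1 - gate))
}

relu_forward <- function(X) pmax(X, 0)

relu_backward <- function(dY, X) dY * (X > 0)

dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- array((runif(length(X)) >= p) / (1 - p), dim(X))
  list(Y = X * mask, mask = mask)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# ---- losses ----------------------------------------------------------------

# logits: (n_class, B); y: integer class index 1..n_class.
softmax_ce <- function(logits, y) {
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  p <- sweep(ex, 2, colSums(ex), "/")
  B <- ncol(logits)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-12)))
  dlogits <- p
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B, probs = p)
}

# logits: (n_label, B); y: 0/1 matrix of the same shape. Mean over batch,
# sum over labels.
sigmoid_bce <- function(logits, y) {
  p <- 1 / (1 + exp(-logits))
  B <- ncol(logits)
  eps <- 1e-12
  loss <- -sum(y * log(p + eps) + (1 - y) * log(1 - p + eps)) / B
  list(loss = loss, dlogits = (p - y) / B, probs = p)
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decoupled weight decay, applied only to parameters flagged in `decay`.
adamw_step <- function(params, grads, state, lr, weight_decay, decay_flags,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    upd <- (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    if (decay_flags[i]) upd <- upd + weight_decay * params[[i]]
    params[[i]] <- params[[i]] - lr * upd
  }
  list(params = params, state = state)
}
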