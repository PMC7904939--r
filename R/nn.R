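# Internal CNN primitives. Tensors are arrays (height, width, channels, batch);
# convolutions are "valid" (no padding) and implemented as im2col followed by
# one BLAS matrix multiply. All gradients are exact (verified against central
# finite differences in the test suite).

# Unroll kh x kw patches of X into a (oh*ow*N) x (kh*kw*C) matrix.
# Column q corresponds to kernel offset (di, dj) and input channel c in
# column-major kernel order; rows run over (i, j, n).
im2col <- function(X, kh, kw) {
  d <- dim(X)
  oh <- d[1L] - kh + 1L
  ow <- d[2L] - kw + 1L
  cols <- matrix(0, oh * ow * d[4L], kh * kw * d[3L])
  q <- 0L
  for (ch in seq_len(d[3L])) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        q <- q + 1L
        cols[, q] <- X[di:(di + oh - 1L), dj:(dj + ow - 1L), ch, ,
                       drop = FALSE]
      }
    }
  }
  list(cols = cols, oh = oh, ow = ow, xdim = d, kh = kh, kw = kw)
}

conv_forward <- function(X, W, b) {
  kh <- attr(W, "kh"); kw <- attr(W, "kw")
  ic <- im2col(X, kh, kw)
  nf <- ncol(W)
  out_mat <- ic$cols %*% W
  out_mat <- out_mat + rep(b, each = nrow(out_mat))
  n <- ic$xdim[4L]
  out <- aperm(array(out_mat, c(ic$oh, ic$ow, n, nf)), c(1L, 2L, 4L, 3L))
  list(out = out, cache = ic)
}

conv_backward <- function(dout, cache, W) {
  d <- dim(dout)  # (oh, ow, F, N)
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(W)
  dX <- array(0, cache$xdim)
  oh <- cache$oh; ow <- cache$ow
  q <- 0L
  for (ch in seq_len(cache$xdim[3L])) {
    for (dj in seq_len(cache$kw)) {
      for (di in seq_len(cache$kh)) {
        q <- q + 1L
        ri <- di:(di + oh - 1L)
        cj <- dj:(dj + ow - 1L)
        upd <- dX[ri, cj, ch, , drop = FALSE] +
          array(dcols[, q], c(oh, ow, 1L, cache$xdim[4L]))
        dX[ri, cj, ch, ] <- upd
      }
    }
  }
  list(dX = dX, dW = dW, db = db)
}

pool_out_len <- function(n, ps, stride) (n - ps) %/% stride + 1L

# Overlapping max pooling (window ps x ps, given stride, per channel).
pool_forward <- function(X, ps, stride) {
  d <- dim(X)
  oh <- pool_out_len(d[1L], ps, stride)
  ow <- pool_out_len(d[2L], ps, stride)
  ri <- (seq_len(oh) - 1L) * stride + 1L
  ci <- (seq_len(ow) - 1L) * stride + 1L
  out <- array(-Inf, c(oh, ow, d[3L], d[4L]))
  for (dj in seq_len(ps)) {
    for (di in seq_len(ps)) {
      out <- pmax(out, X[ri + di - 1L, ci + dj - 1L, , , drop = FALSE])
    }
  }
  out
}

# Gradient routed to the first window position attaining the max (ties broken
# deterministically in kernel scan order).
pool_backward <- function(dout, X, out, ps, stride) {
  d <- dim(X)
  oh <- dim(out)[1L]; ow <- dim(out)[2L]
  ri <- (seq_len(oh) - 1L) * stride + 1L
  ci <- (seq_len(ow) - 1L) * stride + 1L
  dX <- array(0, d)
  taken <- array(FALSE, dim(out))
  for (dj in seq_len(ps)) {
    for (di in seq_len(ps)) {
      slice <- X[ri + di - 1L, ci + dj - 1L, , , drop = FALSE]
      sel <- (slice == out) & !taken
      taken <- taken | sel
      upd <- dX[ri + di - 1L, ci + dj - 1L, , , drop = FALSE] + dout * sel
      dX[ri + di - 1L, ci + dj - 1L, , ] <- upd
    }
  }
  dX
}

flatten4 <- function(X) {
  d <- dim(X)
  t(matrix(X, prod(d[1:3]), d[4L]))
}

unflatten4 <- function(M, d) {
  array(t(M), d)
}

relu <- function(x) pmax(x, 0)

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# Initialize all weights for the two-conv / two-dense architecture.
init_params <- function(shapes, cfg) {
  k1 <- cfg$conv_kernels[[1L]]; k2 <- cfg$conv_kernels[[2L]]
  f1 <- cfg$conv_filters[[1L]]; f2 <- cfg$conv_filters[[2L]]
  flat <- shapes$flatten_length
  W1 <- matrix(glorot_uniform(prod(k1), prod(k1) * f1, prod(k1) * f1),
               prod(k1), f1)
  attr(W1, "kh") <- k1[[1L]]; attr(W1, "kw") <- k1[[2L]]
  W2 <- matrix(glorot_uniform(prod(k2) * f1, prod(k2) * f2,
                              prod(k2) * f1 * f2), prod(k2) * f1, f2)
  attr(W2, "kh") <- k2[[1L]]; attr(W2, "kw") <- k2[[2L]]
  W3 <- matrix(glorot_uniform(flat, cfg$fc_width, flat * cfg$fc_width),
               flat, cfg$fc_width)
  W4 <- matrix(glorot_uniform(cfg$fc_width, 1L, cfg$fc_width), cfg$fc_width, 1L)
  list(W1 = W1, b1 = numeric(f1), W2 = W2, b2 = numeric(f2),
       W3 = W3, b3 = numeric(cfg$fc_width), W4 = W4, b4 = numeric(1L))
}

# Forward pass; training = TRUE activates (inverted) dropout, which draws from
# the current RNG stream.
nn_forward <- function(params, X, cfg, training = FALSE) {
  ps <- cfg$pool_size; st <- cfg$pool_stride
  c1 <- conv_forward(X, params$W1, params$b1)
  p1 <- pool_forward(c1$out, ps, st)
  c2 <- conv_forward(p1, params$W2, params$b2)
  p2 <- pool_forward(c2$out, ps, st)
  flat <- flatten4(p2)
  rate <- cfg$dropout_rate
  if (training && rate > 0) {
    mask <- matrix(runif(length(flat)) >= rate, nrow(flat), ncol(flat))
    flat_d <- flat * mask / (1 - rate)
  } else {
    mask <- NULL
    flat_d <- flat
  }
  z3 <- flat_d %*% params$W3 + rep(params$b3, each = nrow(flat_d))
  h <- relu(z3)
  yhat <- drop(h %*% params$W4) + params$b4
  list(yhat = yhat,
       cache = list(c1 = c1, p1 = p1, c2 = c2, p2 = p2, flat = flat,
                    flat_d = flat_d, mask = mask, z3 = z3, h = h, X = X))
}

# Backward pass for mean-squared-error loss; dy is dL/dyhat (length N).
nn_backward <- function(params, cache, dy, cfg) {
  ps <- cfg$pool_size; st <- cfg$pool_stride
  dy <- matrix(dy, ncol = 1L)
  dW4 <- crossprod(cache$h, dy)
  db4 <- sum(dy)
  dh <- dy %*% t(params$W4)
  dz3 <- dh * (cache$z3 > 0)
  dW3 <- crossprod(cache$flat_d, dz3)
  db3 <- colSums(dz3)
  dflat_d <- dz3 %*% t(params$W3)
  dflat <- if (is.null(cache$mask)) dflat_d else
    dflat_d * cache$mask / (1 - cfg$dropout_rate)
  dp2 <- unflatten4(dflat, dim(cache$p2))
  dc2 <- pool_backward(dp2, cache$c2$out, cache$p2, ps, st)
  cb2 <- conv_backward(dc2, cache$c2$cache, params$W2)
  dp1 <- cb2$dX
  dc1 <- pool_backward(dp1, cache$c1$out, cache$p1, ps, st)
  cb1 <- conv_backward(dc1, cache$c1$cache, params$W1)
  list(W1 = cb1$dW, b1 = cb1$db, W2 = cb2$dW, b2 = cb2$db,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) numeric(length(p))),
       v = lapply(params, function(p) numeric(length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- as.numeric(grads[[k]])
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    upd <- lr * mhat / (sqrt(vhat) + eps)
    attrs <- attributes(params[[k]])
    p <- as.numeric(params[[k]]) - upd
    attributes(p) <- attrs
    params[[k]] <- p
  }
  list(params = params, state = state)
}
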