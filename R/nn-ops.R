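## Minimal dense-tensor neural-network primitives.
##
## No deep-learning framework is used anywhere in this package: the layers
## below carry hand-derived backward passes (verified against central finite
## differences in the test suite). Feature maps are numeric arrays in
## [H, W, C] layout; batches carry a trailing sample axis [H, W, C, N].
## Convolutions are stride-1 "same"/valid via im2col + BLAS matrix products.

.vr_cache <- new.env(parent = emptyenv())

## Gather/scatter plan for k x k stride-1 convolution with zero padding.
im2col_plan <- function(H, W, C, k, pad) {
  key <- paste("i2c", H, W, C, k, pad, sep = "_")
  pl <- .vr_cache[[key]]
  if (!is.null(pl)) return(pl)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- Hp - k + 1L
  Wo <- Wp - k + 1L
  vr_assert(Ho >= 1 && Wo >= 1, "kernel larger than (padded) input")
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  dy <- rep(seq_len(k) - 1L, times = k * C)
  dx <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  cc <- rep(seq_len(C) - 1L, each = k * k)
  M <- outer(dy, io, `+`) + Hp * outer(dx, jo - 1L, `+`) + cc * (Hp * Wp)
  storage.mode(M) <- "integer"
  S <- Matrix::sparseMatrix(i = as.vector(M), j = seq_along(M), x = 1,
                            dims = c(Hp * Wp * C, length(M)))
  pl <- list(M = M, S = S, H = H, W = W, C = C, k = k, pad = pad,
             Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  .vr_cache[[key]] <- pl
  pl
}

pad_zero <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

## x: [H,W,C,N]; Wm: [k*k*C, F]; b: [F]. Returns out [Ho,Wo,F,N].
## Compiled kernels do the gather + BLAS product; the backward pass
## re-gathers instead of caching the column matrices, keeping memory flat.
conv2d_fw <- function(x, Wm, b, k, pad = 1L) {
  d <- dim(x)
  vr_assert(nrow(Wm) == k * k * d[3], "conv weight/input channel mismatch")
  out <- cpp_conv_fw(x, as.integer(d), Wm, as.numeric(b), as.integer(k),
                     as.integer(pad))
  list(out = out,
       cache = list(x = x, Wm = Wm, k = as.integer(k),
                    pad = as.integer(pad), din = d))
}

conv2d_bw <- function(dout, cache, need_dx = TRUE) {
  r <- cpp_conv_bw(cache$x, as.integer(cache$din), cache$Wm, dout,
                   cache$k, cache$pad, need_dx)
  list(dx = if (need_dx) r$dx else NULL, dW = r$dW, db = r$db)
}

relu_fw <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bw <- function(dout, mask) dout * mask

sigmoid_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = s, s = s)
}
sigmoid_bw <- function(dout, s) dout * s * (1 - s)

## x2 average pooling over both spatial dims (H, W even).
pool2_avg_fw <- function(x) {
  d <- dim(x)
  vr_assert(d[1] %% 2 == 0 && d[2] %% 2 == 0, "pool2 needs even spatial dims")
  cpp_pool2_fw(x, as.integer(d))
}

pool2_avg_bw <- function(dout) {
  cpp_pool2_bw(dout, as.integer(dim(dout)))
}

## x2 nearest-neighbour upsampling.
upsample2_fw <- function(x) {
  d <- dim(x)
  ii <- rep(seq_len(d[1]), each = 2L)
  jj <- rep(seq_len(d[2]), each = 2L)
  x[ii, jj, , , drop = FALSE]
}

upsample2_bw <- function(dout) {
  d <- dim(dout)
  o1 <- seq(1L, d[1], 2L)
  o2 <- seq(1L, d[2], 2L)
  y <- dout[o1, , , , drop = FALSE] + dout[o1 + 1L, , , , drop = FALSE]
  y[, o2, , , drop = FALSE] + y[, o2 + 1L, , , drop = FALSE]
}

## Resize a square map to a target side by repeated x2 average pooling or
## nearest upsampling (sides must be related by a power of two).
resize_to_fw <- function(x, target) {
  side <- dim(x)[1]
  ops <- character(0)
  while (side > target) {
    x <- pool2_avg_fw(x)
    ops <- c(ops, "pool")
    side <- side / 2L
  }
  while (side < target) {
    x <- upsample2_fw(x)
    ops <- c(ops, "up")
    side <- side * 2L
  }
  vr_assert(side == target, "sides not related by a power of two")
  list(out = x, ops = ops)
}

resize_to_bw <- function(dout, ops) {
  for (op in rev(ops)) {
    dout <- if (op == "pool") pool2_avg_bw(dout) else upsample2_bw(dout)
  }
  dout
}

## ---- Batch normalization (per channel over batch + space) ----------------

bn_init <- function(C) list(gamma = rep(1, C), beta = rep(0, C))
bn_buf_init <- function(C) list(mean = rep(0, C), var = rep(1, C))

bn_fw <- function(x, gamma, beta, buf, training, momentum = 0.1,
                  eps = 1e-5) {
  d <- dim(x)
  if (training) {
    st <- cpp_bn_stats(x, as.integer(d))
    mu <- st$mean
    va <- st$var
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * va
  } else {
    mu <- buf$mean
    va <- buf$var
  }
  inv <- 1 / sqrt(va + eps)
  y <- cpp_bn_apply(x, as.integer(d), gamma, beta, mu, inv)
  list(out = y, buf = buf,
       cache = list(x = x, mu = mu, inv = inv, gamma = gamma, d = d,
                    training = training))
}

bn_bw <- function(dout, cache) {
  r <- cpp_bn_bw(cache$x, as.integer(cache$d), dout, cache$gamma,
                 cache$mu, cache$inv, cache$training)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

## ---- Group normalization (per sample, per channel group) -----------------

gn_fw <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  vr_assert(C %% groups == 0, "channels not divisible by groups")
  m <- d[1] * d[2] * (C / groups)
  xm <- matrix(x, nrow = m)                 # columns: group within sample
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu * mu
  inv <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = m)) * rep(inv, each = m)
  xh4 <- array(xhat, d)
  gv <- rep(gamma, each = d[1] * d[2])
  bv <- rep(beta, each = d[1] * d[2])
  y <- array(as.vector(xh4) * gv + bv, d)   # gv recycles over samples
  list(out = y, cache = list(xhat = xhat, inv = inv, d = d, m = m,
                             gv = gv, gamma = gamma))
}

gn_bw <- function(dout, cache) {
  d <- cache$d
  xh4 <- array(cache$xhat, d)
  prod4 <- dout * xh4
  perm <- aperm(prod4, c(1, 2, 4, 3))
  dgamma <- colSums(matrix(perm, ncol = d[3]))
  dbeta <- colSums(matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3]))
  dxhat <- matrix(as.vector(dout) * cache$gv, nrow = cache$m)
  m <- cache$m
  t1 <- dxhat - rep(colMeans(dxhat), each = m)
  t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = m)
  dx <- array((t1 - t2) * rep(cache$inv, each = m), d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- Parameter initialization and Adam -----------------------------------

glorot_normal <- function(dims, fan_in, fan_out) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / (fan_in + fan_out))), dims)
}

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (k in names(grads)) {
    g <- grads[[k]]
    if (is.null(g)) next
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (st$m[[k]] / c1) / (sqrt(st$v[[k]] / c2) + eps)
  }
  params
}

## Learning rate at a given 1-based epoch under milestone drops: each
## milestone m contributes one multiplicative drop once epoch > m.
schedule_lr <- function(sched, epoch) {
  sched$lr * sched$drop_factor^sum(sched$milestones < epoch)
}

## ---- Anisotropic total variation (value + gradient) ----------------------

## Mean absolute first difference over all horizontal + vertical neighbour
## pairs; a binary checkerboard scores exactly 1.
tv_value_grad <- function(x, want_grad = TRUE) {
  d <- dim(x)
  H <- d[1]
  W <- d[2]
  dh <- if (W > 1) {
    x[, 2:W, , drop = FALSE] - x[, 1:(W - 1), , drop = FALSE]
  } else {
    array(0, c(H, 0, d[3]))
  }
  dv <- if (H > 1) {
    x[2:H, , , drop = FALSE] - x[1:(H - 1), , , drop = FALSE]
  } else {
    array(0, c(0, W, d[3]))
  }
  nd <- length(dh) + length(dv)
  if (nd == 0) {
    return(list(value = 0, grad = if (want_grad) array(0, d) else NULL))
  }
  val <- (sum(abs(dh)) + sum(abs(dv))) / nd
  g <- NULL
  if (want_grad) {
    g <- array(0, d)
    if (length(dh)) {
      sh <- sign(dh) / nd
      g[, 2:W, ] <- g[, 2:W, , drop = FALSE] + sh
      g[, 1:(W - 1), ] <- g[, 1:(W - 1), , drop = FALSE] - sh
    }
    if (length(dv)) {
      sv <- sign(dv) / nd
      g[2:H, , ] <- g[2:H, , , drop = FALSE] + sv
      g[1:(H - 1), , ] <- g[1:(H - 1), , , drop = FALSE] - sv
    }
  }
  list(value = val, grad = g)
}

## helpers to move between single images [H,W,C] and batch [H,W,C,1]
as_batch <- function(img) {
  if (length(dim(img)) == 3L) array(img, c(dim(img), 1L)) else img
}
from_batch <- function(x) array(x, dim(x)[1:3])
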