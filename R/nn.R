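# Minimal dense-tensor neural-network primitives used by the artifact
# reduction network. Feature maps are 4D arrays [H, W, C, N] (batch last);
# convolutions are evaluated as im2col + BLAS matrix products. Each layer
# exposes a forward pass returning (output, cache) and a backward pass
# returning (dinput, parameter gradients).

# ---- 3x3 convolution, stride 1, zero padding 1 ----

# im2col for one sample: x [H, W, C] -> matrix (H*W) x (9*C), columns ordered
# (ky, kx, c) with ky fastest, matching matrix(W[3,3,C,K], 9*C, K).
im2col3 <- function(x) {
  d <- dim(x)
  .im2col3_cpp(as.numeric(x), d[1L], d[2L], d[3L])
}

col2im3 <- function(dcols, h, w, cch) {
  .col2im3_cpp(dcols, h, w, cch)
}

conv3_forward <- function(x, w, b) {
  d <- dim(x)
  h <- d[1L]; wd <- d[2L]; n <- d[4L]
  k <- dim(w)[4L]
  wm <- matrix(w, ncol = k)
  y <- array(0, c(h, wd, k, n))
  cols <- vector("list", n)
  for (i in seq_len(n)) {
    m <- im2col3(array(x[, , , i], d[1:3]))
    cols[[i]] <- m
    y[, , , i] <- array(m %*% wm + rep(b, each = h * wd), c(h, wd, k))
  }
  list(y = y, cache = list(cols = cols, dims = d, k = k))
}

conv3_backward <- function(dy, w, cache) {
  d <- cache$dims
  h <- d[1L]; wd <- d[2L]; cch <- d[3L]; n <- d[4L]
  k <- cache$k
  wm <- matrix(w, ncol = k)
  dwm <- matrix(0, nrow(wm), k)
  db <- numeric(k)
  dx <- array(0, d)
  for (i in seq_len(n)) {
    dyi <- matrix(dy[, , , i], h * wd, k)
    dwm <- dwm + crossprod(cache$cols[[i]], dyi)
    db <- db + colSums(dyi)
    dx[, , , i] <- col2im3(dyi %*% t(wm), h, wd, cch)
  }
  list(dx = dx, dW = array(dwm, dim(w)), db = db)
}

# ---- 1x1 convolution ----

conv1_forward <- function(x, w, b) {
  d <- dim(x)
  k <- ncol(w)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3L])
  ym <- xm %*% w + rep(b, each = nrow(xm))
  y <- aperm(array(ym, c(d[1L], d[2L], d[4L], k)), c(1, 2, 4, 3))
  list(y = y, cache = list(xm = xm, dims = d, k = k))
}

conv1_backward <- function(dy, w, cache) {
  d <- cache$dims
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = cache$k)
  dxm <- dym %*% t(w)
  dx <- aperm(array(dxm, c(d[1L], d[2L], d[4L], d[3L])), c(1, 2, 4, 3))
  list(dx = dx, dW = crossprod(cache$xm, dym), db = colSums(dym))
}

# ---- ReLU ----

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

# ---- batch normalization (per channel over H, W, N) ----

# Per-channel reductions and broadcasts over [H, W, C, N] use the recycling
# of a length H*W*C vector across the batch dimension (no aperm copies).
channel_mean <- function(x, d) {
  # mean over (H, W, N) per channel
  hw <- d[1L] * d[2L]
  cm <- .colMeans(x, hw, d[3L] * d[4L])       # (C*N) channel-slice means
  .rowMeans(matrix(cm, d[3L], d[4L]), d[3L], d[4L])
}

channel_expand <- function(v, d) rep(v, each = d[1L] * d[2L])

bn_forward <- function(x, gamma, beta, rm, rv, use_batch_stats,
                       update_running = FALSE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  if (use_batch_stats) {
    mu <- channel_mean(x, d)
    xc <- x - channel_expand(mu, d)
    va <- channel_mean(xc^2, d)
    rm_new <- if (update_running) (1 - momentum) * rm + momentum * mu else rm
    rv_new <- if (update_running) (1 - momentum) * rv + momentum * va else rv
  } else {
    mu <- rm; va <- rv
    xc <- x - channel_expand(mu, d)
    rm_new <- rm; rv_new <- rv
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- xc * channel_expand(invstd, d)
  y <- xhat * channel_expand(gamma, d) + channel_expand(beta, d)
  dim(y) <- d
  list(y = y, rm = rm_new, rv = rv_new,
       cache = list(xhat = xhat, invstd = invstd, dims = d))
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dims
  hw <- d[1L] * d[2L]
  xhat <- cache$xhat
  sum_per_channel <- function(z) {
    cs <- .colSums(z, hw, d[3L] * d[4L])
    .rowSums(matrix(cs, d[3L], d[4L]), d[3L], d[4L])
  }
  dgamma <- sum_per_channel(dy * xhat)
  dbeta <- sum_per_channel(dy)
  dxhat <- dy * channel_expand(gamma, d)
  dx <- (dxhat - channel_expand(channel_mean(dxhat, d), d) -
           xhat * channel_expand(channel_mean(dxhat * xhat, d), d)) *
    channel_expand(cache$invstd, d)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- 2x2 max pooling, stride 2 ----

pool_forward <- function(x) {
  d <- dim(x)
  io <- seq.int(1L, d[1L], 2L); ie <- io + 1L
  jo <- seq.int(1L, d[2L], 2L); je <- jo + 1L
  s <- list(x[io, jo, , , drop = FALSE], x[ie, jo, , , drop = FALSE],
            x[io, je, , , drop = FALSE], x[ie, je, , , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  m1 <- s[[1]] == y
  m2 <- (s[[2]] == y) & !m1
  m3 <- (s[[3]] == y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(y = y, cache = list(masks = list(m1, m2, m3, m4), dims = d))
}

pool_backward <- function(dy, cache) {
  d <- cache$dims
  io <- seq.int(1L, d[1L], 2L); ie <- io + 1L
  jo <- seq.int(1L, d[2L], 2L); je <- jo + 1L
  m <- cache$masks
  dx <- array(0, d)
  dx[io, jo, , ] <- dy * m[[1]]
  dx[ie, jo, , ] <- dy * m[[2]]
  dx[io, je, , ] <- dy * m[[3]]
  dx[ie, je, , ] <- dy * m[[4]]
  dx
}

# ---- 2x2 transposed convolution, stride 2 (non-overlapping upsampling) ----

tconv_forward <- function(x, w, b) {
  d <- dim(x)
  h <- d[1L]; wd <- d[2L]; cch <- d[3L]; n <- d[4L]
  k <- dim(w)[4L]
  # columns ordered (dy, dx, k), dy fastest; rows are input channels
  wm <- matrix(aperm(w, c(3, 1, 2, 4)), cch, 4L * k)
  y <- array(0, c(2L * h, 2L * wd, k, n))
  io <- seq.int(1L, 2L * h, 2L); ie <- io + 1L
  jo <- seq.int(1L, 2L * wd, 2L); je <- jo + 1L
  xms <- vector("list", n)
  for (i in seq_len(n)) {
    xm <- matrix(x[, , , i], h * wd, cch)
    xms[[i]] <- xm
    z <- array(xm %*% wm, c(h, wd, 2L, 2L, k))
    y[io, jo, , i] <- z[, , 1, 1, ]
    y[ie, jo, , i] <- z[, , 2, 1, ]
    y[io, je, , i] <- z[, , 1, 2, ]
    y[ie, je, , i] <- z[, , 2, 2, ]
  }
  y <- y + array(rep(b, each = 4L * h * wd), dim(y))
  list(y = y, cache = list(xms = xms, dims = d, k = k))
}

tconv_backward <- function(dy, w, cache) {
  d <- cache$dims
  h <- d[1L]; wd <- d[2L]; cch <- d[3L]; n <- d[4L]
  k <- cache$k
  wm <- matrix(aperm(w, c(3, 1, 2, 4)), cch, 4L * k)
  io <- seq.int(1L, 2L * h, 2L); ie <- io + 1L
  jo <- seq.int(1L, 2L * wd, 2L); je <- jo + 1L
  dwm <- matrix(0, cch, 4L * k)
  db <- numeric(k)
  dx <- array(0, d)
  for (i in seq_len(n)) {
    dz <- array(0, c(h, wd, 2L, 2L, k))
    dz[, , 1, 1, ] <- dy[io, jo, , i]
    dz[, , 2, 1, ] <- dy[ie, jo, , i]
    dz[, , 1, 2, ] <- dy[io, je, , i]
    dz[, , 2, 2, ] <- dy[ie, je, , i]
    dzm <- matrix(dz, h * wd, 4L * k)
    dwm <- dwm + crossprod(cache$xms[[i]], dzm)
    db <- db + colSums(matrix(dy[, , , i], ncol = k))
    dx[, , , i] <- array(dzm %*% t(wm), c(h, wd, cch))
  }
  list(dx = dx, dW = aperm(array(dwm, c(cch, 2L, 2L, k)), c(2, 3, 1, 4)),
       db = db)
}

# ---- channel concatenation (skip connections) ----

concat_forward <- function(skip, x) {
  ds <- dim(skip); dx <- dim(x)
  y <- array(0, c(ds[1L], ds[2L], ds[3L] + dx[3L], ds[4L]))
  y[, , seq_len(ds[3L]), ] <- skip
  y[, , ds[3L] + seq_len(dx[3L]), ] <- x
  list(y = y, c_skip = ds[3L])
}

concat_backward <- function(dy, c_skip) {
  list(dskip = dy[, , seq_len(c_skip), , drop = FALSE],
       dx = dy[, , -seq_len(c_skip), , drop = FALSE])
}

# ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
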