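# Minimal neural-network layer primitives on (batch, channel, height, width)
# arrays: im2col convolution, 2x2 max-pooling, batch normalisation and
# inverted dropout, each with a matching backward pass. Everything is plain
# vectorised R; shapes are small (the largest feature map is 16 x 20 x 10) so
# matrix multiplication dominates and no compiled code is needed.

# Precompute the geometry and gather indices of a convolution layer.
conv_layer <- function(in_ch, in_h, in_w, kh, kw, sh, sw, ph, pw, out_ch) {
  hp <- in_h + 2L * ph
  wp <- in_w + 2L * pw
  if (hp < kh || wp < kw)
    wf_config_error("conv kernel %dx%d larger than padded input %dx%d", kh, kw, hp, wp)
  out_h <- (hp - kh) %/% sh + 1L
  out_w <- (wp - kw) %/% sw + 1L
  # gather index for position p = (oh, ow) and kernel element k = (c, dh, dw),
  # into the padded slab laid out with channel fastest: c + C*(h-1) + C*Hp*(w-1)
  oh <- rep(seq_len(out_h), times = out_w)
  ow <- rep(seq_len(out_w), each = out_h)
  kc <- rep(seq_len(in_ch), times = kh * kw)
  kdh <- rep(rep(seq_len(kh), each = in_ch), times = kw)
  kdw <- rep(seq_len(kw), each = in_ch * kh)
  np <- out_h * out_w
  nk <- in_ch * kh * kw
  h <- outer((oh - 1L) * sh, kdh, `+`)      # np x nk, 1-based row in padded
  w <- outer((ow - 1L) * sw, kdw, `+`)
  idx <- matrix(rep(kc, each = np), np, nk) + in_ch * (h - 1L) + in_ch * hp * (w - 1L)
  list(in_ch = in_ch, in_h = in_h, in_w = in_w, kh = kh, kw = kw,
       sh = sh, sw = sw, ph = ph, pw = pw, out_ch = out_ch,
       out_h = out_h, out_w = out_w, hp = hp, wp = wp,
       np = np, nk = nk, idx = idx,
       # column order: for each position p, all k (k fastest)
       col_idx = as.vector(t(idx)))
}

conv_init <- function(layer, seed = NULL) {
  with_seed(seed, {
    fan_in <- layer$nk
    lim <- sqrt(6 / fan_in)
    list(W = matrix(runif(layer$nk * layer$out_ch, -lim, lim), layer$nk, layer$out_ch),
         b = numeric(layer$out_ch))
  })
}

# x: (B, C, H, W) -> padded channel-fastest matrix (B, C*Hp*Wp)
pad_to_mat <- function(layer, x) {
  b <- dim(x)[1]
  xc <- aperm(x, c(1L, 2L, 3L, 4L))  # already (B,C,H,W)
  if (layer$ph > 0L || layer$pw > 0L) {
    xp <- array(0, c(b, layer$in_ch, layer$hp, layer$wp))
    xp[, , layer$ph + seq_len(layer$in_h), layer$pw + seq_len(layer$in_w)] <- xc
  } else {
    xp <- xc
  }
  # reorder to channel-fastest slabs: (B, C, Hp, Wp) -> (B, C*Hp*Wp) with c fastest
  matrix(aperm(xp, c(1L, 2L, 3L, 4L)), b, layer$in_ch * layer$hp * layer$wp)
}

conv_forward <- function(layer, par, x) {
  b <- dim(x)[1]
  xp <- pad_to_mat(layer, x)
  m0 <- xp[, layer$col_idx, drop = FALSE]            # B x (nk * np), k fastest
  dim(m0) <- c(b, layer$nk, layer$np)
  mm <- matrix(aperm(m0, c(1L, 3L, 2L)), b * layer$np, layer$nk)
  y <- mm %*% par$W
  y <- sweep(y, 2L, par$b, `+`)
  dim(y) <- c(b, layer$out_h, layer$out_w, layer$out_ch)
  list(y = aperm(y, c(1L, 4L, 2L, 3L)), mm = mm)
}

conv_backward <- function(layer, par, cache, dy) {
  b <- dim(dy)[1]
  dym <- matrix(aperm(dy, c(1L, 3L, 4L, 2L)), b * layer$np, layer$out_ch)
  dW <- crossprod(cache$mm, dym)
  db <- colSums(dym)
  dmm <- tcrossprod(dym, par$W)                      # (B*np) x nk
  dim(dmm) <- c(b, layer$np, layer$nk)
  dxp <- matrix(0, b, layer$in_ch * layer$hp * layer$wp)
  for (k in seq_len(layer$nk)) {
    cols <- layer$idx[, k]
    dxp[, cols] <- dxp[, cols] + dmm[, , k]
  }
  dim(dxp) <- c(b, layer$in_ch, layer$hp, layer$wp)
  dx <- dxp[, , layer$ph + seq_len(layer$in_h), layer$pw + seq_len(layer$in_w), drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  oh <- d[3] %/% 2L
  ow <- d[4] %/% 2L
  ri <- seq_len(oh) * 2L - 1L
  ci <- seq_len(ow) * 2L - 1L
  s11 <- x[, , ri, ci, drop = FALSE]
  s21 <- x[, , ri + 1L, ci, drop = FALSE]
  s12 <- x[, , ri, ci + 1L, drop = FALSE]
  s22 <- x[, , ri + 1L, ci + 1L, drop = FALSE]
  y <- pmax(s11, s21, s12, s22)
  # first-match routing for ties, fixed scan order
  w11 <- s11 == y
  w21 <- (s21 == y) & !w11
  w12 <- (s12 == y) & !w11 & !w21
  w22 <- !(w11 | w21 | w12)
  list(y = y, w = list(w11 = w11, w21 = w21, w12 = w12, w22 = w22), in_dim = d)
}

maxpool_backward <- function(cache, dy) {
  d <- cache$in_dim
  oh <- d[3] %/% 2L
  ow <- d[4] %/% 2L
  ri <- seq_len(oh) * 2L - 1L
  ci <- seq_len(ow) * 2L - 1L
  dx <- array(0, d)
  dx[, , ri, ci] <- dy * cache$w$w11
  dx[, , ri + 1L, ci] <- dy * cache$w$w21
  dx[, , ri, ci + 1L] <- dy * cache$w$w12
  dx[, , ri + 1L, ci + 1L] <- dy * cache$w$w22
  dx
}

bn_init <- function(n_ch) {
  list(gamma = rep(1, n_ch), beta = rep(0, n_ch))
}

bn_state_init <- function(n_ch) {
  list(mean = rep(0, n_ch), var = rep(1, n_ch))
}

# Batch normalisation over (B, H, W) per channel. Returns updated running
# state in training mode (momentum 0.1).
bn_forward <- function(par, state, x, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  n <- d[1] * d[3] * d[4]
  xm <- matrix(aperm(x, c(1L, 3L, 4L, 2L)), n, d[2])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- sweep(xm, 2L, mu)
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_std, `*`)
  ym <- sweep(sweep(xhat, 2L, par$gamma, `*`), 2L, par$beta, `+`)
  dim(ym) <- c(d[1], d[3], d[4], d[2])
  list(y = aperm(ym, c(1L, 4L, 2L, 3L)), state = state,
       cache = list(xhat = xhat, inv_std = inv_std, d = d, training = training))
}

bn_backward <- function(par, cache, dy) {
  d <- cache$d
  n <- d[1] * d[3] * d[4]
  dym <- matrix(aperm(dy, c(1L, 3L, 4L, 2L)), n, d[2])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (cache$training) {
    dxhat <- sweep(dym, 2L, par$gamma, `*`)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
    dxm <- sweep(t1 - t2, 2L, cache$inv_std, `*`)
  } else {
    dxm <- sweep(dym, 2L, par$gamma * cache$inv_std, `*`)
  }
  dim(dxm) <- c(d[1], d[3], d[4], d[2])
  list(dx = aperm(dxm, c(1L, 4L, 2L, 3L)), dgamma = dgamma, dbeta = dbeta)
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(cache, dy) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}
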