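# Vectorized layer primitives for the deep classifiers: forward passes
# return (output, cache); backward passes consume the cache and the output
# gradient and return (input gradient, parameter gradients). Conv inputs are
# arrays (batch, height, width, channels); sequence inputs (batch, time,
# features). All layers are exact (checked against numerical gradients).

glorot_mat <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -limit, limit), n_in, n_out)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

apply_activation <- function(x, activation) {
  switch(activation,
         relu = pmax(x, 0),
         sigmoid = sigmoid(x),
         linear = x,
         dv_stop("dysvoice_error_bad_params", "unknown activation %s", activation))
}

activation_grad <- function(out, activation) {
  switch(activation,
         relu = (out > 0) * 1,
         sigmoid = out * (1 - out),
         linear = 1)
}

# ---- convolution ----------------------------------------------------------

# 'same' padding split (asymmetric for even kernels, trailing side larger).
pad_split <- function(k) {
  beg <- (k - 1) %/% 2
  c(beg, k - 1 - beg)
}

# Columnize: (B,H,W,C) -> (B*H*W, kh*kw*C); block order (dj, di), channel
# fastest within a block. Weight rows use the same order.
im2col <- function(x, kh, kw) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  ph <- pad_split(kh); pw <- pad_split(kw)
  xp <- array(0, c(B, H + kh - 1, W + kw - 1, C))
  xp[, (ph[1] + 1):(ph[1] + H), (pw[1] + 1):(pw[1] + W), ] <- x
  blocks <- vector("list", kh * kw)
  idx <- 1
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      sl <- xp[, di:(di + H - 1), dj:(dj + W - 1), , drop = FALSE]
      dim(sl) <- c(B * H * W, C)
      blocks[[idx]] <- sl
      idx <- idx + 1
    }
  }
  do.call(cbind, blocks)
}

col2im <- function(dcols, dims, kh, kw) {
  B <- dims[1]; H <- dims[2]; W <- dims[3]; C <- dims[4]
  ph <- pad_split(kh); pw <- pad_split(kw)
  dxp <- array(0, c(B, H + kh - 1, W + kw - 1, C))
  idx <- 1
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      block <- dcols[, ((idx - 1) * C + 1):(idx * C), drop = FALSE]
      dim(block) <- c(B, H, W, C)
      dxp[, di:(di + H - 1), dj:(dj + W - 1), ] <-
        dxp[, di:(di + H - 1), dj:(dj + W - 1), , drop = FALSE] + block
      idx <- idx + 1
    }
  }
  dxp[, (ph[1] + 1):(ph[1] + H), (pw[1] + 1):(pw[1] + W), , drop = FALSE]
}

conv2d_forward <- function(x, W, b, activation) {
  d <- dim(x)
  cols <- im2col(x, attr(W, "kh"), attr(W, "kw"))
  out <- sweep(cols %*% W, 2, b, `+`)
  out <- apply_activation(out, activation)
  y <- array(out, c(d[1], d[2], d[3], ncol(W)))
  list(out = y, cache = list(cols = cols, dims = d, act_out = out))
}

conv2d_backward <- function(dy, W, cache, activation) {
  d <- dim(dy)
  dym <- matrix(dy, prod(d[1:3]), d[4])
  dym <- dym * activation_grad(cache$act_out, activation)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, W)
  dx <- col2im(dcols, cache$dims, attr(W, "kh"), attr(W, "kw"))
  list(grad_in = dx, grads = list(W = dW, b = db))
}

# ---- 2x2 max pooling ------------------------------------------------------

maxpool_forward <- function(x) {
  d <- dim(x)
  io <- seq(1, d[2], 2); ie <- io + 1
  jo <- seq(1, d[3], 2); je <- jo + 1
  s <- list(x[, io, jo, , drop = FALSE], x[, ie, jo, , drop = FALSE],
            x[, io, je, , drop = FALSE], x[, ie, je, , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(m))
  masks <- vector("list", 4)
  for (q in 1:4) {
    masks[[q]] <- (s[[q]] == m) & !taken
    taken <- taken | masks[[q]]
  }
  list(out = m, cache = list(masks = masks, dims = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims
  io <- seq(1, d[2], 2); ie <- io + 1
  jo <- seq(1, d[3], 2); je <- jo + 1
  dx <- array(0, d)
  dx[, io, jo, ] <- dy * cache$masks[[1]]
  dx[, ie, jo, ] <- dy * cache$masks[[2]]
  dx[, io, je, ] <- dy * cache$masks[[3]]
  dx[, ie, je, ] <- dy * cache$masks[[4]]
  dx
}

# ---- shape plumbing -------------------------------------------------------

flatten_forward <- function(x) {
  d <- dim(x)
  list(out = matrix(x, d[1], prod(d[-1])), cache = d)
}

flatten_backward <- function(dy, dims) array(dy, dims)

# Conv grid -> sequence: time-major flatten (timesteps follow the conv
# height axis, each height row split into T/H consecutive chunks of the
# width-by-channel features), then blocks of size D become timesteps.
reshape_seq_forward <- function(x, timesteps) {
  d <- dim(x)
  if (timesteps %% d[2] != 0 || prod(d[-1]) %% timesteps != 0) {
    dv_stop("dysvoice_error_bad_shape",
            "cannot reshape %s grid into %d timesteps",
            paste(d[-1], collapse = "x"), timesteps)
  }
  D <- prod(d[-1]) / timesteps
  y <- aperm(x, c(1, 3, 4, 2))           # (B, W, C, H): h slowest
  dim(y) <- c(d[1], D, timesteps)
  list(out = aperm(y, c(1, 3, 2)), cache = d)
}

reshape_seq_backward <- function(dy, dims) {
  d <- dim(dy)
  y <- aperm(dy, c(1, 3, 2))
  dim(y) <- c(dims[1], dims[3], dims[4], dims[2])
  aperm(y, c(1, 4, 2, 3))
}

seq_slice <- function(x, t) matrix(x[, t, ], nrow = dim(x)[1])

# ---- dense / dropout ------------------------------------------------------

dense_forward <- function(x, W, b, activation) {
  out <- apply_activation(sweep(x %*% W, 2, b, `+`), activation)
  list(out = out, cache = list(x = x, out = out))
}

dense_backward <- function(dy, W, cache, activation, pre_activation_grad = FALSE) {
  dpre <- if (pre_activation_grad) dy else
    dy * activation_grad(cache$out, activation)
  list(grad_in = tcrossprod(dpre, W),
       grads = list(W = crossprod(cache$x, dpre), b = colSums(dpre)))
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- (matrix(runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dy, mask) if (is.null(mask)) dy else dy * mask

# ---- LSTM -----------------------------------------------------------------

# Gate order within the stacked weight matrices: input, forget, cell, output.
lstm_cell_init <- function(input_dim, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1          # forget-gate bias
  list(Wx = glorot_mat(input_dim, 4 * units),
       Wh = glorot_mat(units, 4 * units),
       b = b)
}

lstm_forward_dir <- function(x, p, units) {
  d <- dim(x); B <- d[1]; Tn <- d[2]
  h <- matrix(0, B, units); cc <- matrix(0, B, units)
  hs <- array(0, c(B, Tn, units))
  cache <- vector("list", Tn)
  iu <- seq_len(units)
  for (t in seq_len(Tn)) {
    xt <- seq_slice(x, t)
    pre <- sweep(xt %*% p$Wx + h %*% p$Wh, 2, p$b, `+`)
    i <- sigmoid(pre[, iu, drop = FALSE])
    f <- sigmoid(pre[, units + iu, drop = FALSE])
    g <- tanh(pre[, 2 * units + iu, drop = FALSE])
    o <- sigmoid(pre[, 3 * units + iu, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = cc, h_prev = h, tc = tc)
    h <- h_new; cc <- c_new
    hs[, t, ] <- h
  }
  list(hs = hs, h_last = h, cache = cache)
}

lstm_backward_dir <- function(dhs, dh_last, p, cache, units, input_dim) {
  Tn <- length(cache); B <- nrow(cache[[1]]$xt)
  dWx <- matrix(0, input_dim, 4 * units)
  dWh <- matrix(0, units, 4 * units)
  db <- numeric(4 * units)
  dx <- array(0, c(B, Tn, input_dim))
  dh <- if (is.null(dh_last)) matrix(0, B, units) else dh_last
  dc <- matrix(0, B, units)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    if (!is.null(dhs)) dh <- dh + seq_slice(dhs, t)
    do <- dh * cc$tc * cc$o * (1 - cc$o)
    dct <- dh * cc$o * (1 - cc$tc^2) + dc
    df <- dct * cc$c_prev * cc$f * (1 - cc$f)
    di <- dct * cc$g * cc$i * (1 - cc$i)
    dg <- dct * cc$i * (1 - cc$g^2)
    dc <- dct * cc$f
    dpre <- cbind(di, df, dg, do)
    dWx <- dWx + crossprod(cc$xt, dpre)
    dWh <- dWh + crossprod(cc$h_prev, dpre)
    db <- db + colSums(dpre)
    dx[, t, ] <- tcrossprod(dpre, p$Wx)
    dh <- tcrossprod(dpre, p$Wh)
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- GRU ------------------------------------------------------------------

# Gate order: update (z), reset (r), candidate (h). The state update follows
# the printed convention h_t = (1 - z_t) * h_{t-1} + z_t * h~_t.
gru_cell_init <- function(input_dim, units) {
  list(Wx = glorot_mat(input_dim, 3 * units),
       Wh = glorot_mat(units, 3 * units),
       b = numeric(3 * units))
}

gru_forward_dir <- function(x, p, units) {
  d <- dim(x); B <- d[1]; Tn <- d[2]
  h <- matrix(0, B, units)
  hs <- array(0, c(B, Tn, units))
  cache <- vector("list", Tn)
  iu <- seq_len(units)
  for (t in seq_len(Tn)) {
    xt <- seq_slice(x, t)
    xw <- sweep(xt %*% p$Wx, 2, p$b, `+`)
    hz <- h %*% p$Wh[, iu, drop = FALSE]
    hr <- h %*% p$Wh[, units + iu, drop = FALSE]
    z <- sigmoid(xw[, iu, drop = FALSE] + hz)
    r <- sigmoid(xw[, units + iu, drop = FALSE] + hr)
    rh <- r * h
    hc <- tanh(xw[, 2 * units + iu, drop = FALSE] +
                 rh %*% p$Wh[, 2 * units + iu, drop = FALSE])
    h_new <- (1 - z) * h + z * hc
    cache[[t]] <- list(xt = xt, z = z, r = r, hc = hc, h_prev = h, rh = rh)
    h <- h_new
    hs[, t, ] <- h
  }
  list(hs = hs, h_last = h, cache = cache)
}

gru_backward_dir <- function(dhs, dh_last, p, cache, units, input_dim) {
  Tn <- length(cache); B <- nrow(cache[[1]]$xt)
  dWx <- matrix(0, input_dim, 3 * units)
  dWh <- matrix(0, units, 3 * units)
  db <- numeric(3 * units)
  dx <- array(0, c(B, Tn, input_dim))
  dh <- if (is.null(dh_last)) matrix(0, B, units) else dh_last
  iu <- seq_len(units)
  Whz <- p$Wh[, iu, drop = FALSE]
  Whr <- p$Wh[, units + iu, drop = FALSE]
  Whh <- p$Wh[, 2 * units + iu, drop = FALSE]
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    if (!is.null(dhs)) dh <- dh + seq_slice(dhs, t)
    dz <- dh * (cc$hc - cc$h_prev) * cc$z * (1 - cc$z)
    dhc <- dh * cc$z * (1 - cc$hc^2)
    dh_prev <- dh * (1 - cc$z)
    drh <- tcrossprod(dhc, Whh)
    dr <- drh * cc$h_prev * cc$r * (1 - cc$r)
    dh_prev <- dh_prev + drh * cc$r
    dh_prev <- dh_prev + tcrossprod(dz, Whz) + tcrossprod(dr, Whr)
    dpre <- cbind(dz, dr, dhc)
    dWx <- dWx + crossprod(cc$xt, dpre)
    db <- db + colSums(dpre)
    dWh[, iu] <- dWh[, iu] + crossprod(cc$h_prev, dz)
    dWh[, units + iu] <- dWh[, units + iu] + crossprod(cc$h_prev, dr)
    dWh[, 2 * units + iu] <- dWh[, 2 * units + iu] + crossprod(cc$rh, dhc)
    dx[, t, ] <- tcrossprod(dpre, p$Wx)
    dh <- dh_prev
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

reverse_time <- function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]

# Recurrent layer front-end: handles uni/bidirectional LSTM and GRU,
# return_sequences or final-state output. For a bidirectional layer the
# forward and backward reads are concatenated along the feature axis.
recurrent_forward <- function(x, params, desc) {
  fwd_fn <- if (desc$cell == "lstm") lstm_forward_dir else gru_forward_dir
  f <- fwd_fn(x, params$fwd, desc$units)
  if (!desc$bidirectional) {
    out <- if (desc$return_sequences) f$hs else f$h_last
    return(list(out = out, cache = list(f = f)))
  }
  b <- fwd_fn(reverse_time(x), params$bwd, desc$units)
  if (desc$return_sequences) {
    B <- dim(x)[1]; Tn <- dim(x)[2]
    out <- array(0, c(B, Tn, 2 * desc$units))
    out[, , seq_len(desc$units)] <- f$hs
    out[, , desc$units + seq_len(desc$units)] <- reverse_time(b$hs)
  } else {
    out <- cbind(f$h_last, b$h_last)
  }
  list(out = out, cache = list(f = f, b = b))
}

recurrent_backward <- function(dy, params, desc, cache, input_dim) {
  bwd_fn <- if (desc$cell == "lstm") lstm_backward_dir else gru_backward_dir
  U <- desc$units
  if (desc$return_sequences) {
    dhs_f <- dy[, , seq_len(U), drop = FALSE]
    r <- bwd_fn(dhs_f, NULL, params$fwd, cache$f$cache, U, input_dim)
  } else {
    r <- bwd_fn(NULL, dy[, seq_len(U), drop = FALSE], params$fwd,
                cache$f$cache, U, input_dim)
  }
  if (!desc$bidirectional) {
    return(list(grad_in = r$dx, grads = list(fwd = r$grads)))
  }
  if (desc$return_sequences) {
    dhs_b <- reverse_time(dy[, , U + seq_len(U), drop = FALSE])
    rb <- bwd_fn(dhs_b, NULL, params$bwd, cache$b$cache, U, input_dim)
  } else {
    rb <- bwd_fn(NULL, dy[, U + seq_len(U), drop = FALSE], params$bwd,
                 cache$b$cache, U, input_dim)
  }
  list(grad_in = r$dx + reverse_time(rb$dx),
       grads = list(fwd = r$grads, bwd = rb$grads))
}
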