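# Minimal recurrent network engine: batched LSTM forward / backward
# (BPTT), leaky ReLU, inverted dropout, dense head, MSE loss and Adam.
# Written in vectorized base R; gradients are validated against central
# finite differences in the test suite. Gate block order in the fused
# weight matrices is (input, forget, cell, output).

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# One LSTM layer's parameters: W [D, 4H], U [H, 4H], b [4H] with the
# forget-gate bias block initialized to 1 (standard practice: start by
# remembering).
init_lstm_params <- function(input_dim, hidden) {
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1
  list(W = glorot(input_dim, 4 * hidden),
       U = glorot(hidden, 4 * hidden),
       b = b)
}

init_dense_params <- function(input_dim, output_dim) {
  list(W = glorot(input_dim, output_dim), b = numeric(output_dim))
}

# x: list over natural time 1..T of [B, D] matrices.
# Returns h: list over natural time of [B, H], plus per-step cache.
lstm_layer_forward <- function(p, x, reverse = FALSE) {
  T_ <- length(x)
  B <- nrow(x[[1]])
  H <- ncol(p$U) / 4L
  idx <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  hprev <- matrix(0, B, H)
  cprev <- matrix(0, B, H)
  h <- vector("list", T_)
  cache <- vector("list", T_)
  bmat <- matrix(p$b, B, 4L * H, byrow = TRUE)
  gi <- 1:H; gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
  for (t in idx) {
    z <- x[[t]] %*% p$W + hprev %*% p$U + bmat
    i <- sigmoid(z[, gi, drop = FALSE])
    f <- sigmoid(z[, gf, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    o <- sigmoid(z[, go, drop = FALSE])
    c_ <- f * cprev + i * g
    tc <- tanh(c_)
    hcur <- o * tc
    cache[[t]] <- list(x = x[[t]], i = i, f = f, g = g, o = o,
                       cprev = cprev, hprev = hprev, tc = tc)
    h[[t]] <- hcur
    hprev <- hcur
    cprev <- c_
  }
  list(h = h, cache = cache, reverse = reverse, H = H)
}

# dh: list over natural time of [B, H] upstream gradients (zeros where
# the layer output is unused). Returns dx (same shape as x) and grads.
lstm_layer_backward <- function(p, fwd, dh) {
  T_ <- length(dh)
  B <- nrow(dh[[1]])
  H <- fwd$H
  idx <- if (fwd$reverse) rev(seq_len(T_)) else seq_len(T_)
  gW <- p$W * 0; gU <- p$U * 0; gb <- p$b * 0
  dx <- vector("list", T_)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  tW <- t(p$W); tU <- t(p$U)
  for (t in rev(idx)) {     # reverse of processing order
    cc <- fwd$cache[[t]]
    d <- dh[[t]] + dh_next
    do_ <- d * cc$tc
    dc <- d * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    df <- dc * cc$cprev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    gW <- gW + crossprod(cc$x, dz)
    gU <- gU + crossprod(cc$hprev, dz)
    gb <- gb + colSums(dz)
    dx[[t]] <- dz %*% tW
    dh_next <- dz %*% tU
    dc_next <- dc * cc$f
  }
  list(dx = dx, grads = list(W = gW, U = gU, b = gb))
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Runtime architecture description derived from a model_spec.
nn_arch <- function(spec, n_channels) {
  dirs <- if (isTRUE(spec$bidirectional)) 2L else 1L
  h1 <- spec$layer1_units
  h2 <- if (isTRUE(spec$stacked)) spec$layer2_units else NULL
  dense_in <- dirs * if (is.null(h2)) h1 else h2
  list(n_channels = n_channels, dirs = dirs, h1 = h1, h2 = h2,
       dense_in = dense_in, horizon = spec$horizon_len,
       slope = spec$leaky_relu_slope, stacked = isTRUE(spec$stacked),
       bidirectional = isTRUE(spec$bidirectional))
}

# Parameter initialization for the full network (uses the current RNG
# state; callers seed it).
init_model_params <- function(arch) {
  p <- list(l1f = init_lstm_params(arch$n_channels, arch$h1))
  if (arch$bidirectional) p$l1b <- init_lstm_params(arch$n_channels, arch$h1)
  if (arch$stacked) {
    in2 <- arch$dirs * arch$h1
    p$l2f <- init_lstm_params(in2, arch$h2)
    if (arch$bidirectional) p$l2b <- init_lstm_params(in2, arch$h2)
  }
  p$dense <- init_dense_params(arch$dense_in, arch$horizon)
  p
}

# X: array [B, T, C] -> list of [B, C] per time step.
unstack_time <- function(X) {
  B <- dim(X)[1]; T_ <- dim(X)[2]; C <- dim(X)[3]
  lapply(seq_len(T_), function(t) matrix(X[, t, ], B, C))
}

# Forward pass. drop_masks: NULL (inference) or list(d1 = [B,T,F1] array,
# d2 = [B,F2] matrix) of inverted-dropout masks (already scaled).
# Architecture: LSTM(h1, sequences) -> leaky ReLU -> dropout ->
# [LSTM(h2, last) -> dropout] -> dense(horizon); the single-layer
# ("vanilla") variant drops the bracketed block and takes the last step
# of layer 1.
nn_forward <- function(params, arch, X, drop_masks = NULL) {
  x <- unstack_time(X)
  T_ <- length(x); B <- nrow(x[[1]])
  f1 <- lstm_layer_forward(params$l1f, x, reverse = FALSE)
  if (arch$bidirectional) {
    b1 <- lstm_layer_forward(params$l1b, x, reverse = TRUE)
    s1 <- lapply(seq_len(T_), function(t) cbind(f1$h[[t]], b1$h[[t]]))
  } else {
    b1 <- NULL
    s1 <- f1$h
  }
  a1 <- lapply(s1, leaky_relu, slope = arch$slope)
  d1 <- a1
  if (!is.null(drop_masks)) {
    d1 <- lapply(seq_len(T_), function(t) {
      a1[[t]] * matrix(drop_masks$d1[, t, ], B)
    })
  }
  if (arch$stacked) {
    f2 <- lstm_layer_forward(params$l2f, d1, reverse = FALSE)
    last <- f2$h[[T_]]
    if (arch$bidirectional) {
      b2 <- lstm_layer_forward(params$l2b, d1, reverse = TRUE)
      last <- cbind(last, b2$h[[1L]])
    } else b2 <- NULL
    pre_dense <- last
  } else {
    f2 <- NULL; b2 <- NULL
    last <- if (arch$bidirectional) cbind(f1$h[[T_]], b1$h[[1L]]) else f1$h[[T_]]
    # vanilla variant: leaky ReLU + dropout act on the last state only
    last <- leaky_relu(last, arch$slope)
    if (!is.null(drop_masks)) {
      last <- last * matrix(drop_masks$d1[, T_, ], B)
    }
    pre_dense <- last
  }
  d2 <- pre_dense
  if (!is.null(drop_masks) && arch$stacked) d2 <- pre_dense * drop_masks$d2
  Y <- d2 %*% params$dense$W +
    matrix(params$dense$b, B, arch$horizon, byrow = TRUE)
  list(Y = Y, f1 = f1, b1 = b1, f2 = f2, b2 = b2, s1 = s1, a1 = a1,
       d1 = d1, d2 = d2, T_ = T_, B = B, drop_masks = drop_masks)
}

# Backward pass from dY ([B, horizon]); returns grads mirroring params.
nn_backward <- function(params, arch, fwd, dY) {
  B <- fwd$B; T_ <- fwd$T_
  grads <- list()
  grads$dense <- list(W = crossprod(fwd$d2, dY), b = colSums(dY))
  d_pre <- dY %*% t(params$dense$W)
  if (arch$stacked && !is.null(fwd$drop_masks)) {
    d_pre <- d_pre * fwd$drop_masks$d2
  }
  zero_seq <- function(H) lapply(seq_len(T_), function(t) matrix(0, B, H))

  if (arch$stacked) {
    h2 <- arch$h2
    dh2f <- zero_seq(h2)
    dh2f[[T_]] <- d_pre[, 1:h2, drop = FALSE]
    bk2f <- lstm_layer_backward(params$l2f, fwd$f2, dh2f)
    grads$l2f <- bk2f$grads
    dd1 <- bk2f$dx
    if (arch$bidirectional) {
      dh2b <- zero_seq(h2)
      dh2b[[1L]] <- d_pre[, h2 + (1:h2), drop = FALSE]
      bk2b <- lstm_layer_backward(params$l2b, fwd$b2, dh2b)
      grads$l2b <- bk2b$grads
      dd1 <- lapply(seq_len(T_), function(t) dd1[[t]] + bk2b$dx[[t]])
    }
    # back through dropout and leaky ReLU on the layer-1 sequence
    da1 <- dd1
    if (!is.null(fwd$drop_masks)) {
      da1 <- lapply(seq_len(T_), function(t) {
        dd1[[t]] * matrix(fwd$drop_masks$d1[, t, ], B)
      })
    }
    ds1 <- lapply(seq_len(T_), function(t) {
      da1[[t]] * leaky_relu_grad(fwd$s1[[t]], arch$slope)
    })
  } else {
    h1w <- arch$dirs * arch$h1
    dlast <- d_pre
    if (!is.null(fwd$drop_masks)) {
      dlast <- dlast * matrix(fwd$drop_masks$d1[, T_, ], B)
    }
    raw_last <- if (arch$bidirectional) {
      cbind(fwd$f1$h[[T_]], fwd$b1$h[[1L]])
    } else fwd$f1$h[[T_]]
    dlast <- dlast * leaky_relu_grad(raw_last, arch$slope)
    ds1 <- zero_seq(h1w)
    if (arch$bidirectional) {
      ds1[[T_]][, 1:arch$h1] <- dlast[, 1:arch$h1]
      ds1[[1L]][, arch$h1 + (1:arch$h1)] <- dlast[, arch$h1 + (1:arch$h1)]
    } else {
      ds1[[T_]] <- dlast
    }
  }

  h1 <- arch$h1
  dh1f <- lapply(ds1, function(m) m[, 1:h1, drop = FALSE])
  bk1f <- lstm_layer_backward(params$l1f, fwd$f1, dh1f)
  grads$l1f <- bk1f$grads
  if (arch$bidirectional) {
    dh1b <- lapply(ds1, function(m) m[, h1 + (1:h1), drop = FALSE])
    bk1b <- lstm_layer_backward(params$l1b, fwd$b1, dh1b)
    grads$l1b <- bk1b$grads
  }
  grads[names(params)]
}

# Mean-squared-error loss and full gradient for one batch.
nn_loss_grads <- function(params, arch, X, Tgt, drop_masks = NULL) {
  fwd <- nn_forward(params, arch, X, drop_masks)
  err <- fwd$Y - Tgt
  loss <- mean(err^2)
  dY <- 2 * err / length(err)
  list(loss = loss, grads = nn_backward(params, arch, fwd, dY), Y = fwd$Y)
}

# --- nested-parameter-list utilities ---------------------------------------

param_map <- function(f, p) {
  if (is.list(p)) return(lapply(p, function(q) param_map(f, q)))
  f(p)
}

param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    return(mapply(function(x, y) param_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

param_count <- function(p) {
  if (is.list(p)) return(sum(vapply(p, param_count, numeric(1))))
  length(p)
}

adam_init <- function(params) {
  list(m = param_map(function(x) x * 0, params),
       v = param_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  mhat <- param_map(function(m) m / c1, state$m)
  vhat <- param_map(function(v) v / c2, state$v)
  upd <- param_map2(function(m, v) m / (sqrt(v) + eps), mhat, vhat)
  params <- param_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}
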