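# Internal layer machinery: forward/backward passes for the small set of
# layer types the four architectures need (input batch norm, flatten, dense,
# ReLU, 1-D temporal convolution, non-overlapping max-pool, LSTM, last-step
# selection), plus ADADELTA. Arrays between layers are either [B x T x C]
# sequence tensors or [B x d] matrices.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# ---- constructors ----------------------------------------------------------

layer_bn <- function(C) {
  list(type = "bn",
       params = list(gamma = rep(1, C), beta = rep(0, C)),
       state = list(run_mean = rep(0, C), run_var = rep(1, C)))
}
layer_flatten <- function() list(type = "flatten", params = list())
layer_fc <- function(d_in, d_out) {
  list(type = "fc", d_in = d_in, d_out = d_out,
       params = list(W = matrix(0, d_in, d_out), b = rep(0, d_out)))
}
layer_relu <- function() list(type = "relu", params = list())
layer_conv <- function(C_in, kernel, stride, n_kernels) {
  list(type = "conv", k = kernel, stride = stride, C_in = C_in, F = n_kernels,
       params = list(W = matrix(0, kernel * C_in, n_kernels),
                     b = rep(0, n_kernels)))
}
layer_pool <- function(p) list(type = "pool", p = p, params = list())
layer_lstm <- function(d_in, hidden) {
  list(type = "lstm", d_in = d_in, hidden = hidden,
       params = list(Wx = matrix(0, d_in, 4 * hidden),
                     Wh = matrix(0, hidden, 4 * hidden),
                     b = rep(0, 4 * hidden)))
}
layer_last_step <- function() list(type = "last", params = list())

# output time length of a conv/pool stack applied to T (for shape checks)
conv_out_len <- function(T, k, stride) (T - k) %/% stride + 1L
pool_out_len <- function(T, p) T %/% p

# ---- forward ---------------------------------------------------------------

layer_forward <- function(layer, X, train) {
  switch(layer$type,
    bn = bn_forward(layer, X, train),
    flatten = {
      d <- dim(X)
      out <- matrix(X, d[1], d[2] * d[3])
      list(out = out, cache = d, layer = layer)
    },
    fc = list(out = sweep(X %*% layer$params$W, 2, layer$params$b, "+"),
              cache = X, layer = layer),
    relu = {
      out <- X
      out[out < 0] <- 0
      list(out = out, cache = (X > 0), layer = layer)
    },
    conv = conv_forward(layer, X),
    pool = pool_forward(layer, X),
    lstm = lstm_forward(layer, X),
    last = {
      d <- dim(X)
      list(out = matrix(X[, d[2], ], d[1], d[3]), cache = d, layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

bn_forward <- function(layer, X, train) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  g <- layer$params$gamma; be <- layer$params$beta
  if (train) {
    mu <- vapply(seq_len(C), function(c) mean(X[, , c]), numeric(1))
    va <- vapply(seq_len(C), function(c) {
      xc <- X[, , c]; mean((xc - mu[c])^2)
    }, numeric(1))
    layer$state$run_mean <- (1 - BN_MOMENTUM) * layer$state$run_mean +
      BN_MOMENTUM * mu
    layer$state$run_var <- (1 - BN_MOMENTUM) * layer$state$run_var +
      BN_MOMENTUM * va
  } else {
    mu <- layer$state$run_mean
    va <- layer$state$run_var
  }
  xhat <- X
  out <- X
  for (c in seq_len(C)) {
    xhat[, , c] <- (X[, , c] - mu[c]) / sqrt(va[c] + BN_EPS)
    out[, , c] <- g[c] * xhat[, , c] + be[c]
  }
  list(out = out, cache = list(xhat = xhat, var = va, train = train),
       layer = layer)
}

# im2col for 1-D temporal convolution: columns ordered kernel-pos fastest
# within input channel; rows ordered batch fastest within output position
conv_im2col <- function(X, k, stride) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  T_out <- conv_out_len(T, k, stride)
  starts <- (seq_len(T_out) - 1L) * stride + 1L
  X2 <- matrix(0, B * T_out, k * C)
  for (c in seq_len(C)) for (j in seq_len(k)) {
    X2[, (c - 1L) * k + j] <- as.vector(X[, starts + j - 1L, c])
  }
  list(X2 = X2, T_out = T_out, starts = starts)
}

conv_forward <- function(layer, X) {
  d <- dim(X); B <- d[1]
  ic <- conv_im2col(X, layer$k, layer$stride)
  Y2 <- sweep(ic$X2 %*% layer$params$W, 2, layer$params$b, "+")
  out <- array(Y2, dim = c(B, ic$T_out, layer$F))
  list(out = out, cache = list(X2 = ic$X2, in_dim = d, starts = ic$starts),
       layer = layer)
}

pool_forward <- function(layer, X) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]; p <- layer$p
  T_out <- pool_out_len(T, p)
  if (T_out < 1) stop_invalid("pooling collapses the time axis below 1")
  cur <- X[, (seq_len(T_out) - 1L) * p + 1L, , drop = FALSE]
  arg <- array(1L, dim = c(B, T_out, C))
  if (p > 1) for (j in 2:p) {
    cand <- X[, (seq_len(T_out) - 1L) * p + j, , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(out = cur, cache = list(arg = arg, in_dim = d), layer = layer)
}

lstm_forward <- function(layer, X) {
  d <- dim(X); B <- d[1]; T <- d[2]
  h <- layer$hidden
  Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
  H <- array(0, dim = c(B, T, h))
  h_t <- matrix(0, B, h); c_t <- matrix(0, B, h)
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    x_t <- matrix(X[, t, ], B, layer$d_in)
    z <- x_t %*% Wx + h_t %*% Wh
    z <- sweep(z, 2, b, "+")
    i <- sigmoid(z[, seq_len(h), drop = FALSE])
    f <- sigmoid(z[, h + seq_len(h), drop = FALSE])
    g <- tanh(z[, 2 * h + seq_len(h), drop = FALSE])
    o <- sigmoid(z[, 3 * h + seq_len(h), drop = FALSE])
    c_prev <- c_t
    c_t <- f * c_prev + i * g
    tc <- tanh(c_t)
    h_prev <- h_t
    h_t <- o * tc
    H[, t, ] <- h_t
    steps[[t]] <- list(x = x_t, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = H, cache = steps, layer = layer)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- backward ----------------------------------------------------------------

layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
    bn = bn_backward(layer, cache, dY),
    flatten = list(dX = array(dY, dim = cache), grads = list()),
    fc = list(dX = dY %*% t(layer$params$W),
              grads = list(W = t(cache) %*% dY, b = colSums(dY))),
    relu = list(dX = dY * cache, grads = list()),
    conv = conv_backward(layer, cache, dY),
    pool = pool_backward(layer, cache, dY),
    lstm = lstm_backward(layer, cache, dY),
    last = {
      dX <- array(0, dim = cache)
      dX[, cache[2], ] <- dY
      list(dX = dX, grads = list())
    },
    stop("unknown layer type: ", layer$type)
  )
}

bn_backward <- function(layer, cache, dY) {
  xhat <- cache$xhat; va <- cache$var
  g <- layer$params$gamma
  d <- dim(dY); C <- d[3]
  dX <- dY
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dy <- dY[, , c]; xh <- xhat[, , c]
    dgamma[c] <- sum(dy * xh)
    dbeta[c] <- sum(dy)
    inv_sd <- 1 / sqrt(va[c] + BN_EPS)
    if (cache$train) {
      dX[, , c] <- g[c] * inv_sd * (dy - mean(dy) - xh * mean(dy * xh))
    } else {
      dX[, , c] <- g[c] * inv_sd * dy
    }
  }
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

conv_backward <- function(layer, cache, dY) {
  d <- dim(dY); B <- d[1]; T_out <- d[2]
  dY2 <- matrix(dY, B * T_out, layer$F)
  dW <- t(cache$X2) %*% dY2
  db <- colSums(dY2)
  dX2 <- dY2 %*% t(layer$params$W)
  dX <- array(0, dim = cache$in_dim)
  k <- layer$k
  for (c in seq_len(layer$C_in)) for (j in seq_len(k)) {
    cols <- cache$starts + j - 1L
    dX[, cols, c] <- dX[, cols, c] +
      matrix(dX2[, (c - 1L) * k + j], B, T_out)
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

pool_backward <- function(layer, cache, dY) {
  p <- layer$p
  d_out <- dim(dY); T_out <- d_out[2]
  dX <- array(0, dim = cache$in_dim)
  for (j in seq_len(p)) {
    sel <- (cache$arg == j) * dY
    dX[, (seq_len(T_out) - 1L) * p + j, ] <-
      dX[, (seq_len(T_out) - 1L) * p + j, ] + sel
  }
  list(dX = dX, grads = list())
}

lstm_backward <- function(layer, steps, dH) {
  d <- dim(dH); B <- d[1]; T <- d[2]; h <- layer$hidden
  Wx <- layer$params$Wx; Wh <- layer$params$Wh
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4 * h)
  dX <- array(0, dim = c(B, T, layer$d_in))
  dh_next <- matrix(0, B, h); dc_next <- matrix(0, B, h)
  for (t in rev(seq_len(T))) {
    st <- steps[[t]]
    dh <- matrix(dH[, t, ], B, h) + dh_next
    do_ <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + t(st$x) %*% dz
    dWh <- dWh + t(st$h_prev) %*% dz
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
    dc_next <- dc * st$f
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- ADADELTA ----------------------------------------------------------------

# per-array accumulator state mirroring the parameter structure
adadelta_init <- function(params) {
  lapply(params, function(p) list(Eg2 = p * 0, Edx2 = p * 0))
}

adadelta_update <- function(params, grads, state, rho = 0.9, eps = 1e-6) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$Eg2 <- rho * st$Eg2 + (1 - rho) * g^2
    dx <- -sqrt(st$Edx2 + eps) / sqrt(st$Eg2 + eps) * g
    st$Edx2 <- rho * st$Edx2 + (1 - rho) * dx^2
    params[[nm]] <- params[[nm]] + dx
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# orthogonal init of every weight matrix in a layer; biases 0, BN gamma/beta
# untouched (1/0)
init_layer_params <- function(layer) {
  p <- layer$params
  for (nm in names(p)) {
    if (nm %in% c("W", "Wx", "Wh")) {
      dmn <- dim(p[[nm]])
      p[[nm]] <- orthogonal_matrix(dmn[1], dmn[2])
    } else if (nm == "b") {
      p[[nm]] <- p[[nm]] * 0
    }
  }
  layer$params <- p
  layer
}
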