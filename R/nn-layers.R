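# Minimal neural-network kernel: 1-D convolution, LSTM, dense layers with
# hand-derived backpropagation and an Adam optimizer. Written in base-R matrix
# code; gradients are verified against finite differences in the test suite.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

adam_init <- function(params) {
  list(m = purrr::map(params, function(p) p * 0),
       v = purrr::map(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, params = params)
}

# ---- CNN-LSTM parameter initialisation -------------------------------------

cnn_lstm_init <- function(n_channels, conv_filters, conv_kernel, lstm_units,
                          lstm_layers, n_outputs) {
  params <- list()
  for (j in seq_len(conv_kernel)) {
    params[[paste0("convW", j)]] <- glorot(n_channels, conv_filters)
  }
  params$convb <- numeric(conv_filters)
  nin <- conv_filters
  for (l in seq_len(lstm_layers)) {
    params[[paste0("Wx", l)]] <- glorot(nin, 4 * lstm_units)
    params[[paste0("Wh", l)]] <- glorot(lstm_units, 4 * lstm_units)
    b <- numeric(4 * lstm_units)
    b[(lstm_units + 1):(2 * lstm_units)] <- 1  # forget-gate bias
    params[[paste0("b", l)]] <- b
    nin <- lstm_units
  }
  params$denseW <- glorot(lstm_units, n_outputs)
  params$denseb <- numeric(n_outputs)
  params
}

# ---- forward pass -----------------------------------------------------------

# X: array [B, T, C]. Returns prediction [B, n_out] and caches for backprop.
cnn_lstm_forward <- function(params, X, conv_kernel, lstm_units, lstm_layers,
                             keep_cache = TRUE) {
  B <- dim(X)[1]; T_in <- dim(X)[2]; C <- dim(X)[3]
  T_c <- T_in - conv_kernel + 1
  H <- lstm_units
  # convolution (valid) + ReLU
  Z <- array(0, c(B, T_c, ncol(params$convW1)))
  for (j in seq_len(conv_kernel)) {
    Wj <- params[[paste0("convW", j)]]
    for (t in seq_len(T_c)) {
      Z[, t, ] <- Z[, t, , drop = FALSE] +
        array(matrix(X[, t + j - 1, ], B, C) %*% Wj, c(B, 1, ncol(Wj)))
    }
  }
  Z <- sweep(Z, 3, params$convb, "+")
  A <- pmax(Z, 0)
  caches <- if (keep_cache) list(X = X, Z = Z, A = A) else list()
  layer_in <- A  # [B, T_c, F]
  lstm_caches <- vector("list", lstm_layers)
  for (l in seq_len(lstm_layers)) {
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    b <- params[[paste0("b", l)]]
    nin <- nrow(Wx)
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    Hs <- array(0, c(B, T_c, H))
    cache_t <- if (keep_cache) vector("list", T_c) else NULL
    for (t in seq_len(T_c)) {
      x_t <- matrix(layer_in[, t, ], B, nin)
      z <- x_t %*% Wx + h %*% Wh
      z <- z + rep(b, each = B)
      i <- sigmoid(z[, 1:H, drop = FALSE])
      f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
      c_prev <- cc
      cc <- f * c_prev + i * g
      tc <- tanh(cc)
      h <- o * tc
      Hs[, t, ] <- h
      if (keep_cache) {
        cache_t[[t]] <- list(x = x_t, i = i, f = f, g = g, o = o,
                             c = cc, c_prev = c_prev, tc = tc)
      }
    }
    if (keep_cache) {
      lstm_caches[[l]] <- list(steps = cache_t, Hs = Hs)
    }
    layer_in <- Hs
  }
  h_last <- matrix(layer_in[, T_c, ], B, H)
  yhat <- h_last %*% params$denseW +
    matrix(params$denseb, B, length(params$denseb), byrow = TRUE)
  list(yhat = yhat, h_last = h_last, caches = caches,
       lstm_caches = lstm_caches, T_c = T_c)
}

# ---- backward pass ----------------------------------------------------------

# dyhat: [B, n_out] gradient of the loss wrt predictions.
cnn_lstm_backward <- function(params, fwd, dyhat, conv_kernel, lstm_units,
                              lstm_layers) {
  B <- nrow(dyhat); H <- lstm_units; T_c <- fwd$T_c
  grads <- purrr::map(params, function(p) p * 0)
  grads$denseW <- crossprod(fwd$h_last, dyhat)
  grads$denseb <- colSums(dyhat)
  # gradient flowing into each layer's hidden sequence
  dH_next <- array(0, c(B, T_c, H))
  dH_next[, T_c, ] <- dyhat %*% t(params$denseW)
  for (l in rev(seq_len(lstm_layers))) {
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    nin <- nrow(Wx)
    steps <- fwd$lstm_caches[[l]]$steps
    dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4 * H)
    dX_layer <- array(0, c(B, T_c, nin))
    dh <- matrix(0, B, H); dc <- matrix(0, B, H)
    for (t in rev(seq_len(T_c))) {
      s <- steps[[t]]
      dh_t <- dh + matrix(dH_next[, t, ], B, H)
      do <- dh_t * s$tc
      dc_t <- dc + dh_t * s$o * (1 - s$tc^2)
      di <- dc_t * s$g
      df <- dc_t * s$c_prev
      dg <- dc_t * s$i
      dc <- dc_t * s$f
      dz <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do * s$o * (1 - s$o))
      dWx <- dWx + crossprod(s$x, dz)
      db <- db + colSums(dz)
      h_prev <- if (t > 1) {
        matrix(fwd$lstm_caches[[l]]$Hs[, t - 1, ], B, H)
      } else matrix(0, B, H)
      dWh <- dWh + crossprod(h_prev, dz)
      dX_layer[, t, ] <- tcrossprod(dz, Wx)
      dh <- tcrossprod(dz, Wh)
    }
    grads[[paste0("Wx", l)]] <- dWx
    grads[[paste0("Wh", l)]] <- dWh
    grads[[paste0("b", l)]] <- db
    dH_next <- dX_layer
  }
  # conv backward: dH_next is now [B, T_c, F] wrt ReLU output
  dZ <- dH_next * (fwd$caches$Z > 0)
  Fdim <- dim(dZ)[3]
  X <- fwd$caches$X
  C <- dim(X)[3]
  for (j in seq_len(conv_kernel)) {
    dWj <- matrix(0, C, Fdim)
    for (t in seq_len(T_c)) {
      dWj <- dWj + crossprod(matrix(X[, t + j - 1, ], B, C), matrix(dZ[, t, ], B, Fdim))
    }
    grads[[paste0("convW", j)]] <- dWj
  }
  grads$convb <- apply(dZ, 3, sum)
  grads
}
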