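# LSTM layer primitives: forward pass, backpropagation through time, and the
# Adam update. Everything operates on dense base-R matrices (BLAS-backed);
# sequences are (batch x f) matrices per time step with a (batch x T) mask.
# Masked steps carry cell and hidden state through unchanged, so a
# sequence-to-one readout is simply the hidden state after the final step and
# padding provably cannot change predictions.

sigmoid <- function(x) 1 / (1 + exp(-x))

act_fun <- function(name) {
  switch(name,
    relu = list(f = function(x) pmax(x, 0), df = function(x) (x > 0) * 1),
    tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2),
    stop_param("unknown activation: ", name)
  )
}

# Glorot-uniform matrix
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# parameters for one LSTM layer; gate order i, f, g, o; forget bias = 1
lstm_init <- function(f, units) {
  b <- numeric(4L * units)
  b[(units + 1L):(2L * units)] <- 1
  list(Wx = glorot(f, 4L * units), Wh = glorot(units, 4L * units), b = b)
}

lstm_n_params <- function(f, units) 4L * (units * (f + units) + units)

# forward over a sequence.
#  X: list over t of (B x f); mask: (B x T) 0/1.
# returns hidden states per step (after mask carry) and caches for backward.
lstm_forward <- function(par, X, mask, activation = "relu", want_cache = FALSE) {
  act <- act_fun(activation)
  Tn <- length(X)
  B <- nrow(X[[1L]])
  u <- length(par$b) %/% 4L
  h <- matrix(0, B, u)
  cc <- matrix(0, B, u)
  H <- vector("list", Tn)
  cache <- if (want_cache) vector("list", Tn) else NULL
  bmat <- matrix(par$b, B, 4L * u, byrow = TRUE)
  gi <- seq_len(u); gf <- u + gi; gg <- 2L * u + gi; go <- 3L * u + gi
  for (t in seq_len(Tn)) {
    xt <- X[[t]]
    z <- xt %*% par$Wx + h %*% par$Wh + bmat
    ig <- sigmoid(z[, gi, drop = FALSE])
    fg <- sigmoid(z[, gf, drop = FALSE])
    gg_pre <- z[, gg, drop = FALSE]
    g <- act$f(gg_pre)
    og <- sigmoid(z[, go, drop = FALSE])
    c_raw <- fg * cc + ig * g
    ac <- act$f(c_raw)
    h_raw <- og * ac
    mt <- mask[, t]
    c_new <- mt * c_raw + (1 - mt) * cc
    h_new <- mt * h_raw + (1 - mt) * h
    if (want_cache) {
      cache[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, ig = ig, fg = fg,
                         g = g, gg_pre = gg_pre, og = og, c_raw = c_raw,
                         ac = ac, mt = mt)
    }
    h <- h_new
    cc <- c_new
    H[[t]] <- h
  }
  list(H = H, h_last = h, cache = cache)
}

# backward pass. dH: list over t of (B x u) gradients on the (masked) hidden
# outputs; zeros where a step receives no gradient. Returns parameter
# gradients and per-step input gradients dX.
lstm_backward <- function(par, cache, dH, activation = "relu") {
  act <- act_fun(activation)
  Tn <- length(cache)
  B <- nrow(dH[[1L]])
  u <- length(par$b) %/% 4L
  gi <- seq_len(u); gf <- u + gi; gg <- 2L * u + gi; go <- 3L * u + gi
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, u, 4L * u)
  db <- numeric(4L * u)
  dh_next <- matrix(0, B, u)
  dc_next <- matrix(0, B, u)
  dX <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    mt <- cc$mt
    dh_tot <- dH[[t]] + dh_next
    dh_raw <- dh_tot * mt
    dh_carry <- dh_tot * (1 - mt)
    dc_tot <- dc_next
    dc_raw <- dc_tot * mt
    dc_carry <- dc_tot * (1 - mt)
    dog <- dh_raw * cc$ac
    dc_raw <- dc_raw + dh_raw * cc$og * act$df(cc$c_raw)
    dfg <- dc_raw * cc$c_prev
    dig <- dc_raw * cc$g
    dg <- dc_raw * cc$ig
    dc_prev <- dc_raw * cc$fg + dc_carry
    dz <- cbind(dig * cc$ig * (1 - cc$ig),
                dfg * cc$fg * (1 - cc$fg),
                dg * act$df(cc$gg_pre),
                dog * cc$og * (1 - cc$og))
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(par$Wx)
    dh_next <- dz %*% t(par$Wh) + dh_carry
    dc_next <- dc_prev
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# dense layer helpers
dense_init <- function(f, units) {
  list(W = glorot(f, units), b = numeric(units))
}
dense_forward <- function(par, x) x %*% par$W + matrix(par$b, nrow(x),
                                                       length(par$b), byrow = TRUE)

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Adam optimizer state and update for a flat list of parameter arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) stop("missing gradient for parameter ", k, call. = FALSE)
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
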