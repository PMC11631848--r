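## Minimal neural-network engine for the learned inverse operators.
##
## Sequences are (features, time, batch) arrays; time-distributed dense
## layers flatten time and batch into one matrix dimension so everything is
## BLAS matrix products. Backward passes are hand-derived and checked
## against finite differences in the test suite.

slice3 <- function(A, t) matrix(A[, t, ], dim(A)[1], dim(A)[3])

mat3 <- function(A) {
  d <- dim(A)
  dim(A) <- c(d[1], d[2] * d[3])
  A
}

arr3 <- function(M, t_len, b_len) {
  dim(M) <- c(nrow(M), t_len, b_len)
  M
}

## ---- time-distributed dense -------------------------------------------

dense_fwd <- function(W, b, X) {
  d <- dim(X)
  out <- W %*% mat3(X) + b
  list(out = arr3(out, d[2], d[3]), X = X)
}

dense_bwd <- function(W, dO, cache) {
  dOm <- mat3(dO)
  Xm <- mat3(cache$X)
  list(dX = arr3(crossprod(W, dOm), dim(dO)[2], dim(dO)[3]),
       dW = tcrossprod(dOm, Xm), db = rowSums(dOm))
}

## ---- activations -------------------------------------------------------

relu_fwd <- function(X) {
  out <- X * (X > 0)
  list(out = out, mask = X > 0)
}
relu_bwd <- function(dO, cache) dO * cache$mask

elu_fwd <- function(X) {
  neg <- X < 0
  out <- X
  out[neg] <- exp(X[neg]) - 1
  list(out = out, neg = neg, out_saved = out)
}
elu_bwd <- function(dO, cache) {
  g <- dO
  g[cache$neg] <- dO[cache$neg] * (cache$out_saved[cache$neg] + 1)
  g
}

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, mask = NULL, p = p))
  mask <- array(runif(length(X)) >= p, dim(X)) / (1 - p)
  list(out = X * mask, mask = mask, p = p)
}
dropout_bwd <- function(dO, cache) {
  if (is.null(cache$mask)) dO else dO * cache$mask
}

## ---- temporal lag embedding (the 1D convolution as a dense layer) ------

# Stacks K time-shifted copies of the input (zero-padded, centered) so a
# dense layer on the result is exactly a temporal convolution with an
# Ne x K kernel and same-padding in time.
lag_embed_fwd <- function(X, K) {
  d <- dim(X)
  if (d[2] < K) stopf("epoch has %d time points but the kernel spans %d",
                      d[2], K)
  pad <- (K - 1) %/% 2
  out <- array(0, c(d[1] * K, d[2], d[3]))
  for (k in seq_len(K)) {
    off <- k - 1 - pad
    src <- seq_len(d[2]) + off
    keep <- src >= 1 & src <= d[2]
    rows <- ((k - 1) * d[1] + 1):(k * d[1])
    out[rows, which(keep), ] <- X[, src[keep], ]
  }
  list(out = out, K = K, d = d)
}

lag_embed_bwd <- function(dO, cache) {
  d <- cache$d
  K <- cache$K
  pad <- (K - 1) %/% 2
  dX <- array(0, d)
  for (k in seq_len(K)) {
    off <- k - 1 - pad
    src <- seq_len(d[2]) + off
    keep <- src >= 1 & src <= d[2]
    rows <- ((k - 1) * d[1] + 1):(k * d[1])
    dX[, src[keep], ] <- dX[, src[keep], , drop = FALSE] +
      dO[rows, which(keep), , drop = FALSE]
  }
  dX
}

## ---- LSTM --------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# Wx: 4H x D, Wh: 4H x H, b: 4H. Gate row order: input, forget, output, cell.
lstm_fwd <- function(Wx, Wh, b, X) {
  d <- dim(X)
  H <- ncol(Wh)
  T_ <- d[2]; B <- d[3]
  I <- array(0, c(H, T_, B)); F_ <- I; O <- I; G <- I; C <- I; Hs <- I
  h <- matrix(0, H, B); c_ <- matrix(0, H, B)
  ri <- 1:H; rf <- H + ri; ro <- 2 * H + ri; rg <- 3 * H + ri
  for (t in seq_len(T_)) {
    z <- Wx %*% slice3(X, t) + Wh %*% h + b
    i <- sigmoid(z[ri, , drop = FALSE])
    f <- sigmoid(z[rf, , drop = FALSE])
    o <- sigmoid(z[ro, , drop = FALSE])
    g <- tanh(z[rg, , drop = FALSE])
    c_ <- f * c_ + i * g
    h <- o * tanh(c_)
    I[, t, ] <- i; F_[, t, ] <- f; O[, t, ] <- o; G[, t, ] <- g
    C[, t, ] <- c_; Hs[, t, ] <- h
  }
  list(out = Hs, I = I, F = F_, O = O, G = G, C = C, X = X, H = Hs)
}

lstm_bwd <- function(Wx, Wh, cache, dH) {
  X <- cache$X
  d <- dim(X)
  H <- dim(cache$I)[1]
  T_ <- d[2]; B <- d[3]
  dWx <- matrix(0, 4 * H, d[1]); dWh <- matrix(0, 4 * H, H)
  db <- numeric(4 * H)
  dX <- array(0, d)
  dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
  for (t in rev(seq_len(T_))) {
    i <- slice3(cache$I, t); f <- slice3(cache$F, t)
    o <- slice3(cache$O, t); g <- slice3(cache$G, t)
    c_ <- slice3(cache$C, t)
    c_prev <- if (t > 1) slice3(cache$C, t - 1) else matrix(0, H, B)
    h_prev <- if (t > 1) slice3(cache$H, t - 1) else matrix(0, H, B)
    dh <- slice3(dH, t) + dh_next
    tc <- tanh(c_)
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g
    df <- dc * c_prev
    dg <- dc * i
    dc_next <- dc * f
    dz <- rbind(di * i * (1 - i), df * f * (1 - f),
                do_ * o * (1 - o), dg * (1 - g^2))
    xt <- slice3(X, t)
    dWx <- dWx + tcrossprod(dz, xt)
    dWh <- dWh + tcrossprod(dz, h_prev)
    db <- db + rowSums(dz)
    dX[, t, ] <- crossprod(Wx, dz)
    dh_next <- crossprod(Wh, dz)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

rev_time <- function(A) A[, rev(seq_len(dim(A)[2])), , drop = FALSE]

## ---- parameter initialization and Adam ---------------------------------

init_mat <- function(nr, nc) {
  s <- 1 / sqrt(nc)
  matrix(runif(nr * nc, -s, s), nr, nc)
}
init_vec <- function(n, fan_in) {
  s <- 1 / sqrt(fan_in)
  runif(n, -s, s)
}
init_lstm <- function(D, H) {
  s <- 1 / sqrt(H)
  list(Wx = matrix(runif(4 * H * D, -s, s), 4 * H, D),
       Wh = matrix(runif(4 * H * H, -s, s), 4 * H, H),
       b = runif(4 * H, -s, s))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}
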