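# Internal numeric core: forward and backward passes for the layer vocabulary
# used by architecture plans (1-D convolution with dilation and same-padding,
# batch normalization, leaky ReLU, max pooling, residual shortcuts, global
# average pooling, LSTM/GRU stacks, dense layers with dropout, softmax).
# Activations are 3-D arrays with dim (batch, positions, channels).

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- 1-D convolution (same padding) ----------------------------------------

# im2col row-gather indices for one layer geometry; cached per layer because
# they only depend on (batch, positions, kernel, dilation)
conv_gather_idx <- function(nb, p, kernel, dilation) {
  span <- dilation * (kernel - 1L) + 1L
  # padded activations live in a (nb * pp, cin) matrix, position-major with
  # batch fastest; tap t of output position o reads padded position
  # o + (t - 1) * dilation
  idx <- integer(nb * p * kernel)
  off <- 0L
  for (t in seq_len(kernel)) {
    base <- (seq_len(p) + (t - 1L) * dilation - 1L) * nb
    idx[off + seq_len(nb * p)] <- rep(base, each = nb) + seq_len(nb)
    off <- off + nb * p
  }
  list(idx = idx, uids = sort(unique(idx)), span = span,
       pad_l = (span - 1L) %/% 2L)
}

# W: matrix (kernel * in_ch, filters), rows ordered tap-major with channels
# fastest; b: numeric (filters)
conv1d_forward <- function(A, W, b, kernel, dilation, idx_env = NULL,
                           key = NULL) {
  d <- dim(A); nb <- d[1]; p <- d[2]; cin <- d[3]
  if (kernel == 1L) {
    Am <- A; dim(Am) <- c(nb * p, cin)
    Y <- Am %*% W
    Y <- sweep(Y, 2L, b, `+`)
    dim(Y) <- c(nb, p, ncol(W))
    return(list(Y = Y, cache = list(M = Am, dims = d, kernel = 1L, gi = NULL)))
  }
  gi <- if (!is.null(idx_env) && !is.null(idx_env[[key]])) idx_env[[key]] else {
    g <- conv_gather_idx(nb, p, kernel, dilation)
    if (!is.null(idx_env)) idx_env[[key]] <- g
    g
  }
  pp <- p + gi$span - 1L
  Ap <- matrix(0, nb * pp, cin)
  Ap[gi$pad_l * nb + seq_len(nb * p), ] <- A
  M <- Ap[gi$idx, , drop = FALSE]
  dim(M) <- c(nb * p, kernel, cin)
  M <- aperm(M, c(1L, 3L, 2L))
  dim(M) <- c(nb * p, cin * kernel)
  Y <- M %*% W
  Y <- sweep(Y, 2L, b, `+`)
  dim(Y) <- c(nb, p, ncol(W))
  list(Y = Y, cache = list(M = M, dims = d, kernel = kernel, gi = gi))
}

conv1d_backward <- function(dY, W, cache) {
  d <- cache$dims; nb <- d[1]; p <- d[2]; cin <- d[3]
  f <- ncol(W)
  dim(dY) <- c(nb * p, f)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- dY %*% t(W)
  if (cache$kernel == 1L) {
    dim(dM) <- d
    return(list(dA = dM, dW = dW, db = db))
  }
  gi <- cache$gi
  dim(dM) <- c(nb * p, cin, cache$kernel)
  dM <- aperm(dM, c(1L, 3L, 2L))
  dim(dM) <- c(nb * p * cache$kernel, cin)
  agg <- rowsum(dM, gi$idx, reorder = TRUE)
  pp <- p + gi$span - 1L
  dAp <- matrix(0, nb * pp, cin)
  dAp[gi$uids, ] <- agg
  dA <- dAp[gi$pad_l * nb + seq_len(nb * p), , drop = FALSE]
  dim(dA) <- d
  list(dA = dA, dW = dW, db = db)
}

# --- batch normalization (per channel over batch x positions) ---------------

bn_forward <- function(A, gamma, beta, state, momentum, training, eps = 1e-5) {
  d <- dim(A); nb <- d[1]; p <- d[2]; ch <- d[3]
  X <- A; dim(X) <- c(nb * p, ch)
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v <- pmax(v, 0)
    # exponentially weighted running stats with bias correction
    state$r_mu <- momentum * state$r_mu + (1 - momentum) * mu
    state$r_var <- momentum * state$r_var + (1 - momentum) * v
    state$t <- state$t + 1L
  } else if (state$t > 0L) {
    corr <- 1 - momentum^state$t
    if (corr <= 0) corr <- 1
    mu <- state$r_mu / corr
    v <- pmax(state$r_var / corr, 0)
  } else {
    mu <- rep(0, ch)
    v <- rep(1, ch)
  }
  inv_sd <- 1 / sqrt(v + eps)
  Xh <- sweep(sweep(X, 2L, mu, `-`), 2L, inv_sd, `*`)
  Y <- sweep(sweep(Xh, 2L, gamma, `*`), 2L, beta, `+`)
  dim(Y) <- d
  list(Y = Y, cache = list(Xh = Xh, inv_sd = inv_sd, dims = d))
}

bn_backward <- function(dY, gamma, cache) {
  d <- cache$dims; n <- d[1] * d[2]; ch <- d[3]
  dim(dY) <- c(n, ch)
  Xh <- cache$Xh
  dgamma <- colSums(dY * Xh)
  dbeta <- colSums(dY)
  dXh <- sweep(dY, 2L, gamma, `*`)
  # dX = inv_sd/n * (n*dXh - sum(dXh) - Xh * sum(dXh*Xh))
  s1 <- colSums(dXh)
  s2 <- colSums(dXh * Xh)
  dX <- sweep(dXh, 2L, s1 / n, `-`) - sweep(Xh, 2L, s2 / n, `*`)
  dX <- sweep(dX, 2L, cache$inv_sd, `*`)
  dim(dX) <- d
  list(dA = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- activations ------------------------------------------------------------

leaky_relu_forward <- function(A, alpha) {
  Y <- ifelse(A > 0, A, alpha * A)
  list(Y = Y, cache = A > 0)
}

leaky_relu_backward <- function(dY, alpha, cache) {
  dY * ifelse(cache, 1, alpha)
}

# --- max pooling (size = stride = s) ----------------------------------------

maxpool_forward <- function(A, s) {
  if (s == 1L) return(list(Y = A, cache = NULL))
  d <- dim(A); nb <- d[1]; p <- d[2]; ch <- d[3]
  p_out <- p %/% s
  best <- A[, seq(1L, p_out * s, by = s), , drop = FALSE]
  bestj <- array(1L, dim(best))
  if (s > 1L) {
    for (j in 2:s) {
      Sj <- A[, seq(j, p_out * s, by = s), , drop = FALSE]
      upd <- Sj > best
      best[upd] <- Sj[upd]
      bestj[upd] <- j
    }
  }
  list(Y = best, cache = list(bestj = bestj, dims = d, s = s, p_out = p_out))
}

maxpool_backward <- function(dY, cache) {
  if (is.null(cache)) return(dY)
  d <- cache$dims; s <- cache$s; p_out <- cache$p_out
  dA <- array(0, d)
  for (j in seq_len(s)) {
    tmp <- array(0, dim(dY))
    mask <- cache$bestj == j
    tmp[mask] <- dY[mask]
    dA[, seq(j, p_out * s, by = s), ] <- tmp
  }
  dA
}

# --- global average pooling -------------------------------------------------

gap_forward <- function(A) {
  d <- dim(A)
  M <- aperm(A, c(2, 1, 3))
  dim(M) <- c(d[2], d[1] * d[3])
  Y <- colMeans(M)
  dim(Y) <- c(d[1], d[3])
  list(Y = Y, cache = d)
}

gap_backward <- function(dY, cache) {
  d <- cache
  dA <- array(0, d)
  for (pp in seq_len(d[2])) dA[, pp, ] <- dY / d[2]
  dA
}

# --- dense ------------------------------------------------------------------

dense_forward <- function(X, W, b, activation = "linear") {
  Z <- sweep(X %*% W, 2L, b, `+`)
  Y <- switch(activation,
    linear = Z,
    relu = pmax(Z, 0),
    tanh = tanh(Z),
    sigmoid = sigmoid(Z))
  list(Y = Y, cache = list(X = X, Y = Y, Z = Z, activation = activation))
}

dense_backward <- function(dY, W, cache) {
  dZ <- switch(cache$activation,
    linear = dY,
    relu = dY * (cache$Z > 0),
    tanh = dY * (1 - cache$Y^2),
    sigmoid = dY * cache$Y * (1 - cache$Y))
  list(dX = dZ %*% t(W), dW = crossprod(cache$X, dZ), db = colSums(dZ))
}

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, cache = NULL))
  keep <- 1 - rate
  mask <- matrix(stats::runif(length(X)) < keep, nrow(X), ncol(X)) / keep
  list(Y = X * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# --- recurrent layers (per-position outputs) --------------------------------

# params: Wx (cin, g*U), Wh (U, g*U), b (g*U); g = 4 (lstm) or 3 (gru)
lstm_forward <- function(X, Wx, Wh, b) {
  d <- dim(X); nb <- d[1]; p <- d[2]
  U <- nrow(Wh)
  H_all <- array(0, c(nb, p, U))
  h <- matrix(0, nb, U); cc <- matrix(0, nb, U)
  steps <- vector("list", p)
  for (t in seq_len(p)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(nb, d[3])
    Z <- sweep(xt %*% Wx + h %*% Wh, 2L, b, `+`)
    i <- sigmoid(Z[, 1:U, drop = FALSE])
    f <- sigmoid(Z[, (U + 1):(2 * U), drop = FALSE])
    g <- tanh(Z[, (2 * U + 1):(3 * U), drop = FALSE])
    o <- sigmoid(Z[, (3 * U + 1):(4 * U), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i, f = f, g = g,
                       o = o, tc = tc)
    h <- h_new; cc <- c_new
    H_all[, t, ] <- h
  }
  list(Y = H_all, cache = list(steps = steps, dims = d, U = U))
}

lstm_backward <- function(dH_all, Wx, Wh, cache) {
  d <- cache$dims; nb <- d[1]; p <- d[2]; cin <- d[3]; U <- cache$U
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(ncol(Wx))
  dX <- array(0, d)
  dh_next <- matrix(0, nb, U); dc_next <- matrix(0, nb, U)
  for (t in rev(seq_len(p))) {
    st <- cache$steps[[t]]
    dh <- dH_all[, t, , drop = FALSE]; dim(dh) <- c(nb, U)
    dh <- dh + dh_next
    do_ <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$xt, dZ)
    dWh <- dWh + crossprod(st$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(Wx)
    dh_next <- dZ %*% t(Wh)
    dc_next <- dc * st$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

gru_forward <- function(X, Wx, Wh, b) {
  d <- dim(X); nb <- d[1]; p <- d[2]
  U <- nrow(Wh)
  H_all <- array(0, c(nb, p, U))
  h <- matrix(0, nb, U)
  steps <- vector("list", p)
  ir <- 1:U; iz <- (U + 1):(2 * U); inn <- (2 * U + 1):(3 * U)
  for (t in seq_len(p)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(nb, d[3])
    Zx <- sweep(xt %*% Wx, 2L, b, `+`)
    Zh <- h %*% Wh
    r <- sigmoid(Zx[, ir, drop = FALSE] + Zh[, ir, drop = FALSE])
    z <- sigmoid(Zx[, iz, drop = FALSE] + Zh[, iz, drop = FALSE])
    u <- Zh[, inn, drop = FALSE]
    n <- tanh(Zx[, inn, drop = FALSE] + r * u)
    h_new <- (1 - z) * n + z * h
    steps[[t]] <- list(xt = xt, h_prev = h, r = r, z = z, n = n, u = u)
    h <- h_new
    H_all[, t, ] <- h
  }
  list(Y = H_all, cache = list(steps = steps, dims = d, U = U))
}

gru_backward <- function(dH_all, Wx, Wh, cache) {
  d <- cache$dims; nb <- d[1]; p <- d[2]; U <- cache$U
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(ncol(Wx))
  dX <- array(0, d)
  dh_next <- matrix(0, nb, U)
  ir <- 1:U; iz <- (U + 1):(2 * U); inn <- (2 * U + 1):(3 * U)
  for (t in rev(seq_len(p))) {
    st <- cache$steps[[t]]
    dh <- dH_all[, t, , drop = FALSE]; dim(dh) <- c(nb, U)
    dh <- dh + dh_next
    dz <- dh * (st$h_prev - st$n)
    dn <- dh * (1 - st$z)
    dh_prev <- dh * st$z
    dn_pre <- dn * (1 - st$n^2)
    dr <- dn_pre * st$u
    du <- dn_pre * st$r
    dr_pre <- dr * st$r * (1 - st$r)
    dz_pre <- dz * st$z * (1 - st$z)
    dZx <- cbind(dr_pre, dz_pre, dn_pre)
    # h-path: r and z gates see h Wh directly; n gate sees r * (h Wh_n)
    dZh <- cbind(dr_pre, dz_pre, du)
    dWx <- dWx + crossprod(st$xt, dZx)
    dWh <- dWh + crossprod(st$h_prev, dZh)
    db <- db + colSums(dZx)
    dX[, t, ] <- dZx %*% t(Wx)
    dh_prev <- dh_prev + dZh %*% t(Wh)
    dh_next <- dh_prev
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# --- softmax cross-entropy --------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# labels: integer vector in 1..n_classes
softmax_xent <- function(logits, labels) {
  P <- softmax_rows(logits)
  nb <- nrow(P)
  idx <- cbind(seq_len(nb), labels)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(P = P, loss = loss, dlogits = dZ / nb)
}

# --- initializers -----------------------------------------------------------

glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}
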