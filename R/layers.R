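# Neural-network primitives for the multi-stream gesture classifier.
#
# Batched signals are stored as 3-D arrays [B, T, C] (batch, time frames,
# feature channels). Flattening an array X[B,T,C] with matrix(X, B*T, C)
# gives a (batch,time)-row by channel-column matrix in column-major order;
# every layer below relies on that layout so all heavy lifting is BLAS
# matrix multiplication. Each `*_forward` returns the output plus the cache
# its `*_backward` needs; backward returns the input gradient and parameter
# gradients with the same shapes as the parameters.

bt_mat <- function(X) {
  d <- dim(X)
  matrix(X, d[1] * d[2], d[3])
}

bt_arr <- function(M, B, T) {
  array(M, c(B, T, ncol(M)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- parameter initialisation ------------------------------------------

# He-style fan-in scaling; all randomness flows through R's global RNG so a
# set.seed() before model construction fixes every weight.
init_mat <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

conv1d_init <- function(cin, cout, k) {
  list(W = init_mat(k * cin, cout), b = numeric(cout), k = k,
       cin = cin, cout = cout)
}

## ---- 1-D convolution (same padding, odd kernel) ------------------------

conv1d_cols <- function(X, k) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  p <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, T + 2L * p, C))
  Xp[, (p + 1L):(p + T), ] <- X
  cols <- matrix(0, B * T, k * C)
  for (tap in seq_len(k))
    for (c in seq_len(C))
      cols[, (tap - 1L) * C + c] <- Xp[, tap:(tap + T - 1L), c]
  cols
}

conv1d_forward <- function(X, par, stride = 1L) {
  d <- dim(X); B <- d[1]; T <- d[2]
  cols <- conv1d_cols(X, par$k)
  Y <- sweep(cols %*% par$W, 2, par$b, `+`)
  Y <- bt_arr(Y, B, T)
  if (stride > 1L) Y <- Y[, seq.int(1L, T, by = stride), , drop = FALSE]
  list(out = Y, cache = list(cols = cols, dims = d, stride = stride, par = par))
}

conv1d_backward <- function(dY, cache) {
  d <- cache$dims; B <- d[1]; T <- d[2]; C <- d[3]
  par <- cache$par; k <- par$k; p <- (k - 1L) %/% 2L
  if (cache$stride > 1L) {
    full <- array(0, c(B, T, par$cout))
    full[, seq.int(1L, T, by = cache$stride), ] <- dY
    dY <- full
  }
  dYm <- bt_mat(dY)
  dW <- crossprod(cache$cols, dYm)
  db <- colSums(dYm)
  dcols <- tcrossprod(dYm, par$W)      # [B*T, k*C]
  dXp <- array(0, c(B, T + 2L * p, C))
  for (tap in seq_len(k))
    for (c in seq_len(C))
      dXp[, tap:(tap + T - 1L), c] <-
        dXp[, tap:(tap + T - 1L), c] + matrix(dcols[, (tap - 1L) * C + c], B, T)
  list(dX = dXp[, (p + 1L):(p + T), , drop = FALSE],
       grads = list(W = dW, b = db))
}

## ---- batch normalisation over (batch, time) per channel ----------------

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

bn_forward <- function(X, par, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(X); B <- d[1]; T <- d[2]
  M <- bt_mat(X)
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(sweep(M, 2, mu)^2)
    par$run_mean <- (1 - momentum) * par$run_mean + momentum * mu
    par$run_var <- (1 - momentum) * par$run_var + momentum * v
  } else {
    mu <- par$run_mean
    v <- par$run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(M, 2, mu), 2, inv, `*`)
  Y <- sweep(sweep(xhat, 2, par$gamma, `*`), 2, par$beta, `+`)
  list(out = bt_arr(Y, B, T), par = par,
       cache = list(xhat = xhat, inv = inv, dims = d, par = par,
                    training = training))
}

bn_backward <- function(dY, cache) {
  d <- cache$dims; B <- d[1]; T <- d[2]
  n <- B * T
  dYm <- bt_mat(dY)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  if (cache$training) {
    dxhat <- sweep(dYm, 2, cache$par$gamma, `*`)
    dX <- sweep(
      dxhat -
        matrix(colMeans(dxhat), n, length(dbeta), byrow = TRUE) -
        cache$xhat * matrix(colMeans(dxhat * cache$xhat), n, length(dbeta),
                            byrow = TRUE),
      2, cache$inv, `*`)
  } else {
    dX <- sweep(dYm, 2, cache$par$gamma * cache$inv, `*`)
  }
  list(dX = bt_arr(dX, B, T), grads = list(gamma = dgamma, beta = dbeta))
}

## ---- rectifier ----------------------------------------------------------

relu_forward <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_backward <- function(dY, cache) dY * cache

## ---- gated recurrent unit ----------------------------------------------

# Gate order in the fused matrices: [update z | reset r | candidate n].
#   z_t = s(x W_z + h U_z + b_z)
#   r_t = s(x W_r + h U_r + b_r)
#   n_t = tanh(x W_n + b_n + r_t * (h U_n + b_hn))
#   h_t = (1 - z_t) * n_t + z_t * h_{t-1}
gru_init <- function(cin, H) {
  list(W = init_mat(cin, 3L * H, fan_in = cin),
       U = init_mat(H, 3L * H, fan_in = H),
       b = numeric(3L * H), bhn = numeric(H), H = H)
}

gru_forward <- function(X, par) {
  d <- dim(X); B <- d[1]; T <- d[2]
  H <- par$H
  iz <- 1:H; ir <- (H + 1):(2 * H); in_ <- (2 * H + 1):(3 * H)
  h <- matrix(0, B, H)
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], B)
    gx <- xt %*% par$W
    gh <- h %*% par$U
    z <- sigmoid(sweep(gx[, iz, drop = FALSE] + gh[, iz, drop = FALSE], 2, par$b[iz], `+`))
    r <- sigmoid(sweep(gx[, ir, drop = FALSE] + gh[, ir, drop = FALSE], 2, par$b[ir], `+`))
    hn <- sweep(gh[, in_, drop = FALSE], 2, par$bhn, `+`)
    n <- tanh(sweep(gx[, in_, drop = FALSE] + r * hn, 2, par$b[in_], `+`))
    h_new <- (1 - z) * n + z * h
    steps[[t]] <- list(xt = xt, h_prev = h, z = z, r = r, n = n, hn = hn)
    h <- h_new
  }
  list(out = h, cache = list(steps = steps, par = par, dims = d))
}

gru_backward <- function(dh, cache) {
  par <- cache$par; H <- par$H
  d <- cache$dims; B <- d[1]; T <- d[2]; C <- d[3]
  iz <- 1:H; ir <- (H + 1):(2 * H); in_ <- (2 * H + 1):(3 * H)
  dW <- matrix(0, nrow(par$W), ncol(par$W))
  dU <- matrix(0, nrow(par$U), ncol(par$U))
  db <- numeric(3 * H); dbhn <- numeric(H)
  dX <- array(0, c(B, T, C))
  for (t in rev(seq_len(T))) {
    st <- cache$steps[[t]]
    dz <- dh * (st$h_prev - st$n) * st$z * (1 - st$z)
    dn <- dh * (1 - st$z) * (1 - st$n^2)
    dr <- dn * st$hn * st$r * (1 - st$r)
    dg <- cbind(dz, dr, dn)                        # grads at pre-activations
    dxt <- tcrossprod(dg, par$W)
    dW <- dW + crossprod(st$xt, dg)
    db <- db + colSums(dg)
    # h-side: z and r gates see h U directly; n gate sees r * (h U_n + bhn)
    dgh <- cbind(dz, dr, dn * st$r)
    dU <- dU + crossprod(st$h_prev, dgh)
    dbhn <- dbhn + colSums(dn * st$r)
    dh <- dh * st$z + tcrossprod(dgh, par$U)
    dX[, t, ] <- dxt
  }
  list(dX = dX, grads = list(W = dW, U = dU, b = db, bhn = dbhn))
}

## ---- dense layer, dropout, softmax cross-entropy ------------------------

dense_init <- function(cin, cout) {
  list(W = init_mat(cin, cout, fan_in = cin), b = numeric(cout))
}

dense_forward <- function(X, par) {
  list(out = sweep(X %*% par$W, 2, par$b, `+`), cache = list(X = X, par = par))
}

dense_backward <- function(dY, cache) {
  list(dX = tcrossprod(dY, cache$par$W),
       grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X)) / (1 - p)
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

#' Softmax class probabilities
#'
#' Converts a pre-softmax label vector `g` (or a row-wise batch of them)
#' into class probabilities `p(m|g) = exp(g_m) / sum_j exp(g_j)`, computed
#' with the max-shift trick so it is invariant to adding a constant.
#'
#' @param g numeric vector of length M, or an N x M matrix of logits.
#' @return probabilities with the same shape; rows sum to 1.
#' @export
softmax_probs <- function(g) {
  if (is.matrix(g)) {
    e <- exp(g - apply(g, 1, max))
    e / rowSums(e)
  } else {
    e <- exp(g - max(g))
    e / sum(e)
  }
}

#' Classification decision
#'
#' `m0 = argmax_m p(m|g)` with the lowest class index winning ties.
#'
#' @param p probability vector or N x M matrix from [softmax_probs()].
#' @return integer class index (or vector of them).
#' @export
decide_class <- function(p) {
  if (is.matrix(p)) max.col(p, ties.method = "first") else which.max(p)
}

softmax_xent <- function(logits, y) {
  p <- softmax_probs(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n, p = p)
}

## ---- Adam on a nested parameter tree ------------------------------------

tree_zeros <- function(tree) {
  rapply(tree, function(x) if (is.numeric(x)) x * 0 else x, how = "replace")
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.numeric(p) && !is.null(g)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^state$t)
      vh <- v / (1 - beta2^state$t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    } else if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(t = state$t, m = r$m, v = r$v))
}
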