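# One-dimensional convolutional block attention.
#
# A feature map F in R^{T x C} (T time frames, C feature channels) is
# re-weighted in two sequential steps:
#   channel attention  M_C in (0,1)^{1 x C}: time-pooled (average & max)
#     channel descriptors pass through a shared bottleneck perceptron
#     (C -> C/r -> C, rectifier in the middle) and are summed before a
#     sigmoid;
#   temporal attention M_T in (0,1)^{T x 1}: channel-pooled (average & max)
#     frame descriptors are stacked as two channels and convolved with a
#     length-3 kernel (zero-padded to length T) before a sigmoid.
# The module output is F'' = M_T (x) (M_C (x) F), channel first.

#' Parameters for the feature-channel attention perceptron
#'
#' The shared two-layer perceptron has a bottleneck of size `C/r` where `r`
#' is the compression rate; `C` must be divisible by `r`. Weights are drawn
#' from the current RNG state; biases are disabled by default.
#'
#' @param C number of feature channels.
#' @param r compression rate (default 8).
#' @param bias include bias vectors in both layers?
#' @return list with `W0` (C x C/r), `W1` (C/r x C), optional `b0`, `b1`,
#'   and `r`.
#' @export
channel_attention_params <- function(C, r = 8, bias = FALSE) {
  if (C %% r != 0)
    stop(sprintf("channel count C = %d must be divisible by the compression rate r = %d",
                 C, r))
  p <- list(W0 = init_mat(C, C %/% r, fan_in = C),
            W1 = init_mat(C %/% r, C, fan_in = C %/% r), r = r)
  if (bias) {
    p$b0 <- numeric(C %/% r)
    p$b1 <- numeric(C)
  }
  p
}

#' Parameters for the temporal attention convolution
#'
#' A length-3 one-dimensional kernel over the 2 stacked pooled channels
#' (average; max) producing 1 output channel, plus a bias.
#'
#' @return list with `conv` (a 2-in/1-out kernel-3 conv parameter set).
#' @export
temporal_attention_params <- function() {
  list(conv = conv1d_init(2L, 1L, 3L))
}

cbam_init <- function(C, r = 8, bias = FALSE) {
  list(ch = channel_attention_params(C, r, bias),
       tmp = temporal_attention_params())
}

# pooled descriptors + argmax bookkeeping --------------------------------

pool_over_time <- function(X) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  avg <- colMeans(aperm(X, c(2, 1, 3)))              # [B, C]
  mx <- matrix(-Inf, B, C); arg <- matrix(1L, B, C)
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], B)
    upd <- xt > mx
    mx[upd] <- xt[upd]
    arg[upd] <- t
  }
  list(avg = avg, max = mx, arg = arg)
}

pool_over_channels <- function(X) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  M <- bt_mat(X)                                     # [B*T, C]
  arg <- max.col(M, ties.method = "first")
  list(avg = matrix(rowMeans(M), B, T),
       max = matrix(M[cbind(seq_len(B * T), arg)], B, T),
       arg = matrix(arg, B, T))
}

mlp2 <- function(V, p) {
  # V: [B, C] -> [B, C]; cache for backward
  A <- V %*% p$W0
  if (!is.null(p$b0)) A <- sweep(A, 2, p$b0, `+`)
  H <- pmax(A, 0)
  O <- H %*% p$W1
  if (!is.null(p$b1)) O <- sweep(O, 2, p$b1, `+`)
  list(out = O, cache = list(V = V, H = H, mask = A > 0))
}

mlp2_backward <- function(dO, cache, p) {
  dH <- tcrossprod(dO, p$W1) * cache$mask
  g <- list(W0 = crossprod(cache$V, dH), W1 = crossprod(cache$H, dO))
  if (!is.null(p$b0)) g$b0 <- colSums(dH)
  if (!is.null(p$b1)) g$b1 <- colSums(dO)
  list(dV = tcrossprod(dH, p$W0), grads = g)
}

cbam_channel_forward <- function(X, p) {
  pool <- pool_over_time(X)
  ma <- mlp2(pool$avg, p)
  mm <- mlp2(pool$max, p)
  MC <- sigmoid(ma$out + mm$out)                     # [B, C]
  list(MC = MC, cache = list(pool = pool, ma = ma, mm = mm, p = p))
}

cbam_temporal_forward <- function(X, p) {
  pool <- pool_over_channels(X)
  d <- dim(X); B <- d[1]; T <- d[2]
  S <- array(0, c(B, T, 2L))
  S[, , 1] <- pool$avg
  S[, , 2] <- pool$max
  cv <- conv1d_forward(S, p$conv)
  MT <- sigmoid(matrix(cv$out[, , 1], B, T))         # [B, T]
  list(MT = MT, cache = list(pool = pool, cv = cv, dims = d))
}

mult_bc <- function(X, MC) {                          # X[b,t,c] * MC[b,c]
  out <- X
  for (c in seq_len(dim(X)[3])) out[, , c] <- X[, , c] * MC[, c]
  out
}

mult_bt <- function(X, MT) {                          # X[b,t,c] * MT[b,t]
  X * as.vector(MT)                                   # recycles over c
}

cbam_forward <- function(X, par) {
  ch <- cbam_channel_forward(X, par$ch)
  Fp <- mult_bc(X, ch$MC)
  tm <- cbam_temporal_forward(Fp, par$tmp)
  Fpp <- mult_bt(Fp, tm$MT)
  list(out = Fpp,
       cache = list(X = X, ch = ch, tm = tm, Fp = Fp, par = par),
       MC = ch$MC, MT = tm$MT)
}

cbam_backward <- function(dFpp, cache) {
  X <- cache$X; par <- cache$par
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  MT <- cache$tm$MT; MC <- cache$ch$MC; Fp <- cache$Fp
  # F'' = F' * MT
  dMT <- matrix(0, B, T)
  for (c in seq_len(C)) dMT <- dMT + dFpp[, , c] * Fp[, , c]
  dFp <- mult_bt(dFpp, MT)
  # temporal attention path
  dlog <- dMT * MT * (1 - MT)
  dcv <- conv1d_backward(array(dlog, c(B, T, 1L)), cache$tm$cache$cv$cache)
  dS <- dcv$dX
  pool <- cache$tm$cache$pool
  dFp_pool <- array(rep(as.vector(dS[, , 1]) / C, C), c(B, T, C))
  dmaxM <- matrix(0, B * T, C)
  dmaxM[cbind(seq_len(B * T), as.vector(pool$arg))] <- as.vector(dS[, , 2])
  dFp <- dFp + dFp_pool + array(dmaxM, c(B, T, C))
  # F' = X * MC
  dMC <- matrix(0, B, C)
  for (c in seq_len(C)) dMC[, c] <- rowSums(matrix(dFp[, , c] * X[, , c], B))
  dX <- mult_bc(dFp, MC)
  # channel attention path
  chc <- cache$ch$cache
  dsum <- dMC * MC * (1 - MC)
  ba <- mlp2_backward(dsum, chc$ma$cache, par$ch)
  bm <- mlp2_backward(dsum, chc$mm$cache, par$ch)
  gch <- mapply(`+`, ba$grads, bm$grads, SIMPLIFY = FALSE)
  # avg pool: spread over T; max pool: route to argmax frame
  for (c in seq_len(C)) {
    dX[, , c] <- dX[, , c] + ba$dV[, c] / T
    sel <- cbind(seq_len(B), chc$pool$arg[, c], c)
    dX[sel] <- dX[sel] + bm$dV[, c]
  }
  list(dX = dX, grads = list(ch = gch, tmp = list(conv = dcv$grads)))
}

## ---- user-facing single-map operations ----------------------------------

as_batch1 <- function(F) {
  stopifnot(is.matrix(F), all(is.finite(F)))
  array(F, c(1L, nrow(F), ncol(F)))
}

#' Feature-channel attention map
#'
#' Computes `M_C = sigmoid(MLP(avgpool_T(F)) + MLP(maxpool_T(F)))` for a
#' single feature map, with the shared bottleneck perceptron.
#'
#' @param F numeric matrix `T x C`.
#' @param params from [channel_attention_params()]; `C` must be divisible
#'   by `params$r`.
#' @return numeric vector of length C, values strictly in (0, 1).
#' @export
channel_attention <- function(F, params) {
  if (ncol(F) %% params$r != 0)
    stop("C must be divisible by the compression rate r")
  as.numeric(cbam_channel_forward(as_batch1(F), params)$MC)
}

#' Temporal attention map
#'
#' Computes `M_T = sigmoid(conv3([avgpool_C(F); maxpool_C(F)]))` for a
#' single feature map; the two pooled frame descriptors are stacked in the
#' order (average, max) and convolved with the length-3 kernel under
#' same-length zero padding.
#'
#' @param F numeric matrix `T x C`.
#' @param params from [temporal_attention_params()].
#' @return numeric vector of length T, values strictly in (0, 1).
#' @export
temporal_attention <- function(F, params) {
  as.numeric(cbam_temporal_forward(as_batch1(F), params)$MT)
}

#' Apply the full 1-D convolutional block attention module
#'
#' Sequential composition, channel attention first:
#' `F' = M_C (x) F`, then `F'' = M_T(F') (x) F'`, where `(x)` is the
#' broadcast elementwise product. Since both maps lie in (0, 1), the module
#' only ever attenuates: `|F''| <= |F|` elementwise.
#'
#' @param F numeric matrix `T x C`.
#' @param cp channel-attention parameters ([channel_attention_params()]).
#' @param tp temporal-attention parameters ([temporal_attention_params()]).
#' @return list with `MC` (length C), `MT` (length T), `F_prime`,
#'   `F_doubleprime` (both `T x C`).
#' @export
apply_cbam <- function(F, cp, tp) {
  res <- cbam_forward(as_batch1(F), list(ch = cp, tmp = tp))
  list(MC = as.numeric(res$MC), MT = as.numeric(res$MT),
       F_prime = matrix(res$cache$Fp[1, , ], nrow(F), ncol(F)),
       F_doubleprime = matrix(res$out[1, , ], nrow(F), ncol(F)))
}

#' Parameters added by one CBAM block
#'
#' Closed form: `2 C^2 / r` perceptron weights (plus `C/r + C` biases when
#' enabled) and `2 * 3 + 1 = 7` for the temporal convolution.
#'
#' @param C feature channels; @param r compression rate; @param bias
#'   whether perceptron biases are enabled.
#' @return integer parameter count.
#' @export
cbam_param_count <- function(C, r = 8, bias = FALSE) {
  as.integer(2 * C^2 %/% r + (if (bias) C %/% r + C else 0L) + 7L)
}
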