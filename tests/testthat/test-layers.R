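# The classifier is trained with hand-written backpropagation, so the
# gradients themselves are a contract: every layer's analytic gradient is
# checked against central finite differences through the full model.

num_grad_check <- function(model, x, y, get, set, ganal, n_probe = 4,
                           eps = 1e-5) {
  loss_of <- function(m) {
    fw <- forward_model(m, x, training = TRUE, return_cache = TRUE)
    softmax_xent(fw$logits, y)$loss
  }
  p0 <- get(model)
  idx <- sample(length(p0), min(n_probe, length(p0)))
  vapply(idx, function(j) {
    mp <- model; p <- get(mp); p[j] <- p[j] + eps; mp <- set(mp, p)
    mm <- model; p <- get(mm); p[j] <- p[j] - eps; mm <- set(mm, p)
    num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
    abs(num - ganal[j]) / max(1e-8, abs(num) + abs(ganal[j]))
  }, numeric(1))
}

test_that("analytic gradients match finite differences through every layer", {
  cfg <- model_config(n_semg_streams = 2, use_acc = TRUE,
                      conv_blocks = list(c(8, 3, 1), c(8, 3, 1)),
                      cbam_r = 4, gru_hidden = 5, fc_hidden = 6,
                      dropout_p = 0, n_classes = 3, seed = 3)
  m <- build_model(cfg)
  set.seed(9)
  B <- 4; T <- 12
  x <- list(array(rnorm(B * T), c(B, T, 1)),
            array(rnorm(B * T), c(B, T, 1)),
            array(rnorm(B * T * 3), c(B, T, 3)))
  y <- c(1, 2, 3, 1)
  fw <- forward_model(m, x, training = TRUE, return_cache = TRUE)
  sx <- softmax_xent(fw$logits, y)
  gr <- backward_model(fw$model, sx$dlogits, fw$cache)
  set.seed(11)
  paths <- list(
    conv_W = list(function(m) m$streams[[1]]$blocks[[1]]$conv$W,
                  function(m, p) { m$streams[[1]]$blocks[[1]]$conv$W[] <- p; m },
                  gr$streams[[1]]$blocks[[1]]$conv$W),
    bn_gamma = list(function(m) m$streams[[1]]$blocks[[2]]$bn$gamma,
                    function(m, p) { m$streams[[1]]$blocks[[2]]$bn$gamma[] <- p; m },
                    gr$streams[[1]]$blocks[[2]]$bn$gamma),
    cbam_W0 = list(function(m) m$streams[[2]]$cbam$ch$W0,
                   function(m, p) { m$streams[[2]]$cbam$ch$W0[] <- p; m },
                   gr$streams[[2]]$cbam$ch$W0),
    cbam_tconv = list(function(m) m$streams[[2]]$cbam$tmp$conv$W,
                      function(m, p) { m$streams[[2]]$cbam$tmp$conv$W[] <- p; m },
                      gr$streams[[2]]$cbam$tmp$conv$W),
    gru_W = list(function(m) m$streams[[3]]$gru$W,
                 function(m, p) { m$streams[[3]]$gru$W[] <- p; m },
                 gr$streams[[3]]$gru$W),
    gru_U = list(function(m) m$streams[[3]]$gru$U,
                 function(m, p) { m$streams[[3]]$gru$U[] <- p; m },
                 gr$streams[[3]]$gru$U),
    fc1_W = list(function(m) m$head$fc1$W,
                 function(m, p) { m$head$fc1$W[] <- p; m },
                 gr$head$fc1$W))
  for (nm in names(paths)) {
    p <- paths[[nm]]
    errs <- num_grad_check(m, x, y, p[[1]], p[[2]], p[[3]])
    expect_lt(max(errs), 1e-5)
  }
})

test_that("1-D convolution matches a direct sliding-window computation", {
  set.seed(5)
  B <- 2; T <- 9; Cin <- 3; Cout <- 2; k <- 3
  X <- array(rnorm(B * T * Cin), c(B, T, Cin))
  par <- semgnet:::conv1d_init(Cin, Cout, k)
  Y <- semgnet:::conv1d_forward(X, par)$out
  # weight rows are ordered tap-major, then input channel
  for (b in 1:B) for (t in 1:T) for (o in 1:Cout) {
    acc <- par$b[o]
    for (tap in 1:k) {
      src <- t + tap - 1 - (k - 1) / 2
      if (src >= 1 && src <= T)
        for (c in 1:Cin) acc <- acc + X[b, src, c] * par$W[(tap - 1) * Cin + c, o]
    }
    expect_equal(Y[b, t, o], acc, tolerance = 1e-12)
  }
})

test_that("batch normalization standardizes per channel in training mode", {
  set.seed(6)
  X <- array(rnorm(4 * 10 * 3, mean = 5, sd = 3), c(4, 10, 3))
  par <- semgnet:::bn_init(3)
  out <- semgnet:::bn_forward(X, par, training = TRUE)
  M <- matrix(out$out, 40, 3)
  expect_equal(colMeans(M), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(M, 2, sd) * sqrt(39 / 40), rep(1, 3), tolerance = 1e-3)
  # eval mode uses running statistics, not batch statistics
  out2 <- semgnet:::bn_forward(X, out$par, training = FALSE)
  expect_false(isTRUE(all.equal(out2$out, out$out)))
})

test_that("GRU last hidden state is deterministic and shape-correct", {
  set.seed(7)
  par <- semgnet:::gru_init(4, 6)
  X <- array(rnorm(3 * 11 * 4), c(3, 11, 4))
  h1 <- semgnet:::gru_forward(X, par)$out
  h2 <- semgnet:::gru_forward(X, par)$out
  expect_identical(h1, h2)
  expect_identical(dim(h1), c(3L, 6L))
  expect_true(all(abs(h1) < 1))            # gated tanh output stays bounded
})
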