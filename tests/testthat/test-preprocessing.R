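test_that("notch design nulls the power line and spares the signal band", {
  fn <- design_notch(notch_spec(omega0 = 50, q = 30, fs = 1000))
  grid <- seq(0, 500, by = 0.1)
  mag <- filter_magnitude(fn, grid)
  expect_equal(grid[which.min(mag)], 50)
  expect_lt(abs(filter_magnitude(fn, 0) - 1), 0.01)   # DC passband
  # seeded 50 Hz tone loses >= 99% power, a 150 Hz tone < 5%
  fs <- 1000; t <- (0:2047) / fs
  x50 <- sin(2 * pi * 50 * t); x150 <- sin(2 * pi * 150 * t)
  rec <- recording(cbind(x50, x150), fs = fs)
  out <- apply_filters(rec, notch = notch_spec(fs = fs), hp = NULL)
  keep <- 513:2048                                   # skip the IIR transient
  p50 <- tone_power(out$semg[keep, 1], fs, 50) / tone_power(x50[keep], fs, 50)
  p150 <- tone_power(out$semg[keep, 2], fs, 150) / tone_power(x150[keep], fs, 150)
  expect_lt(p50, 0.01)
  expect_gt(p150, 0.95)
  expect_error(design_notch(notch_spec(omega0 = 600, fs = 1000)), "fs/2")
})

test_that("high-pass magnitude matches the analytic Butterworth form", {
  spec <- butterworth_spec(order_n = 3, cutoff_hz = 20, epsilon = 1, fs = 1000)
  hp <- design_highpass(spec)
  grid <- seq(1, 400, by = 0.25)
  rel <- abs(filter_magnitude(hp, grid) - butterworth_magnitude(spec, grid)) /
    butterworth_magnitude(spec, grid)
  expect_lt(max(rel), 0.01)
  # cutoff gain forced to 1/sqrt(1+eps^2) = -3.01 dB
  expect_equal(20 * log10(filter_magnitude(hp, 20)), -3.0103, tolerance = 1e-3)
  expect_equal(filter_magnitude(hp, 0), 0)
  # deep-stopband slope: 6N = 18 dB per octave
  slope <- 20 * log10(filter_magnitude(hp, 4) / filter_magnitude(hp, 2))
  expect_lt(abs(slope - 18), 0.5)
  # epsilon shifts the passband edge as the closed form dictates
  s2 <- butterworth_spec(epsilon = 0.5)
  expect_equal(filter_magnitude(design_highpass(s2), 20),
               1 / sqrt(1.25), tolerance = 1e-3)
})

test_that("filtering is linear and leaves ACC untouched", {
  fs <- 1000; n <- 1024
  set.seed(1)
  x <- rnorm(n); y <- rnorm(n); acc <- matrix(rnorm(n * 3), n, 3)
  f <- function(v) apply_filters(recording(matrix(v), acc = acc, fs = fs))$semg[, 1]
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-8)
  expect_equal(f(numeric(n)), numeric(n))
  out <- apply_filters(recording(matrix(x), acc = acc, fs = fs))
  expect_identical(out$acc, acc)
  expect_identical(nrow(out$semg), as.integer(n))
  # constant (DC) channel is annihilated once the (high-Q notch) transient
  # has rung down
  dc <- apply_filters(recording(matrix(5, n, 1), fs = fs))$semg[, 1]
  expect_lt(max(abs(dc[897:n])), 0.01)
})

test_that("rectification is elementwise absolute value on sEMG only", {
  rec <- recording(matrix(c(1, -1, 2), 3, 1), acc = matrix(-1, 3, 3))
  r <- rectify(rec)
  expect_equal(r$semg[, 1], c(1, 1, 2))
  expect_identical(r$acc, rec$acc)
  set.seed(2)
  rr <- recording(matrix(rnorm(100), 50, 2))
  expect_gte(min(rectify(rr)$semg), 0)
  expect_identical(rectify(rectify(rr)), rectify(rr))
})

test_that("normalization standardizes with training statistics only", {
  set.seed(4)
  train <- list(matrix(rnorm(200, mean = 3, sd = 2), 100, 2),
                matrix(rnorm(200, mean = 3, sd = 2), 100, 2))
  nm <- normalize_channels(train)
  pooled <- do.call(rbind, nm$segments)
  expect_equal(colMeans(pooled), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(pooled, 2, sd), c(1, 1), tolerance = 1e-10)
  # a shifted test set keeps its shift relative to the training statistics
  test <- list(matrix(rnorm(200, mean = 10, sd = 2), 100, 2))
  out <- normalize_channels(train, apply_to = test)
  expect_gt(min(colMeans(out$segments[[1]])), 2)
  # reusing stored statistics gives the same transform
  out2 <- normalize_channels(NULL, apply_to = test, stats = nm$stats)
  expect_identical(out$segments, out2$segments)
  # constant channel -> zeros with a warning
  const <- list(matrix(c(rnorm(50), rep(7, 50)), 50, 2))
  expect_warning(nc <- normalize_channels(const), "zero-variance")
  expect_equal(nc$segments[[1]][, 2], rep(0, 50))
})

test_that("window segmentation is exact index bookkeeping", {
  seg <- matrix(seq_len(10000 * 2), 10000, 2)
  w <- segment_windows(seg, window_ms = 200, step_ms = 100, fs = 1000)
  expect_length(w, 99)                       # floor((10000-200)/100)+1
  expect_true(all(vapply(w, nrow, integer(1)) == 200L))
  for (i in c(1, 37, 99))                    # window i starts at (i-1)*step
    expect_identical(w[[i]], seg[((i - 1) * 100 + 1):((i - 1) * 100 + 200), ])
  expect_length(segment_windows(seg[1:200, ], 200, 100, 1000), 1)
  expect_warning(none <- segment_windows(seg[1:50, ], 200, 100, 1000), "longer")
  expect_length(none, 0)
})
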