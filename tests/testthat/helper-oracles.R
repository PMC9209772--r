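# Independent brute-force references used to cross-check the vectorized
# implementations. Everything here is deliberately written as plain loops
# over the defining formulas, sharing no code with the package internals.

# one-sided periodogram by direct DFT summation (O(n^2))
naive_periodogram <- function(x, fs) {
  n <- length(x)
  n_keep <- floor(n / 2) + 1L
  P <- numeric(n_keep)
  for (k in seq_len(n_keep)) {
    re <- 0; im <- 0
    for (t in seq_len(n)) {
      ang <- -2 * pi * (k - 1) * (t - 1) / n
      re <- re + x[t] * cos(ang)
      im <- im + x[t] * sin(ang)
    }
    P[k] <- (re^2 + im^2) / n
  }
  list(freq = (seq_len(n_keep) - 1) * fs / n, power = P)
}

naive_iemg <- function(x) { s <- 0; for (v in x) s <- s + abs(v); s }

naive_var <- function(x) { s <- 0; for (v in x) s <- s + v^2; s / (length(x) - 1) }

naive_mdf <- function(x, fs) {
  sp <- naive_periodogram(x, fs)
  half <- sum(sp$power) / 2
  run <- 0
  for (i in seq_along(sp$power)) {
    run <- run + sp$power[i]
    if (run >= half) return(sp$freq[i])
  }
}

naive_fr <- function(x, fs, edges) {
  sp <- naive_periodogram(x, fs)
  lo <- 0; hi <- 0
  for (i in seq_along(sp$freq)) {
    f <- sp$freq[i]
    if (f >= edges$llc && f <= edges$lhc) lo <- lo + sp$power[i]
    if (f >= edges$hlc && f <= edges$hhc) hi <- hi + sp$power[i]
  }
  lo / hi
}

# scalar-loop reference for the full CBAM chain on a single T x C map
naive_cbam <- function(F, cp, tp) {
  T <- nrow(F); C <- ncol(F)
  mlp <- function(v) {
    h <- numeric(ncol(cp$W0))
    for (j in seq_along(h)) {
      a <- if (is.null(cp$b0)) 0 else cp$b0[j]
      for (c in seq_len(C)) a <- a + v[c] * cp$W0[c, j]
      h[j] <- max(a, 0)
    }
    o <- numeric(C)
    for (c in seq_len(C)) {
      a <- if (is.null(cp$b1)) 0 else cp$b1[c]
      for (j in seq_along(h)) a <- a + h[j] * cp$W1[j, c]
      o[c] <- a
    }
    o
  }
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) { avg[c] <- mean(F[, c]); mx[c] <- max(F[, c]) }
  MC <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  Fp <- F
  for (t in seq_len(T)) for (c in seq_len(C)) Fp[t, c] <- F[t, c] * MC[c]
  avT <- numeric(T); mxT <- numeric(T)
  for (t in seq_len(T)) { avT[t] <- mean(Fp[t, ]); mxT[t] <- max(Fp[t, ]) }
  # kernel rows ordered tap-major then input channel (avg, max)
  ker <- matrix(tp$conv$W, 3, 2, byrow = TRUE)
  MT <- numeric(T)
  for (t in seq_len(T)) {
    a <- tp$conv$b[1]
    for (tap in 1:3) {
      src <- t + tap - 2
      if (src >= 1 && src <= T)
        a <- a + ker[tap, 1] * avT[src] + ker[tap, 2] * mxT[src]
    }
    MT[t] <- 1 / (1 + exp(-a))
  }
  Fpp <- Fp
  for (t in seq_len(T)) for (c in seq_len(C)) Fpp[t, c] <- Fp[t, c] * MT[t]
  list(MC = MC, MT = MT, F_prime = Fp, F_doubleprime = Fpp)
}

# small random recording for IO round trips
random_recording <- function(seed = 1, n = 50, n_ch = 4) {
  set.seed(seed)
  recording(
    semg = matrix(rnorm(n * n_ch), n, n_ch),
    acc = matrix(rnorm(n * 3), n, 3),
    fs = 1000, channel_ids = seq_len(n_ch),
    events = list(gesture_event(1, 5, 20, 1), gesture_event(2, 25, 45, 1)))
}

# power of a tone at frequency f0 in x, from the periodogram bin
tone_power <- function(x, fs, f0) {
  sp <- semgnet::window_spectrum(x, fs)
  sum(sp$power[abs(sp$freq - f0) <= fs / length(x)])
}

# compact labelled-segment fixtures for the redundancy module
make_segments <- function(rms_table, n = 400, reps = 1, seed = 1) {
  # rms_table: gestures x channels target RMS levels
  set.seed(seed)
  out <- list()
  for (r in seq_len(reps))
    for (k in seq_len(nrow(rms_table))) {
      m <- sapply(rms_table[k, ], function(s) rnorm(n, sd = 1) * s)
      out[[length(out) + 1L]] <- list(gesture_id = k, repetition = r,
                                      semg = m, acc = matrix(0, n, 3))
    }
  out
}
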