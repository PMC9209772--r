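# Seeded synthetic sEMG + ACC generator.
#
# The generator emulates the statistical structure the recognition method
# assumes rather than motor-unit physiology: each channel's muscle activity
# is an amplitude-modulated band-limited (10-200 Hz) Gaussian carrier, with
# a per-class x per-channel gain matrix, a trapezoidal activation envelope
# per action, a broadband noise floor, additive 50 Hz power-line
# interference, and sub-5 Hz baseline drift. Actions alternate with rest
# intervals and every action is annotated as an event. The accelerometer
# traces are class-specific smooth low-frequency trajectories plus noise.

#' Simulation specification
#'
#' Defaults mirror a 16-electrode cuff sampling at 1000 Hz with 10 s
#' actions repeated 15 times; tests and quick demonstrations pass smaller
#' `action_s` / `reps` / `n_classes`.
#'
#' @param n_channels number of sEMG electrodes (default 16).
#' @param n_classes number of gesture classes (<= 52).
#' @param fs sampling rate in Hz.
#' @param action_s seconds per action (default 10).
#' @param rest_s seconds of rest between actions (default 3).
#' @param reps repetitions per class (default 15).
#' @param amplitude_matrix `n_classes x n_channels` non-negative activation
#'   gains; `NULL` builds a deterministic bump pattern giving every class a
#'   distinct channel profile.
#' @param redundant_channels channel indices whose activation gain is
#'   forced to zero for every class (they still carry floor, line and
#'   drift), i.e. planted redundant electrodes.
#' @param line_hz,line_amp power-line interference frequency (50 Hz) and
#'   amplitude.
#' @param drift_amp baseline-drift amplitude (energy below 5 Hz).
#' @param noise_floor broadband noise amplitude present at rest.
#' @param acc_amp accelerometer trajectory amplitude in g.
#' @param seed integer; the generator is a pure function of this spec.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_channels = 16, n_classes = 52, fs = 1000,
                     action_s = 10, rest_s = 3, reps = 15,
                     amplitude_matrix = NULL, redundant_channels = integer(0),
                     line_hz = 50, line_amp = 0.5, drift_amp = 0.3,
                     noise_floor = 0.05, acc_amp = 1, seed = 1) {
  if (n_classes < 1 || n_classes > 52) stop("n_classes must be in 1..52")
  if (fs <= 2 * line_hz) stop("fs must exceed twice the line frequency")
  if (is.null(amplitude_matrix))
    amplitude_matrix <- default_amplitudes(n_classes, n_channels)
  amplitude_matrix <- as.matrix(amplitude_matrix)
  if (any(amplitude_matrix < 0)) stop("amplitude_matrix must be non-negative")
  if (!all(dim(amplitude_matrix) == c(n_classes, n_channels)))
    stop("amplitude_matrix must be n_classes x n_channels")
  if (length(redundant_channels))
    amplitude_matrix[, redundant_channels] <- 0
  structure(list(n_channels = n_channels, n_classes = n_classes, fs = fs,
                 action_s = action_s, rest_s = rest_s, reps = reps,
                 amplitude_matrix = amplitude_matrix,
                 redundant_channels = as.integer(redundant_channels),
                 line_hz = line_hz, line_amp = line_amp,
                 drift_amp = drift_amp, noise_floor = noise_floor,
                 acc_amp = acc_amp, seed = as.integer(seed)),
            class = "sim_spec")
}

# deterministic, well-conditioned class-by-channel gain pattern: each class
# activates a Gaussian bump of channels centred at a class-specific
# electrode, on top of a small shared baseline.
default_amplitudes <- function(n_classes, n_channels) {
  A <- matrix(0.2, n_classes, n_channels)
  sigma <- max(1, n_channels / 6)
  for (k in seq_len(n_classes)) {
    mu <- 1 + (k - 1) %% n_channels
    d <- pmin(abs(seq_len(n_channels) - mu),
              n_channels - abs(seq_len(n_channels) - mu))  # circular distance
    A[k, ] <- A[k, ] + 1.5 * exp(-d^2 / (2 * sigma^2)) +
      0.3 * ((seq_len(n_channels) + k) %% 3 == 0)
  }
  A
}

#' Easy desk-scale specification
#'
#' Five well-separated classes on six channels with short actions — the
#' configuration used for fast end-to-end checks. Class profiles are nearly
#' orthogonal so a small model separates them comfortably.
#'
#' @param seed integer seed.
#' @param ... overrides forwarded to [sim_spec()].
#' @return a `sim_spec`.
#' @export
sim_spec_easy <- function(seed = 1, ...) {
  A <- matrix(0.1, 5, 6)
  for (k in 1:5) A[k, k] <- 2      # one dominant electrode per class
  A[, 6] <- 0.5                     # shared mildly active electrode
  args <- utils::modifyList(
    list(n_channels = 6, n_classes = 5, fs = 1000, action_s = 2,
         rest_s = 0.5, reps = 5, amplitude_matrix = A,
         line_amp = 0.3, drift_amp = 0.2, noise_floor = 0.05, seed = seed),
    list(...))
  do.call(sim_spec, args)
}

trapezoid <- function(n, fs, ramp_s = 0.5) {
  r <- min(floor(ramp_s * fs), floor(n / 2))
  env <- rep(1, n)
  if (r > 0) {
    env[seq_len(r)] <- seq_len(r) / r
    env[(n - r + 1):n] <- rev(seq_len(r)) / r
  }
  env
}

bandlimit <- function(x, fs, lo = 10, hi = 200, order = 4) {
  ba <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filter(ba, x))
}

#' Simulate a labelled recording
#'
#' Layout: repetitions of (rest, action for class 1, rest, action for class
#' 2, ...) with a trailing rest block, every action annotated as an event.
#' Fully determined by `spec` (including its seed).
#'
#' @param spec a [sim_spec()].
#' @return a [recording()].
#' @export
simulate_recording <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n_act <- round(spec$action_s * fs)
  n_rest <- round(spec$rest_s * fs)
  n_total <- spec$reps * spec$n_classes * (n_act + n_rest) + n_rest
  tt <- (seq_len(n_total) - 1) / fs

  # class-activation envelope shared by all channels, events alongside
  env_class <- matrix(0, n_total, spec$n_classes)
  events <- list()
  pos <- 0L
  for (r in seq_len(spec$reps)) {
    for (k in seq_len(spec$n_classes)) {
      pos <- pos + n_rest
      idx <- (pos + 1):(pos + n_act)
      env_class[idx, k] <- trapezoid(n_act, fs)
      events[[length(events) + 1L]] <-
        gesture_event(k, pos, pos + n_act, repetition = r)
      pos <- pos + n_act
    }
  }

  semg <- matrix(0, n_total, spec$n_channels)
  for (c in seq_len(spec$n_channels)) {
    gain <- as.numeric(env_class %*% spec$amplitude_matrix[, c])
    carrier <- bandlimit(stats::rnorm(n_total), fs)
    floor_noise <- bandlimit(stats::rnorm(n_total), fs)
    line <- spec$line_amp * sin(2 * pi * spec$line_hz * tt +
                                  stats::runif(1, 0, 2 * pi))
    drift <- spec$drift_amp * (sin(2 * pi * 0.3 * tt + stats::runif(1, 0, 2 * pi)) +
                               0.5 * sin(2 * pi * 1.1 * tt + stats::runif(1, 0, 2 * pi)))
    semg[, c] <- carrier * gain + spec$noise_floor * floor_noise + line + drift
  }

  acc <- matrix(stats::rnorm(n_total * 3, sd = 0.02), n_total, 3)
  for (j in 1:3) {
    traj <- numeric(n_total)
    for (k in seq_len(spec$n_classes)) {
      f_kj <- 0.4 + 0.15 * ((k * 3 + j) %% 7)          # class-specific slow rate
      a_kj <- spec$acc_amp * (0.3 + 0.7 * ((k + j) %% 4) / 3)
      traj <- traj + env_class[, k] * a_kj * sin(2 * pi * f_kj * tt)
    }
    acc[, j] <- acc[, j] + traj
  }

  recording(semg = semg, acc = acc, fs = fs,
            channel_ids = seq_len(spec$n_channels), events = events,
            has_acc = TRUE)
}

#' Simulate a class-stratified train/test split
#'
#' Simulates one session per the spec, slices the labelled segments, and
#' splits them by repetition (the first `round(reps * train_fraction)`
#' repetitions of every class train, the rest test), so no decision window
#' can straddle the split.
#'
#' @param spec a [sim_spec()].
#' @param train_fraction fraction of repetitions assigned to training
#'   (default 8/9).
#' @return list with `train`, `test` (labelled segment lists), `rest`
#'   (rest segments), `recording`, `spec`.
#' @export
simulate_dataset <- function(spec, train_fraction = 8 / 9) {
  rec <- simulate_recording(spec)
  segs <- extract_labeled_segments(rec)
  rest <- extract_rest_segments(rec, min_samples = round(spec$fs / 4))
  n_train <- round(spec$reps * train_fraction)
  if (n_train < 1 || n_train >= spec$reps)
    stop("train_fraction leaves an empty train or test partition")
  reps <- vapply(segs, function(s) s$repetition, integer(1))
  list(train = segs[reps <= n_train], test = segs[reps > n_train],
       rest = rest, recording = rec, spec = spec)
}
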