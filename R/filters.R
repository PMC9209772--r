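#' Notch (trap) filter specification
#'
#' Describes a narrow band-stop filter nulling the power-line component.
#' The ideal trap has unit gain everywhere except a null at `omega0`; the
#' realizable design is a second-order IIR biquad whose zeros sit exactly on
#' the unit circle at the notch frequency, so the magnitude response is 0 at
#' `omega0` and near 1 elsewhere. `q` sets the -3 dB bandwidth
#' (`omega0 / q`); the default Q = 30 gives roughly a 1.7 Hz wide notch at
#' 50 Hz, narrow enough to spare the 10-200 Hz band that carries most sEMG
#' energy.
#'
#' @param omega0 notch frequency in Hz (power line, default 50).
#' @param q quality factor (dimensionless, > 0).
#' @param fs sampling rate in Hz.
#' @return A list of class `notch_spec`.
#' @export
notch_spec <- function(omega0 = 50, q = 30, fs = 1000) {
  if (!(omega0 > 0 && omega0 < fs / 2))
    stop("notch frequency must satisfy 0 < omega0 < fs/2")
  if (q <= 0) stop("q must be positive")
  structure(list(omega0 = omega0, q = q, fs = fs), class = "notch_spec")
}

#' Butterworth high-pass specification
#'
#' Magnitude follows the maximally flat closed form
#' `|H(jW)|^2 = 1 / (1 + eps^2 (Wc/W)^(2N))` (high-pass), i.e. gain
#' `1/sqrt(1 + eps^2)` at the cutoff and an asymptotic stopband slope of
#' `6N` dB per octave — 18 dB/octave at the default order 3.
#'
#' @param order_n filter order N (default 3).
#' @param cutoff_hz turning frequency in Hz (default 20).
#' @param epsilon passband-edge parameter (default 1, the standard
#'   Butterworth -3 dB cutoff convention).
#' @param fs sampling rate in Hz.
#' @return A list of class `butterworth_spec`.
#' @export
butterworth_spec <- function(order_n = 3, cutoff_hz = 20, epsilon = 1,
                             fs = 1000) {
  if (order_n < 1) stop("order_n must be >= 1")
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2))
    stop("cutoff must satisfy 0 < cutoff_hz < fs/2")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(order_n = as.integer(order_n), cutoff_hz = cutoff_hz,
                 epsilon = epsilon, fs = fs, mode = "highpass"),
            class = "butterworth_spec")
}

#' Design the power-line notch filter
#'
#' Second-order IIR notch (constrained biquad): zeros on the unit circle at
#' +-omega0, poles pulled inside by the bandwidth. Gain is exactly zero at
#' the notch frequency and within a fraction of a percent of unity outside
#' the notch band.
#'
#' @param spec a [notch_spec()].
#' @return list with transfer-function coefficients `b`, `a` and the spec.
#' @export
design_notch <- function(spec) {
  stopifnot(inherits(spec, "notch_spec"))
  w0 <- 2 * pi * spec$omega0 / spec$fs
  alpha <- sin(w0) / (2 * spec$q)  # biquad bandwidth term; -3 dB width = omega0/Q
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]; a <- a / a[1]
  structure(list(b = b, a = a, spec = spec), class = "semg_filter")
}

#' Design the Butterworth high-pass filter
#'
#' Digital realization via `signal::butter` (bilinear transform with cutoff
#' prewarping), so the -3 dB point lands exactly at `cutoff_hz`. `epsilon`
#' values other than 1 rescale the effective cutoff to
#' `cutoff_hz * epsilon^(1/N)` so the closed-form gain at `cutoff_hz` is
#' `1/sqrt(1 + eps^2)`.
#'
#' @param spec a [butterworth_spec()].
#' @return list with `b`, `a` coefficients and the spec.
#' @export
design_highpass <- function(spec) {
  stopifnot(inherits(spec, "butterworth_spec"))
  # |H|^2 = 1/(1 + eps^2 (Wc/W)^2N)  ==  standard -3 dB butterworth with
  # cutoff Wc * eps^(1/N)
  fc_eff <- spec$cutoff_hz * spec$epsilon^(1 / spec$order_n)
  if (fc_eff >= spec$fs / 2) stop("effective cutoff is at or above Nyquist")
  ba <- signal::butter(spec$order_n, fc_eff / (spec$fs / 2), type = "high")
  structure(list(b = as.numeric(ba$b), a = as.numeric(ba$a), spec = spec),
            class = "semg_filter")
}

#' Magnitude response of a designed filter on a frequency grid
#'
#' @param filt a filter from [design_notch()] or [design_highpass()].
#' @param freqs_hz frequencies at which to evaluate |H(f)|.
#' @return numeric vector of magnitudes.
#' @export
filter_magnitude <- function(filt, freqs_hz) {
  fs <- filt$spec$fs
  w <- 2 * pi * freqs_hz / fs
  z <- exp(-1i * w)
  num <- outer(z, seq_along(filt$b) - 1, `^`) %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1, `^`) %*% filt$a
  as.numeric(Mod(num / den))
}

#' Closed-form Butterworth high-pass magnitude
#'
#' The analytic target `1/sqrt(1 + eps^2 (Wc/W)^(2N))` that the digital
#' design approximates.
#'
#' @param spec a [butterworth_spec()].
#' @param freqs_hz frequencies in Hz.
#' @return numeric vector of magnitudes.
#' @export
butterworth_magnitude <- function(spec, freqs_hz) {
  1 / sqrt(1 + spec$epsilon^2 * (spec$cutoff_hz / freqs_hz)^(2 * spec$order_n))
}

apply_ba <- function(filt, x, zero_phase = FALSE) {
  if (zero_phase)
    as.numeric(signal::filtfilt(signal::Arma(b = filt$b, a = filt$a), x))
  else
    as.numeric(signal::filter(signal::Arma(b = filt$b, a = filt$a), x))
}

#' Denoise the sEMG channels of a recording
#'
#' Applies the 50 Hz notch then the 20 Hz Butterworth high-pass to every
#' sEMG channel; ACC channels and events pass through untouched. Causal
#' single-pass filtering is the default, matching a real-time pipeline;
#' `zero_phase = TRUE` runs each filter forward-backward (offline use only —
#' two passes double the stopband slope).
#'
#' @param rec a [recording()].
#' @param notch a [notch_spec()] (or NULL to skip).
#' @param hp a [butterworth_spec()] (or NULL to skip).
#' @param zero_phase logical.
#' @return the filtered [recording()].
#' @export
apply_filters <- function(rec, notch = notch_spec(fs = rec$fs),
                          hp = butterworth_spec(fs = rec$fs),
                          zero_phase = FALSE) {
  validate_recording(rec)
  fn <- if (!is.null(notch)) design_notch(notch)
  fh <- if (!is.null(hp)) design_highpass(hp)
  semg <- rec$semg
  for (j in seq_len(ncol(semg))) {
    x <- semg[, j]
    if (!is.null(fn)) x <- apply_ba(fn, x, zero_phase)
    if (!is.null(fh)) x <- apply_ba(fh, x, zero_phase)
    semg[, j] <- x
  }
  rec$semg <- semg
  rec
}

#' Full-wave rectification
#'
#' Elementwise absolute value on the sEMG channels only, used to make the
#' active-segment amplitude visible before feature extraction. Idempotent.
#'
#' @param rec a [recording()].
#' @return the rectified [recording()].
#' @export
rectify <- function(rec) {
  validate_recording(rec)
  rec$semg <- abs(rec$semg)
  rec
}
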