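#' Integrated EMG
#'
#' `IEMG = sum(|x_i|)` over the window — the classical sEMG activity level.
#'
#' @param x numeric vector, one channel of a decision window.
#' @return non-negative scalar.
#' @export
iemg <- function(x) sum(abs(x))

#' Second-moment "variance" feature
#'
#' `VAR = 1/(N-1) * sum(x_i^2)`, the raw second moment with an N-1 divisor
#' and no mean subtraction. The filtered sEMG is near zero-mean so this is
#' close to the sample variance, but the raw-moment form is the one used
#' here deliberately.
#'
#' @param x numeric vector with at least 2 samples.
#' @return non-negative scalar.
#' @export
var_feature <- function(x) {
  n <- length(x)
  if (n < 2) stop("VAR needs at least two samples")
  sum(x^2) / (n - 1)
}

#' One-sided power spectrum of a window
#'
#' Rectangular-window (untapered) periodogram: `P_i = |X_i|^2 / N` at the
#' non-negative FFT bins. Used by [mdf()] and [fr()].
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return list with `freq` (Hz) and `power` (non-negative), one entry per
#'   bin from DC to Nyquist.
#' @export
window_spectrum <- function(x, fs) {
  n <- length(x)
  xf <- stats::fft(x)
  n_keep <- floor(n / 2) + 1L
  list(freq = (seq_len(n_keep) - 1) * fs / n,
       power = Mod(xf[seq_len(n_keep)])^2 / n)
}

#' Median frequency
#'
#' The smallest bin frequency at which the cumulative one-sided periodogram
#' power first reaches half the total (inclusive cumulative sum; an exact
#' half-total tie resolves to the lower bin). For a pure tone this is the
#' tone frequency; for white noise it approaches fs/4.
#'
#' @param x numeric vector (time-domain window).
#' @param fs sampling rate in Hz.
#' @return frequency in Hz.
#' @export
mdf <- function(x, fs) {
  sp <- window_spectrum(x, fs)
  tot <- sum(sp$power)
  if (tot <= 0) stop("zero total power; MDF undefined")
  idx <- which(cumsum(sp$power) >= tot / 2)[1]
  sp$freq[idx]
}

#' Band edges for the frequency-ratio feature
#'
#' The defaults split the sEMG band into a low band (20-45 Hz) and a high
#' band (95-450 Hz) inside the 0-500 Hz signal bandwidth; all four edges
#' are configurable.
#'
#' @param llc,lhc lower and upper cut-off of the low band (Hz).
#' @param hlc,hhc lower and upper cut-off of the high band (Hz).
#' @return named list of class `band_edges`.
#' @export
band_edges <- function(llc = 20, lhc = 45, hlc = 95, hhc = 450) {
  if (!(llc < lhc && lhc <= hlc && hlc < hhc))
    stop("band edges must satisfy LLC < LHC <= HLC < HHC")
  structure(list(llc = llc, lhc = lhc, hlc = hlc, hhc = hhc),
            class = "band_edges")
}

#' Frequency ratio
#'
#' Low-band over high-band periodogram power:
#' `FR = sum(P_i, LLC..LHC) / sum(P_i, HLC..HHC)` (band edges inclusive).
#'
#' @param x numeric vector (time-domain window).
#' @param fs sampling rate in Hz.
#' @param edges a [band_edges()].
#' @return positive scalar; error if the high band holds no power.
#' @export
fr <- function(x, fs, edges = band_edges()) {
  stopifnot(inherits(edges, "band_edges"))
  sp <- window_spectrum(x, fs)
  lo <- sum(sp$power[sp$freq >= edges$llc & sp$freq <= edges$lhc])
  hi <- sum(sp$power[sp$freq >= edges$hlc & sp$freq <= edges$hhc])
  # guard against a numerically empty high band (e.g. a pure DC window)
  if (hi <= sum(sp$power) * 1e-12)
    stop("zero high-band power; frequency ratio undefined")
  lo / hi
}

#' Multi-channel EMG feature image
#'
#' Applies the four window features (in the fixed order IEMG, VAR, MDF, FR)
#' to every channel of every window and stacks them into a
#' `channels x 4 x windows` array.
#'
#' @param windows list of window matrices (samples x channels), e.g. from
#'   [segment_windows()].
#' @param fs sampling rate in Hz.
#' @param edges a [band_edges()] for FR.
#' @return array `[n_channels, 4, n_windows]` with dimnames on the feature
#'   axis; class `feature_image`.
#' @export
build_feature_image <- function(windows, fs, edges = band_edges()) {
  if (!length(windows)) stop("no windows supplied")
  n_ch <- ncol(windows[[1]])
  out <- array(NA_real_, c(n_ch, 4L, length(windows)),
               dimnames = list(NULL, c("IEMG", "VAR", "MDF", "FR"), NULL))
  for (w in seq_along(windows)) {
    m <- windows[[w]]
    for (ch in seq_len(n_ch)) {
      x <- m[, ch]
      out[ch, , w] <- c(iemg(x), var_feature(x), mdf(x, fs), fr(x, fs, edges))
    }
  }
  structure(out, class = c("feature_image", "array"))
}

#' Export a feature image as a long-format table
#'
#' @param fi a `feature_image` from [build_feature_image()].
#' @return data.frame with window_id, channel, IEMG, VAR, MDF, FR.
#' @export
feature_image_table <- function(fi) {
  n_ch <- dim(fi)[1]; n_w <- dim(fi)[3]
  grid <- expand.grid(channel = seq_len(n_ch), window_id = seq_len(n_w))
  vals <- t(vapply(seq_len(nrow(grid)), function(i)
    fi[grid$channel[i], , grid$window_id[i]], numeric(4)))
  colnames(vals) <- dimnames(fi)[[2]]
  cbind(grid[, c("window_id", "channel")], as.data.frame(vals))
}
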