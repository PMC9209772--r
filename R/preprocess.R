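#' Per-channel standardization fitted on training segments
#'
#' Computes per-channel mean and standard deviation over all rows of the
#' training segments and applies the affine transform `(x - mean) / sd` to
#' every segment passed in `apply_to`. The statistics come from the training
#' set only — at inference time a stored `semg_norm` is reused so test data
#' is never normalized by its own statistics.
#'
#' @param train_segments list of numeric matrices (rows = samples,
#'   cols = channels), the training set.
#' @param apply_to list of matrices to transform (default: the training
#'   segments themselves).
#' @param stats an existing `semg_norm` to reuse instead of fitting.
#' @return list with `segments` (transformed) and `stats` (`semg_norm`:
#'   `mean`, `sd` per channel).
#' @export
normalize_channels <- function(train_segments, apply_to = train_segments,
                               stats = NULL) {
  if (is.null(stats)) {
    if (!length(train_segments)) stop("training set is empty")
    all_rows <- do.call(rbind, train_segments)
    mu <- colMeans(all_rows)
    sd_ <- apply(all_rows, 2, stats::sd)
    zero_var <- !is.finite(sd_) | sd_ == 0
    if (any(zero_var)) {
      warning(sprintf("%d zero-variance channel(s); using unit divisor",
                      sum(zero_var)))
      sd_[zero_var] <- 1
    }
    stats <- structure(list(mean = mu, sd = sd_), class = "semg_norm")
  }
  segs <- lapply(apply_to, function(m)
    sweep(sweep(m, 2, stats$mean, `-`), 2, stats$sd, `/`))
  list(segments = segs, stats = stats)
}

#' Cut a segment into fixed-length decision windows
#'
#' Regularly strided windows; a trailing remainder shorter than the window
#' is dropped. For 10,000 samples with a 200 ms window and 100 ms step at
#' 1000 Hz this yields `floor((10000 - 200)/100) + 1 = 99` windows.
#'
#' @param segment numeric matrix (samples x channels) or vector.
#' @param window_ms window length in milliseconds (default 200 — together
#'   with model inference this fits a sub-300 ms decision budget).
#' @param step_ms stride in milliseconds (default 100).
#' @param fs sampling rate in Hz.
#' @return list of window matrices, each `window_ms * fs / 1000` rows.
#' @export
segment_windows <- function(segment, window_ms = 200, step_ms = 100,
                            fs = 1000) {
  if (is.vector(segment)) segment <- matrix(segment, ncol = 1)
  wlen <- as.integer(round(window_ms * fs / 1000))
  step <- as.integer(round(step_ms * fs / 1000))
  if (wlen < 1 || step < 1) stop("window and step must be at least one sample")
  n <- nrow(segment)
  if (wlen > n) {
    warning("window longer than segment; returning no windows")
    return(list())
  }
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  lapply(starts, function(s) segment[s:(s + wlen - 1L), , drop = FALSE])
}
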