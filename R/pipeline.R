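# Glue between the signal-level modules and the classifier: filtering,
# splitting, windowing, feature images, and per-stream tensor assembly.

split_by_repetition <- function(segments, reps_total, train_fraction) {
  n_train <- round(reps_total * train_fraction)
  if (n_train < 1 || n_train >= reps_total)
    stop("train_fraction leaves an empty train or test partition")
  reps <- vapply(segments, function(s) s$repetition, integer(1))
  list(train = segments[reps <= n_train], test = segments[reps > n_train])
}

window_features_matrix <- function(w, fs, n_sub, edges) {
  # one channel window -> [n_sub, 4] sub-window feature sequence
  n <- length(w)
  sub <- floor(n / n_sub)
  t(vapply(seq_len(n_sub), function(i) {
    x <- w[((i - 1) * sub + 1):(i * sub)]
    c(iemg(x), var_feature(x), mdf(x, fs), fr(x, fs, edges))
  }, numeric(4)))
}

segments_to_streams <- function(segments, retained, window_ms, step_ms, fs,
                                input_mode, n_sub, edges, use_acc) {
  xs <- list(); ys <- integer(0)
  n_semg <- length(retained)
  for (seg in segments) {
    ws <- segment_windows(seg$semg[, retained, drop = FALSE],
                          window_ms, step_ms, fs)
    wa <- segment_windows(seg$acc, window_ms, step_ms, fs)
    for (i in seq_along(ws)) {
      item <- vector("list", n_semg + as.integer(use_acc))
      for (ch in seq_len(n_semg)) {
        item[[ch]] <- if (input_mode == "raw_windows")
          matrix(ws[[i]][, ch], ncol = 1)
        else
          window_features_matrix(ws[[i]][, ch], fs, n_sub, edges)
      }
      if (use_acc) item[[n_semg + 1L]] <- wa[[i]]
      xs[[length(xs) + 1L]] <- item
      ys <- c(ys, seg$gesture_id)
    }
  }
  n_streams <- n_semg + as.integer(use_acc)
  arrays <- lapply(seq_len(n_streams), function(s) {
    m1 <- xs[[1]][[s]]
    a <- array(0, c(length(xs), nrow(m1), ncol(m1)))
    for (i in seq_along(xs)) a[i, , ] <- xs[[i]][[s]]
    a
  })
  list(x = arrays, y = ys)
}

fit_stream_norm <- function(x) {
  lapply(x, function(a) {
    C <- dim(a)[3]
    mu <- numeric(C); sd_ <- numeric(C)
    for (c in seq_len(C)) {
      v <- a[, , c]
      mu[c] <- mean(v)
      s <- stats::sd(v)
      sd_[c] <- if (!is.finite(s) || s == 0) 1 else s
    }
    list(mean = mu, sd = sd_)
  })
}

apply_stream_norm <- function(x, norm) {
  for (s in seq_along(x))
    for (c in seq_len(dim(x[[s]])[3]))
      x[[s]][, , c] <- (x[[s]][, , c] - norm[[s]]$mean[c]) / norm[[s]]$sd[c]
  x
}

#' Build a train/test window dataset from a labelled recording
#'
#' Runs the full signal path: denoising filters on the continuous
#' recording, segment extraction, repetition-stratified train/test split,
#' decision-window slicing, per-stream tensor assembly (raw windows or
#' sub-window feature images), and per-stream standardization fitted on the
#' training windows only.
#'
#' @param rec a labelled [recording()].
#' @param train_fraction fraction of repetitions used for training.
#' @param retained sEMG channel indices to keep as streams (default all).
#' @param window_ms,step_ms decision-window geometry (defaults 200/100 ms).
#' @param input_mode `"raw_windows"` or `"feature_images"`.
#' @param n_sub sub-windows per decision window in feature mode.
#' @param edges [band_edges()] for the frequency-ratio feature.
#' @param use_acc include the accelerometer stream?
#' @param notch,hp filter specs (NULL to skip either).
#' @return list with `train` and `test` (`list(x, y)` per-stream arrays and
#'   labels), `norm`, `retained`, and window metadata.
#' @export
make_window_dataset <- function(rec, train_fraction = 0.8, retained = NULL,
                                window_ms = 200, step_ms = 100,
                                input_mode = c("raw_windows", "feature_images"),
                                n_sub = 8, edges = band_edges(),
                                use_acc = TRUE,
                                notch = notch_spec(fs = rec$fs),
                                hp = butterworth_spec(fs = rec$fs)) {
  input_mode <- match.arg(input_mode)
  if (is.null(retained)) retained <- seq_len(ncol(rec$semg))
  filt <- apply_filters(rec, notch, hp)
  segs <- extract_labeled_segments(filt)
  reps_total <- max(vapply(segs, function(s) s$repetition, integer(1)))
  sp <- split_by_repetition(segs, reps_total, train_fraction)
  tr <- segments_to_streams(sp$train, retained, window_ms, step_ms, rec$fs,
                            input_mode, n_sub, edges, use_acc)
  te <- segments_to_streams(sp$test, retained, window_ms, step_ms, rec$fs,
                            input_mode, n_sub, edges, use_acc)
  norm <- fit_stream_norm(tr$x)
  tr$x <- apply_stream_norm(tr$x, norm)
  te$x <- apply_stream_norm(te$x, norm)
  list(train = tr, test = te, norm = norm, retained = retained,
       window_ms = window_ms, step_ms = step_ms, fs = rec$fs,
       input_mode = input_mode, use_acc = use_acc)
}
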