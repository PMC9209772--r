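#' Multi-channel sEMG + accelerometer recording
#'
#' A `semg_recording` bundles a surface-EMG matrix (microvolts), a 3-axis
#' accelerometer matrix (g units), the sampling rate and a list of labelled
#' gesture events. Sample indexing is 0-based and event windows are half-open
#' `[onset, offset)`.
#'
#' @param semg numeric matrix, samples x channels.
#' @param acc numeric matrix, samples x 3 (all zeros when no accelerometer
#'   was worn; see `has_acc`).
#' @param fs sampling rate in Hz.
#' @param channel_ids integer electrode labels (1-based cuff numbering),
#'   one per sEMG column.
#' @param events list of [gesture_event()] annotations.
#' @param has_acc logical; `FALSE` means the ACC block is a placeholder of
#'   zeros so downstream fusion code keeps a uniform contract.
#' @return An object of class `semg_recording`.
#' @export
recording <- function(semg, acc = NULL, fs = 1000, channel_ids = NULL,
                      events = list(), has_acc = NULL) {
  semg <- as.matrix(semg)
  if (is.null(has_acc)) has_acc <- !is.null(acc)
  if (is.null(acc)) acc <- matrix(0, nrow(semg), 3L)
  acc <- as.matrix(acc)
  if (is.null(channel_ids)) channel_ids <- seq_len(ncol(semg))
  rec <- structure(
    list(semg = semg, acc = acc, fs = fs,
         channel_ids = as.integer(channel_ids),
         events = events, has_acc = isTRUE(has_acc)),
    class = "semg_recording")
  validate_recording(rec)
  rec
}

#' Gesture event annotation
#'
#' @param gesture_id integer class label in 1..52 (0 is reserved for rest).
#' @param onset_sample,offset_sample 0-based half-open window `[onset, offset)`.
#' @param repetition repetition index of this gesture.
#' @return A list of class `gesture_event`.
#' @export
gesture_event <- function(gesture_id, onset_sample, offset_sample,
                          repetition = 1L) {
  ev <- structure(
    list(gesture_id = as.integer(gesture_id),
         onset_sample = as.integer(onset_sample),
         offset_sample = as.integer(offset_sample),
         repetition = as.integer(repetition)),
    class = "gesture_event")
  if (ev$gesture_id < 0L || ev$gesture_id > 52L)
    stop("gesture_id must be in 0..52 (0 = rest)")
  if (ev$onset_sample < 0L || ev$onset_sample >= ev$offset_sample)
    stop("event window must satisfy 0 <= onset < offset")
  ev
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %d samples, %d sEMG channels, fs = %g Hz, %d events%s\n",
              nrow(x$semg), ncol(x$semg), x$fs, length(x$events),
              if (x$has_acc) ", 3-axis ACC" else ""))
  invisible(x)
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "semg_recording"))
  if (nrow(rec$semg) != nrow(rec$acc))
    stop("semg and acc must have the same number of sample rows")
  if (ncol(rec$acc) != 3L)
    stop("acc must have exactly 3 columns")
  if (!is.numeric(rec$fs) || rec$fs <= 0)
    stop("fs must be a positive sampling rate in Hz")
  if (anyDuplicated(rec$channel_ids))
    stop("channel_ids must be unique")
  if (length(rec$channel_ids) != ncol(rec$semg))
    stop("channel_ids must match the number of sEMG columns")
  n <- nrow(rec$semg)
  for (ev in rec$events) {
    if (!inherits(ev, "gesture_event")) stop("events must be gesture_event objects")
    if (ev$offset_sample > n)
      stop(sprintf("event [%d, %d) exceeds recording length %d",
                   ev$onset_sample, ev$offset_sample, n))
  }
  invisible(rec)
}

#' Read a recording from a CSV signal table plus JSON sidecar
#'
#' The signal table has a header row with columns `time`, `ch<k>` for each
#' electrode, then `accx`, `accy`, `accz`. The sidecar carries `fs`,
#' `channel_ids`, `has_acc` and the event list.
#'
#' @param signal_path path to the delimited signal table.
#' @param sidecar_path path to the JSON sidecar.
#' @return A [recording()].
#' @export
read_recording <- function(signal_path, sidecar_path) {
  tab <- utils::read.csv(signal_path, check.names = FALSE)
  side <- jsonlite::fromJSON(sidecar_path, simplifyDataFrame = FALSE)
  ch_ids <- as.integer(unlist(side$channel_ids))
  ch_cols <- paste0("ch", ch_ids)
  missing <- setdiff(ch_cols, names(tab))
  if (length(missing))
    stop("signal table is missing channel column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(names(tab)))
    stop("signal table has duplicate columns: ",
         paste(unique(names(tab)[duplicated(names(tab))]), collapse = ", "))
  acc_cols <- c("accx", "accy", "accz")
  if (!all(acc_cols %in% names(tab)))
    stop("signal table is missing accelerometer columns accx/accy/accz")
  events <- lapply(side$events, function(e)
    gesture_event(e$gesture_id, e$onset_sample, e$offset_sample,
                  if (is.null(e$repetition)) 1L else e$repetition))
  recording(semg = as.matrix(tab[, ch_cols, drop = FALSE]),
            acc = as.matrix(tab[, acc_cols, drop = FALSE]),
            fs = side$fs, channel_ids = ch_ids, events = events,
            has_acc = isTRUE(side$has_acc))
}

#' Write a recording to a CSV signal table plus JSON sidecar
#'
#' Inverse of [read_recording()]; floats are printed with 15 significant
#' digits so a round trip preserves values to within formatting precision
#' and a fixed input yields byte-stable files.
#'
#' @param rec a [recording()].
#' @param signal_path,sidecar_path output paths.
#' @export
write_recording <- function(rec, signal_path, sidecar_path) {
  validate_recording(rec)
  n <- nrow(rec$semg)
  tab <- data.frame(time = (seq_len(n) - 1) / rec$fs)
  for (i in seq_along(rec$channel_ids))
    tab[[paste0("ch", rec$channel_ids[i])]] <- rec$semg[, i]
  tab$accx <- rec$acc[, 1]; tab$accy <- rec$acc[, 2]; tab$accz <- rec$acc[, 3]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(tab, signal_path, row.names = FALSE, quote = FALSE)
  side <- list(
    fs = rec$fs,
    channel_ids = rec$channel_ids,
    has_acc = rec$has_acc,
    events = lapply(rec$events, function(e)
      list(gesture_id = e$gesture_id, onset_sample = e$onset_sample,
           offset_sample = e$offset_sample, repetition = e$repetition)))
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}

#' Slice the labelled action segments out of a recording
#'
#' @param rec a [recording()] with at least one event.
#' @return A list with one element per event, in event order, each a list of
#'   `gesture_id`, `repetition`, `semg` (rows `[onset, offset)`), `acc`.
#' @export
extract_labeled_segments <- function(rec) {
  validate_recording(rec)
  if (!length(rec$events)) stop("recording has no events to extract")
  lapply(rec$events, function(ev) {
    idx <- (ev$onset_sample + 1L):ev$offset_sample  # 0-based half-open -> R rows
    list(gesture_id = ev$gesture_id, repetition = ev$repetition,
         semg = rec$semg[idx, , drop = FALSE],
         acc = rec$acc[idx, , drop = FALSE])
  })
}

#' Slice the unlabelled (rest) gaps between events
#'
#' Returns the complement of the event windows, one matrix pair per maximal
#' gap, used as the rest benchmark by the redundancy ranking.
#'
#' @param rec a [recording()].
#' @param min_samples drop gaps shorter than this.
#' @return list of `list(semg, acc)` rest segments.
#' @export
extract_rest_segments <- function(rec, min_samples = 1L) {
  validate_recording(rec)
  n <- nrow(rec$semg)
  covered <- rep(FALSE, n)
  for (ev in rec$events)
    covered[(ev$onset_sample + 1L):ev$offset_sample] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i] && r$lengths[i] >= min_samples) {
      idx <- starts[i]:ends[i]
      out[[length(out) + 1L]] <- list(semg = rec$semg[idx, , drop = FALSE],
                                      acc = rec$acc[idx, , drop = FALSE])
    }
  }
  out
}
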