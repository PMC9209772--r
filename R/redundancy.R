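#' Per-channel action-information score
#'
#' Electrodes whose activity barely changes across gestures carry redundant
#' information. With the motionless arm as benchmark, each channel gets the
#' variance, across gesture classes, of its rest-corrected activation level:
#' `score_c = Var_k( RMS_{k,c} - RMS_{rest,c} )`, where `RMS_{k,c}` is the
#' root-mean-square of channel `c` over the (filtered) segments of gesture
#' `k`, averaged over repetitions. A LOW score means the channel looks the
#' same whatever the gesture — i.e. it is redundant; ranking for removal
#' therefore inverts this score (see [grade_and_weight()]).
#'
#' RMS is computed on the signal as given; rectification does not change it
#' (squaring removes sign), so segments may be passed rectified or not.
#'
#' @param segments list of labelled segments as returned by
#'   [extract_labeled_segments()] (elements need `gesture_id` and `semg`).
#' @param rest_segments list with `semg` matrices of motionless-arm signal.
#' @return numeric vector, one score per channel (named by column index).
#' @export
compute_redundancy_scores <- function(segments, rest_segments) {
  if (!length(rest_segments)) stop("rest segments are required as benchmark")
  gids <- vapply(segments, function(s) s$gesture_id, integer(1))
  if (length(unique(gids)) < 2L)
    stop("at least two distinct gestures are needed for a cross-action variance")
  rms <- function(m) sqrt(colMeans(m^2))
  rest_rms <- colMeans(do.call(rbind, lapply(rest_segments,
                                             function(s) rms(s$semg))))
  per_gesture <- lapply(split(segments, gids), function(group)
    colMeans(do.call(rbind, lapply(group, function(s) rms(s$semg)))))
  delta <- do.call(rbind, per_gesture)            # gestures x channels
  delta <- sweep(delta, 2, rest_rms, `-`)
  scores <- apply(delta, 2, stats::var)
  names(scores) <- seq_along(scores)
  scores
}

#' Ordinal redundancy grading and weighting
#'
#' Channels are binned into `n_levels` quantile grades by ascending score
#' (simple sequencing coding); the weight is the reversed grade so that it
#' correlates positively with redundancy: weight `n_levels` = lowest-score
#' (most redundant) bin, weight 1 = highest-score bin. Channels with equal
#' scores share a grade.
#'
#' @param scores numeric vector from [compute_redundancy_scores()].
#' @param n_levels number of ordinal levels (default 8).
#' @return data.frame with `channel`, `score`, `grade` (1 = lowest score),
#'   `weight` (n_levels = most redundant).
#' @export
grade_and_weight <- function(scores, n_levels = 8) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  probs <- seq(0, 1, length.out = n_levels + 1)
  brk <- unique(stats::quantile(scores, probs, names = FALSE, type = 7))
  if (length(brk) < 2L) {
    grade <- rep(1L, length(scores))           # all scores identical
  } else {
    grade <- as.integer(cut(scores, breaks = brk, include.lowest = TRUE))
  }
  data.frame(channel = seq_along(scores), score = as.numeric(scores),
             grade = grade, weight = as.integer(n_levels) + 1L - grade)
}

#' Cross-validated redundancy weighting
#'
#' The labelled data is divided into `k_folds` parts by repetition; each
#' part is held out in turn and [compute_redundancy_scores()] +
#' [grade_and_weight()] run on the remainder. The final per-channel weight
#' (the channel "redundancy rate") is the arithmetic mean over folds.
#'
#' @param segments labelled segments (with `repetition` fields).
#' @param rest_segments rest benchmark segments.
#' @param k_folds number of folds (default 8).
#' @param n_levels ordinal levels per fold (default 8).
#' @param n_remove channels to mark for removal (default 10, leaving 6 of
#'   the 16 cuff electrodes).
#' @param seed integer; folds are assigned by shuffling repetitions with
#'   this seed, so a run is reproducible bit-for-bit.
#' @return A `redundancy_report`: list with `weights` (mean over folds),
#'   `per_fold` (fold x channel weight matrix), `grades` (fold x channel),
#'   `retained`, `removed`.
#' @export
crossval_aggregate <- function(segments, rest_segments, k_folds = 8,
                               n_levels = 8, n_remove = 10, seed = 1) {
  reps <- sort(unique(vapply(segments, function(s) s$repetition, integer(1))))
  if (k_folds > length(reps))
    stop(sprintf("k_folds = %d exceeds the %d available repetitions",
                 k_folds, length(reps)))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(k_folds), length(reps)))
  names(fold_of) <- reps
  n_ch <- ncol(segments[[1]]$semg)
  per_fold <- matrix(NA_real_, k_folds, n_ch)
  grades <- matrix(NA_integer_, k_folds, n_ch)
  for (f in seq_len(k_folds)) {
    keep <- vapply(segments, function(s)
      fold_of[as.character(s$repetition)] != f, logical(1))
    gw <- grade_and_weight(
      compute_redundancy_scores(segments[keep], rest_segments), n_levels)
    per_fold[f, ] <- gw$weight
    grades[f, ] <- gw$grade
  }
  weights <- colMeans(per_fold)
  sel <- select_channels_from_weights(weights, n_remove)
  structure(list(weights = weights, per_fold = per_fold, grades = grades,
                 retained = sel$retained, removed = sel$removed,
                 n_levels = n_levels, k_folds = k_folds, seed = seed),
            class = "redundancy_report")
}

select_channels_from_weights <- function(weights, n_remove) {
  n <- length(weights)
  if (n_remove < 0 || n_remove >= n)
    stop("n_remove must satisfy 0 <= n_remove < n_channels")
  # most redundant first: highest weight, ties -> lower channel id first
  ord <- order(-weights, seq_len(n))
  removed <- sort(ord[seq_len(n_remove)])
  retained <- sort(setdiff(seq_len(n), removed))
  list(retained = retained, removed = if (n_remove) removed else integer(0))
}

#' Select channels to retain from a redundancy report
#'
#' Removes the `n_remove` highest-weight (most redundant) channels; ties are
#' broken by removing the lower channel id first.
#'
#' @param report a `redundancy_report` from [crossval_aggregate()].
#' @param n_remove how many channels to drop.
#' @return integer vector of retained channel indices, ascending.
#' @export
select_channels <- function(report, n_remove = 10) {
  stopifnot(inherits(report, "redundancy_report"))
  select_channels_from_weights(report$weights, n_remove)$retained
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf("<redundancy_report> %d channels, %d folds\n",
              length(x$weights), x$k_folds))
  cat("  weights:", paste(sprintf("%.2f", x$weights), collapse = " "), "\n")
  cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}
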