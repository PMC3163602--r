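#' Motion score: mean absolute pixel difference within a zone
#'
#' Low values mean the animal was still, so the frame is least likely to be
#' motion-blurred. `previous` must be the immediately preceding decoded frame
#' of the same stream (at native frame rate; for the paper's constant-rate
#' recordings this is the frame 1/fps seconds earlier).
#'
#' @param current,previous [frame_ref()]s of identical dimensions.
#' @param zone the [cage_zone()] over which to compare (motion is computed
#'   over the whole cage zone, not just the face region).
#' @return Non-negative mean of `|current - previous|` over zone pixels;
#'   exactly 0 iff the zone pixels are identical.
#' @export
motion_score <- function(current, previous, zone) {
  stopifnot(inherits(current, "frame_ref"), inherits(previous, "frame_ref"))
  if (!identical(dim(current$pixels), dim(previous$pixels))) {
    stop("frames differ in dimensions")
  }
  check_zone_in_frame(zone, current$pixels)
  zr <- zone_rect(zone)
  mean(abs(rect_pixels(current$pixels, zr) - rect_pixels(previous$pixels, zr)))
}

#' Bucket candidate frames into fixed time intervals
#'
#' Intervals are half-open windows `[i * window_s, (i + 1) * window_s)`
#' anchored at stream time 0, so every candidate lands in exactly one bucket.
#' All intervals covering `[0, duration_s)` are returned, including empty
#' ones (empty intervals feed the gap report).
#'
#' @param candidates list of `candidate_frame`s from one source/zone.
#' @param window_s interval length in seconds (default 180, the 3-minute
#'   scoring interval).
#' @param duration_s stream duration; defaults to just past the last
#'   candidate's timestamp.
#' @param zone_label zone label recorded on the buckets; defaults to the
#'   candidates' zone.
#' @return List of `interval_bucket` objects (fields `interval_index`,
#'   `start_s`, `end_s`, `zone_label`, `candidates`, `selected`, `sparse`).
#' @export
bucket_by_interval <- function(candidates, window_s = 180,
                               duration_s = NULL, zone_label = NULL) {
  if (window_s <= 0) stop("interval window must be positive")
  ts <- vapply(candidates, function(cf) cf$frame$timestamp_s, 0)
  if (is.null(duration_s)) {
    if (length(candidates) == 0) return(list())
    duration_s <- max(ts) + 1e-9
  }
  if (is.null(zone_label) && length(candidates) > 0) {
    zone_label <- candidates[[1]]$zone_label
  }
  n_int <- max(1L, as.integer(ceiling(duration_s / window_s)))
  idx <- if (length(candidates)) floor(ts / window_s) else integer(0)
  if (any(idx >= n_int)) stop("candidate timestamp beyond stream duration")
  lapply(seq_len(n_int) - 1L, function(i) {
    structure(
      list(interval_index = i, start_s = i * window_s,
           end_s = (i + 1) * window_s,
           zone_label = zone_label %||% NA_character_,
           candidates = candidates[idx == i],
           selected = list(), sparse = NA),
      class = "interval_bucket"
    )
  })
}

#' Select the stillest candidates in an interval
#'
#' Keeps the `k` candidates with the smallest motion score (default 3 per
#' 3-minute interval), ties broken by earlier frame index, so the selection
#' is deterministic and equals the head of a stable sort by
#' `(motion_score, frame_index)`. Candidates without a motion score (the
#' first decoded frame has no predecessor) are excluded from ranking with a
#' message. Intervals with fewer than `k` ranked candidates keep them all and
#' are flagged sparse.
#'
#' @param bucket an `interval_bucket` from [bucket_by_interval()].
#' @param k number of frames to keep per interval.
#' @return The bucket with `selected` and `sparse` filled.
#' @export
select_stillest <- function(bucket, k = 3L) {
  stopifnot(inherits(bucket, "interval_bucket"))
  cands <- bucket$candidates
  scores <- vapply(cands, function(cf) cf$motion_score %||% NA_real_, 0)
  unranked <- is.na(scores)
  if (any(unranked)) {
    message(sum(unranked), " candidate(s) without motion score excluded ",
            "from ranking in interval ", bucket$interval_index)
    cands <- cands[!unranked]
    scores <- scores[!unranked]
  }
  idx <- vapply(cands, function(cf) cf$frame$frame_index, 0L)
  ord <- order(scores, idx)
  keep <- ord[seq_len(min(k, length(ord)))]
  bucket$selected <- cands[keep]
  bucket$sparse <- length(keep) < k
  if (bucket$sparse && length(bucket$candidates) > 0) {
    message("interval ", bucket$interval_index, " is sparse: ",
            length(keep), " < ", k, " ranked candidates")
  }
  bucket
}

#' Report intervals with no candidate frames
#'
#' Intervals in which the animal never faced the camera (or detection failed)
#' yield no candidates; the paper's workflow falls back to manual frame
#' grabs there. The report lists those intervals machine-readably.
#'
#' @param buckets list of `interval_bucket`s from one source/zone.
#' @param path optional CSV output path.
#' @return Data frame with columns `interval_index`, `start_s`, `end_s`,
#'   `zone_label`, one row per empty interval (zero rows if none).
#' @export
report_gaps <- function(buckets, path = NULL) {
  empty <- Filter(function(b) length(b$candidates) == 0, buckets)
  rep <- data.frame(
    interval_index = vapply(empty, `[[`, 0L, "interval_index"),
    start_s = vapply(empty, `[[`, 0, "start_s"),
    end_s = vapply(empty, `[[`, 0, "end_s"),
    zone_label = vapply(empty, function(b) b$zone_label %||% NA_character_, "")
  )
  if (!is.null(path)) utils::write.csv(rep, path, row.names = FALSE)
  rep
}
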