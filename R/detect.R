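#' Multi-scale scan parameters
#'
#' @param scale_factor geometric growth of the detection window between
#'   scales (standard cascade-scanning default 1.1).
#' @param step_frac window shift between evaluations, as a fraction of the
#'   current window side.
#' @param min_neighbors minimum number of raw overlapping hits required for a
#'   merged detection (suppresses isolated false positives).
#' @param merge_eps relative position/size slack when grouping raw hits.
#' @param max_window_frac largest window side as a fraction of the shorter
#'   zone side.
#' @param min_sd windows whose intensity standard deviation falls below this
#'   are rejected before cascade evaluation: featureless regions cannot
#'   contain an eye or ear, and skipping them dominates scan cost on mostly
#'   empty zones. Must stay well below the contrast of real features (a
#'   dark pupil on a lighter face gives window sds an order of magnitude
#'   above sensor noise).
#' @return Named list of scan parameters.
#' @export
scan_params <- function(scale_factor = 1.1, step_frac = 0.125,
                        min_neighbors = 3L, merge_eps = 0.25,
                        max_window_frac = 0.6, min_sd = 6) {
  list(scale_factor = scale_factor, step_frac = step_frac,
       min_neighbors = as.integer(min_neighbors), merge_eps = merge_eps,
       max_window_frac = max_window_frac, min_sd = min_sd)
}

# Flatten a haar_cascade into the vectors the compiled scanner takes.
# The flat form is cached on the model at training/load time.
flatten_cascade <- function(model) {
  if (!is.null(model$.flat)) return(model$.flat)
  stages <- model$stages
  weaks <- do.call(c, lapply(stages, `[[`, "weaks"))
  rect_list <- model$features
  nrects <- vapply(rect_list, nrow, 0L)
  list(
    stage_thr = vapply(stages, `[[`, 0, "threshold"),
    stage_nweak = vapply(stages, function(s) length(s$weaks), 0L),
    weak_feature = vapply(weaks, function(w) w$feature - 1L, 0L),
    weak_thr = vapply(weaks, `[[`, 0, "thr"),
    weak_pol = vapply(weaks, `[[`, 0, "pol"),
    weak_alpha = vapply(weaks, `[[`, 0, "alpha"),
    feat_offset = c(0L, cumsum(nrects)[-length(nrects)]),
    feat_nrects = nrects,
    rects = do.call(rbind, rect_list)
  )
}

# Group raw hits (x, y, size) into merged detections. Two hits are neighbors
# when their positions and sizes agree within merge_eps of the mean size;
# groups with >= min_neighbors members are averaged into one box.
merge_hits <- function(hits, min_neighbors, merge_eps) {
  n <- nrow(hits)
  empty <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), scale = numeric(0), n_raw = integer(0))
  if (n == 0) return(empty)
  groups <- split(seq_len(n), group_hits_cpp(hits, merge_eps))
  rows <- lapply(groups, function(idx) {
    if (length(idx) < min_neighbors) return(NULL)
    size <- round(mean(hits[idx, "size"]))
    data.frame(x = round(mean(hits[idx, "x"])),
               y = round(mean(hits[idx, "y"])),
               w = size, h = size, scale = size,
               n_raw = length(idx))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$x, out$y), , drop = FALSE]
}

#' Detect eyes and ears in one cage zone
#'
#' Scans the zone with each cascade at a ladder of window scales, merges
#' overlapping raw hits, and returns every detection as a box in full-frame
#' coordinates tagged with its feature kind and detection scale. Detection is
#' deterministic: the same frame, models and parameters always give the same
#' box list, and pixels outside the zone cannot influence the result.
#'
#' @param frame a [frame_ref()].
#' @param zone a [cage_zone()] valid for the frame.
#' @param models named list with elements `eye` and/or `ear`, each a
#'   `haar_cascade`.
#' @param params scan parameters from [scan_params()].
#' @return A data frame with columns `feature_kind`, `x`, `y`, `w`, `h`
#'   (full-frame coordinates), `scale` (window side, px) and `n_raw` (merged
#'   hit count).
#' @export
detect_features <- function(frame, zone, models, params = scan_params()) {
  stopifnot(inherits(frame, "frame_ref"))
  check_zone_in_frame(zone, frame$pixels)
  zpx <- rect_pixels(frame$pixels, zone_rect(zone))
  out <- lapply(names(models), function(kind) {
    model <- models[[kind]]
    fl <- flatten_cascade(model)
    hits <- scan_cascade_cpp(zpx, model$window, fl$stage_thr, fl$stage_nweak,
                             fl$weak_feature, fl$weak_thr, fl$weak_pol,
                             fl$weak_alpha, fl$feat_offset, fl$feat_nrects,
                             fl$rects, params$scale_factor, params$step_frac,
                             params$max_window_frac, params$min_sd %||% 0)
    det <- merge_hits(hits, params$min_neighbors, params$merge_eps)
    if (nrow(det) == 0) return(cbind(feature_kind = character(0), det))
    # the scan window carries the training-crop margin around the feature;
    # shrink reported boxes to the fraction the feature itself occupies
    frac <- model$object_frac %||% 1
    if (frac < 1) {
      inner <- pmax(1, round(det$w * frac))
      det$x <- det$x + round((det$w - inner) / 2)
      det$y <- det$y + round((det$h - inner) / 2)
      det$w <- det$h <- inner
    }
    det$x <- det$x + zone$x
    det$y <- det$y + zone$y
    cbind(feature_kind = kind, det)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the candidate rule to a frame's detections
#'
#' A frame qualifies as a scoring candidate when at least one eye and at
#' least one ear are detected and some eye–ear pair has a center-to-center
#' distance within configured bounds; the bounds are expressed as multiples
#' of the mean of the pair's box widths, which keeps the rule
#' resolution-independent. When several pairs qualify, the closest pair
#' defines the face region (ties broken by smaller eye x). Returns `NULL`
#' when no pair qualifies — absence of a candidate is a normal outcome.
#'
#' @param frame a [frame_ref()].
#' @param zone the [cage_zone()] the detections came from.
#' @param detections data frame from [detect_features()].
#' @param bounds length-2 numeric `c(d_min, d_max)` in units of the pair's
#'   mean box width.
#' @param expansion face-region expansion factor (see
#'   [estimate_face_region()]).
#' @return A `candidate_frame` (fields `frame`, `zone_label`, `detections`,
#'   `eye`, `ear`, `pair_distance`, `face_region`, `motion_score`) or `NULL`.
#' @export
flag_candidate <- function(frame, zone, detections, bounds = c(0.5, 4.0),
                           expansion = 0.5) {
  eyes <- detections[detections$feature_kind == "eye", , drop = FALSE]
  ears <- detections[detections$feature_kind == "ear", , drop = FALSE]
  if (nrow(eyes) == 0 || nrow(ears) == 0) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(eyes))) {
    for (j in seq_len(nrow(ears))) {
      eye_r <- rect(eyes$x[i], eyes$y[i], eyes$w[i], eyes$h[i])
      ear_r <- rect(ears$x[j], ears$y[j], ears$w[j], ears$h[j])
      ce <- rect_center(eye_r); ca <- rect_center(ear_r)
      d <- sqrt(sum((ce - ca)^2))
      mw <- (eye_r[["w"]] + ear_r[["w"]]) / 2
      if (d >= bounds[1] * mw && d <= bounds[2] * mw) {
        if (is.null(best) || d < best$d ||
            (d == best$d && eye_r[["x"]] < best$eye[["x"]])) {
          best <- list(eye = eye_r, ear = ear_r, d = d)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  face <- estimate_face_region(best$eye, best$ear, zone, expansion)
  structure(
    list(frame = frame, zone_label = zone$label, detections = detections,
         eye = best$eye, ear = best$ear, pair_distance = best$d,
         face_region = face, motion_score = NA_real_),
    class = "candidate_frame"
  )
}

#' Estimate the face region from a qualifying eye–ear pair
#'
#' The face region is the bounding box of the eye and ear boxes, expanded on
#' each side by `expansion` times its own width/height (rounded outward, so
#' the region never shrinks below the stated rule), then clipped to the cage
#' zone.
#'
#' @param eye,ear rectangles ([rect()]) of the qualifying pair.
#' @param zone the [cage_zone()] to clip to.
#' @param expansion per-side expansion factor; 0 gives the exact union
#'   bounding box.
#' @return A rectangle, guaranteed inside the zone.
#' @export
estimate_face_region <- function(eye, ear, zone, expansion = 0.5) {
  u <- rect_union_bbox(eye, ear)
  x1 <- floor(u[["x"]] - expansion * u[["w"]])
  y1 <- floor(u[["y"]] - expansion * u[["h"]])
  x2 <- ceiling(rect_x2(u) + expansion * u[["w"]])
  y2 <- ceiling(rect_y2(u) + expansion * u[["h"]])
  rect_clip(rect(x1, y1, x2 - x1, y2 - y1), zone_rect(zone))
}
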