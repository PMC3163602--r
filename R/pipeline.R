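#' Scan a stream for scoring candidates
#'
#' Runs detection and the candidate rule over every frame and zone of a
#' stream, attaching each candidate's motion score (mean absolute pixel
#' difference to the previous decoded frame over its zone). Frames are
#' decoded in chunks so long streams never sit in memory whole; candidates
#' are slimmed to their face-region crop plus metadata.
#'
#' @param stream a [frame_stream][open_stream] (or a path).
#' @param zones list of [cage_zone()]s.
#' @param models named list of `haar_cascade`s (`eye`, `ear`).
#' @param scan [scan_params()].
#' @param bounds eye-ear distance bounds (multiples of mean box width).
#' @param chunk frames decoded per chunk.
#' @param progress print a line every chunk.
#' @return List with `candidates` (per-zone lists of slim
#'   `candidate_frame`s), `duration_s`, `stream`.
#' @export
extract_candidates <- function(stream, zones, models, scan = scan_params(),
                               bounds = c(0.5, 4.0), chunk = 200L,
                               progress = FALSE) {
  if (is.character(stream)) stream <- open_stream(stream)
  labels <- vapply(zones, `[[`, "", "label")
  cands <- stats::setNames(vector("list", length(zones)), labels)
  cands[] <- list(list())
  prev <- NULL
  starts <- seq(0L, stream$n_frames - 1L, by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, stream$n_frames - 1L)
    frames <- read_frames(stream, idx)
    for (fr in frames) {
      for (z in zones) {
        det <- detect_features(fr, z, models, scan)
        cand <- flag_candidate(fr, z, det, bounds)
        if (!is.null(cand)) {
          cand$motion_score <- if (is.null(prev)) NA_real_ else {
            motion_score(fr, prev, z)
          }
          cand$face_pixels <- rect_pixels(fr$pixels, cand$face_region)
          cand$frame$pixels <- NULL
          cands[[z$label]][[length(cands[[z$label]]) + 1L]] <- cand
        }
      }
      prev <- fr
    }
    if (progress) {
      message("scanned frames ", idx[1], "-", idx[length(idx)], " (",
              sum(lengths(cands)), " candidates)")
    }
  }
  list(candidates = cands, duration_s = stream$n_frames / stream$fps,
       stream = stream)
}

#' Extract, rank and export scoring images from a stream
#'
#' The full frame-capture pass: detect candidates ([extract_candidates()]),
#' bucket them into fixed intervals per zone, keep the `k` stillest per
#' interval, and export each selected face crop as
#' `out_dir/<source>/<zone>/interval_<idx>/rank<r>.png`, alongside a
#' `candidates.csv` (all candidates with motion scores and selection rank)
#' and a `gaps.csv` listing intervals with no candidates.
#'
#' @inheritParams extract_candidates
#' @param out_dir output directory (created).
#' @param window_s interval length, seconds (default 180).
#' @param k images kept per interval per zone.
#' @return List with `images` (data frame: `image_path`, `zone`, `interval`,
#'   `rank`, `frame_index`, `timestamp_s`, `motion_score`), `candidates`
#'   (data frame of all candidates), `gaps` (data frame), `buckets`
#'   (per-zone lists of filled `interval_bucket`s).
#' @export
run_extraction <- function(stream, zones, models, out_dir,
                           scan = scan_params(), bounds = c(0.5, 4.0),
                           window_s = 180, k = 3L, chunk = 200L,
                           progress = FALSE) {
  ex <- extract_candidates(stream, zones, models, scan, bounds, chunk,
                           progress)
  stream <- ex$stream
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  images <- list(); all_cands <- list(); gaps <- list(); buckets_out <- list()
  for (z in zones) {
    zcands <- ex$candidates[[z$label]]
    buckets <- bucket_by_interval(zcands, window_s,
                                  duration_s = ex$duration_s,
                                  zone_label = z$label)
    buckets <- lapply(buckets, select_stillest, k = k)
    buckets_out[[z$label]] <- buckets
    gaps[[z$label]] <- report_gaps(buckets)
    for (b in buckets) {
      sel_idx <- vapply(b$selected, function(cf) cf$frame$frame_index, 0L)
      for (ci in seq_along(b$candidates)) {
        cf <- b$candidates[[ci]]
        rank <- match(cf$frame$frame_index, sel_idx)
        all_cands[[length(all_cands) + 1L]] <- data.frame(
          zone = z$label, interval = b$interval_index,
          frame_index = cf$frame$frame_index,
          timestamp_s = cf$frame$timestamp_s,
          motion_score = cf$motion_score, rank = rank
        )
      }
      for (r in seq_along(b$selected)) {
        cf <- b$selected[[r]]
        img_dir <- file.path(out_dir, stream$source_id, z$label,
                             sprintf("interval_%d", b$interval_index))
        dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
        img_path <- file.path(img_dir, sprintf("rank%d.png", r))
        png::writePNG(cf$face_pixels / 255, img_path)
        images[[length(images) + 1L]] <- data.frame(
          image_path = img_path, zone = z$label,
          interval = b$interval_index, rank = r,
          frame_index = cf$frame$frame_index,
          timestamp_s = cf$frame$timestamp_s,
          motion_score = cf$motion_score
        )
      }
    }
  }
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  images_df <- bind(images, data.frame())
  cand_df <- bind(all_cands, data.frame())
  gaps_df <- do.call(rbind, gaps)
  rownames(gaps_df) <- NULL
  utils::write.csv(cand_df, file.path(out_dir, "candidates.csv"),
                   row.names = FALSE)
  utils::write.csv(gaps_df, file.path(out_dir, "gaps.csv"), row.names = FALSE)
  list(images = images_df, candidates = cand_df, gaps = gaps_df,
       buckets = buckets_out)
}

#' Write a plain-text statistics report
#'
#' Collects the statistical endpoints of a scoring session — reliability,
#' signal-detection accuracy, difference scores and (optionally) analgesic
#' potency — into one human-readable file.
#'
#' @param path output text file.
#' @param icc optional `icc_result`.
#' @param confusion optional `confusion_summary`.
#' @param diffs optional data frame from [difference_scores()].
#' @param ad50_fit optional `ad50_result`.
#' @return `path`, invisibly.
#' @export
write_report <- function(path, icc = NULL, confusion = NULL, diffs = NULL,
                         ad50_fit = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  out <- function(...) writeLines(paste0(...), con)
  out("Grimace-scale scoring report")
  out(strrep("=", 28))
  if (!is.null(icc)) {
    out("")
    out(sprintf("Reliability (%d images x %d scorers):", icc$n_subjects,
                icc$n_raters))
    for (v in names(icc$estimates)) {
      out(sprintf("  ICC %-20s %.3f%s", v, icc$estimates[[v]],
                  if (v == icc$variant) "  (reported)" else ""))
    }
  }
  if (!is.null(confusion)) {
    p <- confusion$pooled
    out("")
    out(sprintf("Accuracy: %.1f%% of %d judgments", p$accuracy, p$n))
    out(sprintf("  hits %.1f%%  correct rejections %.1f%%  misses %.1f%%  false alarms %.1f%%",
                p$hit_rate, p$correct_rejection_rate, p$miss_rate,
                p$false_alarm_rate))
  }
  if (!is.null(diffs)) {
    out("")
    out("Difference scores (pain - no pain):")
    for (i in seq_len(nrow(diffs))) {
      out(sprintf("  %-22s delta %+.3f (SEM %.3f, n = %d)",
                  diffs$action_unit[i], diffs$delta[i], diffs$sem[i],
                  diffs$n_animals[i]))
    }
  }
  if (!is.null(ad50_fit)) {
    out("")
    out(sprintf("AD50: %.3g (CI %.3g-%.3g) dose units; slope %.3g %%MPE/decade",
                ad50_fit$estimate, ad50_fit$ci_low, ad50_fit$ci_high,
                ad50_fit$slope))
  }
  invisible(path)
}
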