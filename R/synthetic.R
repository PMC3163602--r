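# ---- Stylized face rendering ------------------------------------------------
#
# The fixture generator draws stylized rodent faces: a mid-gray elliptical
# face backdrop carrying a dark filled ellipse (eye) and a darker annulus
# segment (ear) on a light, seeded noise background. The shapes are not
# photorealistic — they reproduce the contrast structure a Haar detector
# keys on (dark compact feature on a lighter surround) while making exact
# ground-truth bounding boxes available for every rendered frame.

#' Face rendering specification
#'
#' Geometry in pixels at scale 1, intensities on the 0-255 gray scale. The
#' defaults keep at least 30 gray levels of contrast between each feature
#' and its surround.
#'
#' @param backdrop_axes half-axes (x, y) of the face-backdrop ellipse.
#' @param backdrop_value backdrop intensity.
#' @param eye_offset eye-center offset (x, y) from the face center.
#' @param eye_axes eye ellipse half-axes (x, y).
#' @param eye_value eye intensity.
#' @param ear_offset ear-center offset from the face center.
#' @param ear_radii ear annulus inner and outer radius.
#' @param ear_angles angular extent of the ear segment, degrees.
#' @param ear_value ear intensity.
#' @param bg_mean,bg_sd background noise field mean and standard deviation.
#' @return A `face_render_spec` list.
#' @export
face_render_spec <- function(backdrop_axes = c(26, 20), backdrop_value = 140,
                             eye_offset = c(-8, -5), eye_axes = c(6, 4),
                             eye_value = 60,
                             ear_offset = c(11, -13), ear_radii = c(4.5, 9),
                             ear_angles = c(-150, 90), ear_value = 40,
                             bg_mean = 200, bg_sd = 3) {
  structure(
    list(backdrop_axes = backdrop_axes, backdrop_value = backdrop_value,
         eye_offset = eye_offset, eye_axes = eye_axes, eye_value = eye_value,
         ear_offset = ear_offset, ear_radii = ear_radii,
         ear_angles = ear_angles, ear_value = ear_value,
         bg_mean = bg_mean, bg_sd = bg_sd),
    class = "face_render_spec"
  )
}

# Fill an ellipse into px (frame matrix, 0-based pixel coordinates); returns
# the modified matrix and the tight bounding box of the filled pixels.
fill_ellipse <- function(px, cx, cy, a, b, value) {
  H <- nrow(px); W <- ncol(px)
  xs <- max(0, floor(cx - a)):min(W - 1, ceiling(cx + a))
  ys <- max(0, floor(cy - b)):min(H - 1, ceiling(cy + b))
  if (length(xs) == 0 || length(ys) == 0) return(list(px = px, box = NULL))
  gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
  mask <- ((gx - cx) / a)^2 + ((gy - cy) / b)^2 <= 1
  if (!any(mask)) return(list(px = px, box = NULL))
  sub <- px[ys + 1, xs + 1, drop = FALSE]
  sub[mask] <- value
  px[ys + 1, xs + 1] <- sub
  cols <- xs[colSums(mask) > 0]; rows <- ys[rowSums(mask) > 0]
  list(px = px, box = rect(min(cols), min(rows),
                           max(cols) - min(cols) + 1,
                           max(rows) - min(rows) + 1))
}

# Fill an annulus segment (ring between r_in and r_out, angles in degrees,
# measured from +x axis, y pointing down).
fill_annulus_segment <- function(px, cx, cy, r_in, r_out, ang0, ang1, value) {
  H <- nrow(px); W <- ncol(px)
  xs <- max(0, floor(cx - r_out)):min(W - 1, ceiling(cx + r_out))
  ys <- max(0, floor(cy - r_out)):min(H - 1, ceiling(cy + r_out))
  if (length(xs) == 0 || length(ys) == 0) return(list(px = px, box = NULL))
  gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
  dx <- gx - cx; dy <- gy - cy
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) * 180 / pi
  in_arc <- if (ang1 >= ang0) ang >= ang0 & ang <= ang1 else ang >= ang0 | ang <= ang1
  mask <- r >= r_in & r <= r_out & in_arc
  if (!any(mask)) return(list(px = px, box = NULL))
  sub <- px[ys + 1, xs + 1, drop = FALSE]
  sub[mask] <- value
  px[ys + 1, xs + 1] <- sub
  cols <- xs[colSums(mask) > 0]; rows <- ys[rowSums(mask) > 0]
  list(px = px, box = rect(min(cols), min(rows),
                           max(cols) - min(cols) + 1,
                           max(rows) - min(rows) + 1))
}

#' Draw one stylized face into a frame
#'
#' @param px frame pixel matrix (modified copy returned).
#' @param cx,cy face center, frame coordinates.
#' @param spec a [face_render_spec()].
#' @param scale geometry scale factor.
#' @return List with `px` (frame with the face drawn), `eye_box` and
#'   `ear_box` (tight ground-truth rectangles).
#' @export
render_face <- function(px, cx, cy, spec = face_render_spec(), scale = 1) {
  s <- scale
  r1 <- fill_ellipse(px, cx, cy, spec$backdrop_axes[1] * s,
                     spec$backdrop_axes[2] * s, spec$backdrop_value)
  px <- r1$px
  r2 <- fill_annulus_segment(px, cx + spec$ear_offset[1] * s,
                             cy + spec$ear_offset[2] * s,
                             spec$ear_radii[1] * s, spec$ear_radii[2] * s,
                             spec$ear_angles[1], spec$ear_angles[2],
                             spec$ear_value)
  px <- r2$px
  r3 <- fill_ellipse(px, cx + spec$eye_offset[1] * s,
                     cy + spec$eye_offset[2] * s,
                     spec$eye_axes[1] * s, spec$eye_axes[2] * s,
                     spec$eye_value)
  list(px = r3$px, eye_box = r3$box, ear_box = r2$box)
}

# ---- Video scripting --------------------------------------------------------

#' Script a synthetic cage video
#'
#' A script fixes the stream geometry and a per-zone schedule of segments;
#' each segment states whether the face is visible in that zone and the
#' per-frame displacement magnitude (px) of its position path. Within a
#' segment the face bounces along a fixed diagonal inside a small box around
#' the zone anchor; a displacement of 0 freezes the zone pixels entirely, so
#' the motion-score noise floor is exactly 0 there.
#'
#' @param duration_s stream length, seconds.
#' @param fps frame rate, frames per second.
#' @param width,height frame dimensions, px.
#' @param segments data frame with columns `zone`, `start_s`, `end_s`,
#'   `present`, `displacement`; per zone the segments must tile
#'   `[0, duration_s)` without overlap.
#' @return A `video_script` list.
#' @export
video_script <- function(duration_s, fps, width, height, segments) {
  needed <- c("zone", "start_s", "end_s", "present", "displacement")
  stopifnot(all(needed %in% names(segments)), duration_s > 0, fps > 0)
  for (z in unique(segments$zone)) {
    seg <- segments[segments$zone == z, ]
    seg <- seg[order(seg$start_s), ]
    if (seg$start_s[1] != 0 || seg$end_s[nrow(seg)] != duration_s ||
        (nrow(seg) > 1 && any(seg$start_s[-1] != seg$end_s[-nrow(seg)]))) {
      stop("segments for zone '", z, "' must tile [0, ", duration_s,
           ") without gaps or overlap")
    }
  }
  structure(list(duration_s = duration_s, fps = fps, width = width,
                 height = height, segments = segments),
            class = "video_script")
}

#' Default fixture conditions: script, zones, face spec
#'
#' The default study-condition fixture is a 6-minute stream at 10 fps,
#' 320x180 px (the 16:9 aspect of the original 1920x1080 recordings at
#' desk scale), split into left/right cage zones. The face is visible in
#' the left zone for the first half and in the right zone for the second,
#' alternating still and moving segments, so the 3-minute interval logic is
#' exercised over two intervals per zone, each zone has one fully face-free
#' interval for the gap report, and still/moving segments probe the motion
#' ranking.
#'
#' @return `default_video_script()`: a [video_script()];
#'   `default_zones()`: list of two [cage_zone()]s;
#'   `default_zone_anchors()`: per-zone face anchor points.
#' @export
default_video_script <- function() {
  segments <- rbind(
    data.frame(zone = "left", start_s = c(0, 60, 120, 180),
               end_s = c(60, 120, 180, 360),
               present = c(TRUE, TRUE, TRUE, FALSE),
               displacement = c(0, 1.5, 0, 0)),
    data.frame(zone = "right", start_s = c(0, 180, 240, 300),
               end_s = c(180, 240, 300, 360),
               present = c(FALSE, TRUE, TRUE, TRUE),
               displacement = c(0, 0, 2, 0))
  )
  video_script(360, 10, 320, 180, segments)
}

#' @rdname default_video_script
#' @export
default_zones <- function() {
  list(cage_zone("left", 0, 0, 160, 180),
       cage_zone("right", 160, 0, 160, 180))
}

#' @rdname default_video_script
#' @export
default_zone_anchors <- function() {
  list(left = c(80, 90), right = c(240, 90))
}

# Per-frame face positions for one zone's schedule: bounce along direction
# (0.8, 0.6) inside +/- bounce px of the anchor; position resets to the
# anchor at each segment start. Returns data.frame(present, displacement,
# cx, cy) with one row per frame.
zone_positions <- function(script, zone, anchor, bounce = 8) {
  n <- round(script$duration_s * script$fps)
  seg <- script$segments[script$segments$zone == zone, ]
  seg <- seg[order(seg$start_s), ]
  out <- data.frame(present = rep(FALSE, n), displacement = 0,
                    cx = NA_real_, cy = NA_real_)
  dirv <- c(0.8, 0.6)
  for (i in seq_len(nrow(seg))) {
    f0 <- round(seg$start_s[i] * script$fps)
    f1 <- round(seg$end_s[i] * script$fps) - 1
    if (f1 < f0) next
    idx <- (f0:f1) + 1
    out$present[idx] <- seg$present[i]
    out$displacement[idx] <- seg$displacement[i]
    if (!seg$present[i]) next
    pos <- anchor
    vel <- dirv * seg$displacement[i]
    for (f in idx) {
      out$cx[f] <- pos[1]; out$cy[f] <- pos[2]
      if (seg$displacement[i] > 0) {
        pos <- pos + vel
        for (d in 1:2) {
          lo <- anchor[d] - bounce; hi <- anchor[d] + bounce
          if (pos[d] > hi) { pos[d] <- 2 * hi - pos[d]; vel[d] <- -vel[d] }
          if (pos[d] < lo) { pos[d] <- 2 * lo - pos[d]; vel[d] <- -vel[d] }
        }
      }
    }
  }
  out
}

#' Render a scripted synthetic cage video with ground truth
#'
#' Writes a decodable frame stack ([open_stream()] reads it back) and a
#' per-frame ground-truth table: for every frame and zone, whether the face
#' is visible, the tight eye and ear bounding boxes, the scripted per-frame
#' displacement, and the face center. The background of each zone is one
#' seeded Gaussian noise field, fixed for the whole stream, so frames in
#' zero-displacement segments are pixel-identical.
#'
#' @param script a [video_script()].
#' @param spec a [face_render_spec()].
#' @param out_path output stream path (`.tif`); ground truth is written to
#'   `<out_path>.truth.csv`.
#' @param zones list of [cage_zone()]s; default [default_zones()].
#' @param anchors named per-zone face anchors; default
#'   [default_zone_anchors()].
#' @param seed noise-field seed; the render is a pure function of
#'   script, spec, zones, anchors and seed.
#' @return List with `path`, `truth` (data frame), `stream`
#'   (a [frame_stream] on the written file).
#' @export
render_video <- function(script, spec = face_render_spec(), out_path,
                         zones = default_zones(),
                         anchors = default_zone_anchors(), seed = 1L) {
  stopifnot(inherits(script, "video_script"))
  n <- round(script$duration_s * script$fps)
  validate_zones(zones, script$width, script$height)
  zl <- vapply(zones, `[[`, "", "label")
  background <- withr::with_seed(as.integer(seed), {
    bg <- matrix(spec$bg_mean, script$height, script$width)
    for (z in zones) {
      noise <- matrix(stats::rnorm(z$width * z$height, 0, spec$bg_sd),
                      z$height, z$width)
      bg[(z$y + 1):(z$y + z$height), (z$x + 1):(z$x + z$width)] <-
        pmin(pmax(spec$bg_mean + noise, 0), 255)
    }
    round(bg)
  })
  pos <- lapply(zl, function(z) {
    zone_positions(script, z, anchors[[z]])
  })
  names(pos) <- zl

  frames <- vector("list", n)
  truth <- vector("list", n * length(zones))
  for (f in seq_len(n)) {
    px <- background
    for (zi in seq_along(zones)) {
      z <- zones[[zi]]
      p <- pos[[z$label]][f, ]
      eye_box <- ear_box <- NULL
      if (isTRUE(p$present)) {
        drawn <- render_face(px, p$cx, p$cy, spec)
        px <- drawn$px
        eye_box <- drawn$eye_box; ear_box <- drawn$ear_box
      }
      truth[[(f - 1) * length(zones) + zi]] <- data.frame(
        frame_index = f - 1L, timestamp_s = (f - 1) / script$fps,
        zone = z$label, present = isTRUE(p$present),
        displacement = p$displacement,
        cx = p$cx, cy = p$cy,
        eye_x = if (is.null(eye_box)) NA else eye_box[["x"]],
        eye_y = if (is.null(eye_box)) NA else eye_box[["y"]],
        eye_w = if (is.null(eye_box)) NA else eye_box[["w"]],
        eye_h = if (is.null(eye_box)) NA else eye_box[["h"]],
        ear_x = if (is.null(ear_box)) NA else ear_box[["x"]],
        ear_y = if (is.null(ear_box)) NA else ear_box[["y"]],
        ear_w = if (is.null(ear_box)) NA else ear_box[["w"]],
        ear_h = if (is.null(ear_box)) NA else ear_box[["h"]]
      )
    }
    frames[[f]] <- px
  }
  write_frame_stack(frames, out_path, script$fps,
                    source_id = tools::file_path_sans_ext(basename(out_path)))
  truth_df <- do.call(rbind, truth)
  utils::write.csv(truth_df, paste0(out_path, ".truth.csv"), row.names = FALSE)
  list(path = out_path, truth = truth_df, stream = open_stream(out_path))
}

# ---- Cascade training crops -------------------------------------------------

#' Generate a seeded cascade-training crop set
#'
#' Emulates hand-cropped eye/ear training examples harvested from real
#' frames: each positive is cut out of a fully rendered face scene (backdrop,
#' eye and ear on the noisy background), so crops carry the same surround a
#' scan window sees, with jittered position, scale and intensity. Byte-
#' identical for identical seeds. With `dir = NULL` the crops stay in
#' memory; with a directory they are written as PNGs plus an `index.csv`
#' (path, feature_kind, bbox_w, bbox_h).
#'
#' @param spec a [face_render_spec()].
#' @param kind `"eye"` or `"ear"`.
#' @param n_pos,n_neg crop counts (defaults 500, matching the roughly 500
#'   hand-cropped examples used to train the original detectors).
#' @param seed generation seed.
#' @param scale geometry scale factor (ground-truth boxes scale with it).
#' @param dir optional output directory.
#' @param crop_margin crop side as a multiple of the feature's larger
#'   bounding-box dimension (must match the detector's `object_frac`:
#'   `crop_margin = 1 / object_frac`).
#' @return List with `positives`, `negatives` (lists of matrices) and
#'   `index` (data frame; `path` columns filled only when `dir` is given).
#' @export
make_crop_set <- function(spec = face_render_spec(), kind = c("eye", "ear"),
                          n_pos = 500L, n_neg = 500L, seed = 1L, scale = 1,
                          dir = NULL, crop_margin = 1.25) {
  kind <- match.arg(kind)
  if (n_pos < 1 || n_neg < 1) stop("n_pos and n_neg must be >= 1")
  res <- withr::with_seed(as.integer(seed), {
    positives <- vector("list", n_pos)
    bbox_wh <- matrix(0, n_pos, 2)
    jitters <- scene_jitters(n_pos)
    for (i in seq_len(n_pos)) {
      sc <- render_scene_patch(spec, scale * jitters$s[i], jitters$val[i],
                               jitters$dx[i], jitters$dy[i])
      box <- if (kind == "eye") sc$eye_box else sc$ear_box
      positives[[i]] <- round(crop_around(sc$px, box, crop_margin))
      bbox_wh[i, ] <- c(box[["w"]], box[["h"]])
    }
    negatives <- lapply(seq_len(n_neg), function(i) {
      side <- round(stats::runif(1, 12, 28) * scale)
      if (i %% 2 == 0) {
        # plain featureless backdrop with noise
        matrix(pmin(pmax(stats::rnorm(side^2, spec$backdrop_value,
                                      spec$bg_sd), 0), 255), side, side)
      } else {
        matrix(pmin(pmax(stats::rnorm(side^2, spec$bg_mean, spec$bg_sd),
                         0), 255), side, side)
      }
    })
    list(positives = positives, negatives = lapply(negatives, round),
         bbox_wh = bbox_wh)
  })
  index <- data.frame(
    path = NA_character_,
    feature_kind = c(rep(kind, n_pos), rep("negative", n_neg)),
    bbox_w = c(res$bbox_wh[, 1], rep(NA, n_neg)),
    bbox_h = c(res$bbox_wh[, 2], rep(NA, n_neg))
  )
  if (!is.null(dir)) {
    dir.create(file.path(dir, "pos"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "neg"), recursive = TRUE, showWarnings = FALSE)
    paths <- character(n_pos + n_neg)
    for (i in seq_len(n_pos)) {
      paths[i] <- file.path(dir, "pos", sprintf("%s_%04d.png", kind, i))
      png::writePNG(res$positives[[i]] / 255, paths[i])
    }
    for (i in seq_len(n_neg)) {
      paths[n_pos + i] <- file.path(dir, "neg", sprintf("neg_%04d.png", i))
      png::writePNG(res$negatives[[i]] / 255, paths[n_pos + i])
    }
    index$path <- paths
    utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  }
  list(positives = res$positives, negatives = res$negatives, index = index)
}

# Per-sample jitters for scene rendering, drawn in one block so the count
# of noise values consumed by each patch cannot shift them.
scene_jitters <- function(n) {
  data.frame(s = stats::runif(n, 0.85, 1.25),
             val = stats::runif(n, -10, 10),
             dx = stats::runif(n, -2, 2),
             dy = stats::runif(n, -2, 2))
}

# Render one full face (backdrop + ear + eye) on a noisy background patch
# sized to the face geometry; returns the patch and ground-truth boxes.
render_scene_patch <- function(spec, s, val_jit, dx, dy) {
  patch <- ceiling(3.2 * max(spec$backdrop_axes) * max(1, s))
  px <- matrix(pmin(pmax(stats::rnorm(patch^2, spec$bg_mean, spec$bg_sd),
                         0), 255), patch, patch)
  sp <- spec
  sp$eye_value <- sp$eye_value + val_jit
  sp$ear_value <- sp$ear_value + val_jit
  drawn <- render_face(round(px), patch / 2 + dx, patch / 2 + dy, sp,
                       scale = s)
  drawn
}

# Square crop of side margin * max(box dims), centered on the box, clipped
# to the patch.
crop_around <- function(px, box, margin, offset = c(0, 0)) {
  side <- ceiling(margin * max(box[["w"]], box[["h"]]))
  side <- min(side, nrow(px), ncol(px))
  bc <- rect_center(box)
  x0 <- round(bc[["x"]] - side / 2 + offset[1])
  y0 <- round(bc[["y"]] - side / 2 + offset[2])
  x0 <- min(max(x0, 0), ncol(px) - side)
  y0 <- min(max(y0, 0), nrow(px) - side)
  rect_pixels(px, rect(x0, y0, side, side))
}

#' Generate near-miss distractor crops for cascade training
#'
#' Plain background negatives make the detection problem too easy: a
#' classifier that accepts any dark blob separates them perfectly, then
#' confuses eyes with ears and fires at wrong scales when scanning. This
#' generator cuts the near misses out of rendered face scenes: crops of the
#' *other* feature kind, own-kind features off-center inside a larger
#' context window (wrong scale and position), and backdrop-edge crops.
#'
#' @inheritParams make_crop_set
#' @param kind the feature kind the cascade is being trained FOR; the
#'   distractors are what it must reject.
#' @param n number of distractor crops.
#' @return List of crop matrices.
#' @export
make_distractor_set <- function(spec = face_render_spec(),
                                kind = c("eye", "ear"), n = 500L, seed = 1L,
                                scale = 1) {
  kind <- match.arg(kind)
  withr::with_seed(as.integer(seed), {
    n1 <- ceiling(n / 3); n2 <- ceiling(n / 3); n3 <- n - n1 - n2
    jit_a <- scene_jitters(n1)
    # (a) the other feature, centered, as a positive crop would be
    other <- lapply(seq_len(n1), function(i) {
      sc <- render_scene_patch(spec, scale * jit_a$s[i], jit_a$val[i],
                               jit_a$dx[i], jit_a$dy[i])
      box <- if (kind == "eye") sc$ear_box else sc$eye_box
      round(crop_around(sc$px, box, 1.25))
    })
    # (b) own-kind feature off-center in a 2-3.5x context window
    jit_b <- scene_jitters(n2)
    ctx <- lapply(seq_len(n2), function(i) {
      sc <- render_scene_patch(spec, scale * jit_b$s[i], jit_b$val[i],
                               jit_b$dx[i], jit_b$dy[i])
      box <- if (kind == "eye") sc$eye_box else sc$ear_box
      m <- stats::runif(1, 2.2, 3.5)
      off <- stats::runif(2, -0.4, 0.4) * m * max(box[["w"]], box[["h"]])
      round(crop_around(sc$px, box, m, offset = off))
    })
    # (c) backdrop/background boundary crops
    edges <- lapply(seq_len(n3), function(i) {
      side <- round(stats::runif(1, 12, 30) * scale)
      px <- matrix(pmin(pmax(stats::rnorm(side^2, spec$bg_mean, spec$bg_sd),
                             0), 255), side, side)
      split_at <- round(stats::runif(1, 0.3, 0.7) * side)
      if (stats::runif(1) < 0.5) {
        px[, seq_len(split_at)] <- pmin(pmax(
          stats::rnorm(side * split_at, spec$backdrop_value, spec$bg_sd),
          0), 255)
      } else {
        px[seq_len(split_at), ] <- pmin(pmax(
          stats::rnorm(side * split_at, spec$backdrop_value, spec$bg_sd),
          0), 255)
      }
      round(px)
    })
    c(other, ctx, edges)
  })
}

#' Train the default eye and ear cascades for the synthetic face domain
#'
#' The packaged training recipe: positives from [make_crop_set()], negatives
#' from the same generator's background crops plus near-miss distractors
#' ([make_distractor_set()]). Because positives and distractors are cut out
#' of fully rendered scenes, the training distribution matches what the
#' scanner evaluates and no bootstrap mining pass is needed by default
#' (`bootstrap_frames` can turn one on). Deterministic for a fixed seed.
#' Users with real footage supply their own crop sets to [train_cascade()]
#' instead.
#'
#' @param spec a [face_render_spec()].
#' @param n_pos positives per cascade (default 500, the rough size of the
#'   original hand-cropped training sets).
#' @param n_neg background negatives per cascade.
#' @param n_hard near-miss distractor negatives per cascade.
#' @param seed master seed.
#' @param params training configuration ([haar_params()]); its `seed` is
#'   derived from `seed`.
#' @return Named list with trained `eye` and `ear` `haar_cascade`s.
#' @export
train_default_cascades <- function(spec = face_render_spec(), n_pos = 500L,
                                   n_neg = 250L, n_hard = 500L, seed = 1L,
                                   params = haar_params(),
                                   bootstrap_frames = 0L) {
  seeds <- withr::with_seed(as.integer(seed), sample.int(1e6, 8))
  sets <- list(); out <- list()
  kinds <- c("eye", "ear")
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    set <- make_crop_set(spec, kind, n_pos = n_pos, n_neg = n_neg,
                         seed = seeds[2 * i - 1])
    hard <- make_distractor_set(spec, kind, n = n_hard, seed = seeds[2 * i])
    sets[[kind]] <- list(pos = set$positives, neg = c(set$negatives, hard))
    params$seed <- seeds[4 + i]
    out[[kind]] <- train_cascade(sets[[kind]]$pos, sets[[kind]]$neg,
                                 kind, params)
  }
  if (bootstrap_frames > 0) {
    mined <- mine_hard_negatives(out, spec, n_frames = bootstrap_frames,
                                 seed = seeds[7])
    for (i in seq_along(kinds)) {
      kind <- kinds[i]
      if (length(mined[[kind]]) == 0) next
      params$seed <- seeds[4 + i]
      out[[kind]] <- train_cascade(sets[[kind]]$pos,
                                   c(sets[[kind]]$neg, mined[[kind]]),
                                   kind, params)
    }
  }
  out
}

# Bootstrap hard-negative mining: scan rendered frames with the current
# cascades (no neighbor suppression) and harvest every raw window that does
# not overlap the ground-truth box of its own kind. Retraining with these
# windows teaches the cascade to reject wrong-scale and wrong-feature hits
# the crop-level negatives never show it.
mine_hard_negatives <- function(models, spec, n_frames = 12L, seed = 1L,
                                iou_cut = 0.1, contain_cut = 0.5,
                                max_per_kind = 600L) {
  zone <- cage_zone("mine", 0, 0, 160, 180)
  loose <- scan_params(min_neighbors = 1L)
  # harvest full scan windows (not margin-shrunk reports): the negatives
  # must match the distribution the scanner evaluates
  models <- lapply(models, function(m) {
    m$object_frac <- 1
    m
  })
  withr::with_seed(as.integer(seed), {
    mined <- list(eye = list(), ear = list())
    for (f in seq_len(n_frames)) {
      bg <- matrix(pmin(pmax(stats::rnorm(160 * 180, spec$bg_mean,
                                          spec$bg_sd), 0), 255), 180, 160)
      cx <- stats::runif(1, 45, 115); cy <- stats::runif(1, 45, 135)
      drawn <- render_face(round(bg), cx, cy, spec)
      fr <- frame_ref("mine", f - 1L, 0, drawn$px)
      truth <- list(eye = drawn$eye_box, ear = drawn$ear_box)
      det <- detect_features(fr, zone, models, loose)
      for (kind in names(mined)) {
        dk <- det[det$feature_kind == kind, , drop = FALSE]
        if (nrow(dk) == 0) next
        for (r in seq_len(nrow(dk))) {
          box <- rect(dk$x[r], dk$y[r], dk$w[r], dk$h[r])
          # a window overlapping the true feature, or swallowing most of
          # it at a larger scale, is a near-positive: labeling it negative
          # would teach the cascade to reject true matched-scale windows
          inter <- rect_intersect(box, truth[[kind]])
          contained <- if (is.null(inter)) 0 else {
            rect_area(inter) / rect_area(truth[[kind]])
          }
          if (rect_iou(box, truth[[kind]]) < iou_cut &&
              contained < contain_cut &&
              length(mined[[kind]]) < max_per_kind) {
            mined[[kind]][[length(mined[[kind]]) + 1L]] <-
              rect_pixels(drawn$px, box)
          }
        }
      }
    }
    mined
  })
}

# ---- Statistical fixtures ---------------------------------------------------

#' Simulate a ratings matrix with known variance components
#'
#' Draws scores from the additive two-way model
#' `y[i, j] = 1 + s[i] + r[j] + e[ij]` (subject, rater and residual effects
#' independent normal with the given variances, scaled so 2.5 total SDs fit
#' the half-range), then clips to the 0-2 score range. The closed-form
#' population ICCs of the pre-clipping model are returned alongside:
#' single-measure absolute agreement `s / (s + r + e)`, average-measure
#' absolute `s / (s + (r + e) / k)`, and the consistency versions without
#' `r`.
#'
#' @param n_subjects,n_raters matrix dimensions.
#' @param var_subject,var_rater,var_error variance components (>= 0, not all
#'   zero).
#' @param seed mandatory generation seed.
#' @return List with `scores` (matrix), `population_icc` (named vector),
#'   `clipped` (fraction of cells clipped).
#' @export
simulate_ratings <- function(n_subjects, n_raters, var_subject, var_rater,
                             var_error, seed) {
  if (any(c(var_subject, var_rater, var_error) < 0)) {
    stop("variance components must be >= 0")
  }
  total <- var_subject + var_rater + var_error
  if (total == 0) stop("degenerate simulation: all variance components zero")
  k <- n_raters
  icc <- c(
    single_absolute = var_subject / total,
    average_absolute = var_subject / (var_subject + (var_rater + var_error) / k),
    single_consistency = var_subject / (var_subject + var_error),
    average_consistency = var_subject / (var_subject + var_error / k)
  )
  scl <- 1 / (2.5 * sqrt(total))
  scores <- withr::with_seed(as.integer(seed), {
    s <- stats::rnorm(n_subjects, 0, sqrt(var_subject))
    r <- stats::rnorm(n_raters, 0, sqrt(var_rater))
    e <- matrix(stats::rnorm(n_subjects * n_raters, 0, sqrt(var_error)),
                n_subjects, n_raters)
    raw <- 1 + scl * (outer(s, r, `+`) + e)
    pmin(pmax(raw, 0), 2)
  })
  clipped <- mean(scores == 0 | scores == 2)
  list(scores = scores, population_icc = icc, clipped = clipped)
}

#' Simulate a dose-response cohort with known AD50
#'
#' Per-animal grimace responses follow a linear %MPE-vs-log10(dose) effect
#' curve passing 50% at `true_ad50`, mapped back to the score scale between
#' the vehicle mean and the baseline level, plus Gaussian noise, clipped to
#' `[0, 2]`. A vehicle group is always included. The default true AD50 of
#' 0.8 mg/kg mirrors the morphine potency the workflow is meant to resolve.
#'
#' @param true_ad50 dose at 50% effect, mg/kg.
#' @param slope %MPE per decade of dose.
#' @param doses non-vehicle dose levels, mg/kg.
#' @param n_per_group animals per group (vehicle included).
#' @param noise_sd per-animal noise on the score scale.
#' @param vehicle_mean mean score of the vehicle (pain, untreated) group.
#' @param baseline_level mean score of uninjured animals.
#' @param seed mandatory generation seed.
#' @return List with `data` (data frame `animal_id`, `dose`, `response`;
#'   vehicle rows have `dose = 0`) and `true` (the generating parameters).
#' @export
simulate_dose_response <- function(true_ad50 = 0.8, slope = 60,
                                   doses = c(1, 2, 5), n_per_group = 8L,
                                   noise_sd = 0.2, vehicle_mean = 1.4,
                                   baseline_level = 0.4, seed) {
  stopifnot(all(doses > 0), n_per_group >= 1)
  all_doses <- c(0, doses)
  data <- withr::with_seed(as.integer(seed), {
    rows <- lapply(all_doses, function(d) {
      mpe <- if (d == 0) 0 else 50 + slope * (log10(d) - log10(true_ad50))
      mu <- vehicle_mean - (vehicle_mean - baseline_level) * mpe / 100
      data.frame(dose = d,
                 response = pmin(pmax(mu + stats::rnorm(n_per_group, 0,
                                                        noise_sd), 0), 2))
    })
    out <- do.call(rbind, rows)
    out$animal_id <- sprintf("rat%02d", seq_len(nrow(out)))
    out[, c("animal_id", "dose", "response")]
  })
  list(data = data,
       true = list(ad50 = true_ad50, slope = slope, doses = doses,
                   n_per_group = n_per_group, noise_sd = noise_sd,
                   vehicle_mean = vehicle_mean,
                   baseline_level = baseline_level))
}

#' Simulate human scoring of a blinded image set
#'
#' A test bed for the scoring-session and statistics modules: given an
#' unblinding key with a `condition` column, draws per-scorer action-unit
#' scores around condition-dependent means (then discretized to 0/1/2) and a
#' dichotomous pain call per scorer and image from the scorer's own mean
#' score.
#'
#' @param key a `scoring_manifest` key data frame (needs `blinded_id` and
#'   `condition`).
#' @param n_scorers number of simulated scorers.
#' @param seed generation seed.
#' @param pain_mean,no_pain_mean latent unit-score means per condition.
#' @param sd latent score noise.
#' @param call_threshold pain call iff the scorer's mean score exceeds this.
#' @return List with `scores` (rows scorer x image with unit columns) and
#'   `judgments` (`blinded_id`, `scorer_id`, `call`).
#' @export
simulate_scores <- function(key, n_scorers = 5L, seed = 1L,
                            pain_mean = 1.4, no_pain_mean = 0.4, sd = 0.45,
                            call_threshold = 0.9) {
  stopifnot(all(c("blinded_id", "condition") %in% names(key)))
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (s in seq_len(n_scorers)) {
      for (i in seq_len(nrow(key))) {
        mu <- if (tolower(key$condition[i]) == "pain") pain_mean else no_pain_mean
        units <- pmin(pmax(round(stats::rnorm(4, mu, sd)), 0), 2)
        rows[[length(rows) + 1]] <- data.frame(
          blinded_id = key$blinded_id[i],
          scorer_id = sprintf("scorer%d", s),
          orbital_tightening = units[1], nose_cheek_flattening = units[2],
          ear_changes = units[3], whisker_change = units[4]
        )
      }
    }
    scores <- do.call(rbind, rows)
    m <- rowMeans(scores[, rgs_units])
    judgments <- data.frame(blinded_id = scores$blinded_id,
                            scorer_id = scores$scorer_id,
                            call = ifelse(m > call_threshold, "pain",
                                          "no_pain"))
    list(scores = scores, judgments = judgments)
  })
}
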