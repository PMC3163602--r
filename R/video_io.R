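#' Frame streams: decode video into timestamped grayscale frames
#'
#' The pipeline's video input is an 8-bit grayscale image-stack stream: a
#' multi-page TIFF holding one page per frame, with an optional JSON sidecar
#' (`<path>.json`) carrying the frame rate and a source identifier. The
#' fixtures module ([render_video()]) writes exactly this format, so the whole
#' pipeline round-trips on files it can itself produce. Frames are converted
#' to single-channel intensities in `[0, 255]` on decode (color pages are
#' reduced by ITU-R 601 luma), so all downstream detection and motion math is
#' single-channel.
#'
#' @param path path to the frame-stack file.
#' @param fps_override optional frame rate overriding the sidecar (frames per
#'   second; timestamps are `frame_index / fps`).
#' @return An object of class `frame_stream` with fields `path`, `source_id`,
#'   `n_frames`, `fps`, `width`, `height`.
#' @seealso [read_frames()] to decode frames, [render_video()] to write
#'   synthetic streams.
#' @export
open_stream <- function(path, fps_override = NULL) {
  if (!file.exists(path)) {
    stop("video stream not found: ", path)
  }
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  first <- tryCatch(
    tiff::readTIFF(path, all = 1L),
    error = function(e) {
      stop("cannot decode '", path, "' as a TIFF frame stack: ",
           conditionMessage(e))
    }
  )
  if (is.list(first)) first <- first[[1]]
  # page count: trust the sidecar (our writer records it); a foreign stack
  # without one needs a full decode, the only reliable count
  n_frames <- meta$n_frames %||% length(tiff::readTIFF(path, all = TRUE))
  if (n_frames < 1) stop("frame stack '", path, "' holds no frames")
  fps <- fps_override %||% meta$fps %||% 30
  if (!is.numeric(fps) || fps <= 0) stop("fps must be a positive rate")
  dims <- dim(first)
  structure(
    list(
      path = path,
      source_id = meta$source_id %||% tools::file_path_sans_ext(basename(path)),
      n_frames = as.integer(n_frames),
      fps = as.numeric(fps),
      height = dims[1],
      width = dims[2]
    ),
    class = "frame_stream"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream '%s': %d frames, %dx%d px, %.3g fps (%.1f s)>\n",
              x$source_id, x$n_frames, x$width, x$height, x$fps,
              x$n_frames / x$fps))
  invisible(x)
}

#' Construct a single frame reference
#'
#' A `frame_ref` bundles one decoded frame with its stream identity: the
#' 0-based frame index, the timestamp in seconds from stream start, and the
#' grayscale pixel matrix (rows = y, columns = x, intensities in `[0, 255]`).
#'
#' @param source_id opaque identifier of the source stream.
#' @param frame_index integer frame position, 0-based.
#' @param timestamp_s seconds from stream start.
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @return An object of class `frame_ref`.
#' @export
frame_ref <- function(source_id, frame_index, timestamp_s, pixels) {
  stopifnot(is.matrix(pixels), frame_index >= 0, timestamp_s >= 0)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("frame intensities must lie in [0, 255]")
  }
  structure(
    list(source_id = source_id, frame_index = as.integer(frame_index),
         timestamp_s = as.numeric(timestamp_s), pixels = pixels),
    class = "frame_ref"
  )
}

# Reduce a decoded TIFF page to a 0..255 grayscale matrix.
page_to_gray <- function(page) {
  if (length(dim(page)) == 3) {
    # ITU-R 601 luma; alpha (4th channel) ignored
    page <- 0.299 * page[, , 1] + 0.587 * page[, , 2] + 0.114 * page[, , 3]
  }
  round(page * 255)
}

#' Read frames from a stream
#'
#' Decodes the requested frames (by default all of them) and returns them as
#' `frame_ref` objects. Reads are indexed, so long streams can be processed in
#' chunks without holding the whole stack in memory.
#'
#' @param stream a `frame_stream` from [open_stream()].
#' @param indices 0-based frame indices; default all frames in order.
#' @return A list of [frame_ref()] objects.
#' @export
read_frames <- function(stream, indices = NULL) {
  stopifnot(inherits(stream, "frame_stream"))
  if (is.null(indices)) indices <- seq_len(stream$n_frames) - 1L
  indices <- as.integer(indices)
  if (any(indices < 0 | indices >= stream$n_frames)) {
    stop("frame indices out of range [0, ", stream$n_frames - 1L, "]")
  }
  pages <- tiff::readTIFF(stream$path, all = indices + 1L)
  if (length(indices) == 1L && !is.list(pages)) pages <- list(pages)
  Map(function(idx, page) {
    frame_ref(stream$source_id, idx, idx / stream$fps, page_to_gray(page))
  }, indices, pages)
}

#' Write a grayscale frame stack
#'
#' The writer behind [render_video()]: stores frames as an 8-bit multi-page
#' TIFF plus a JSON sidecar with `fps` and `source_id`, the format
#' [open_stream()] reads.
#'
#' @param frames list of numeric matrices with intensities in `[0, 255]`, all
#'   the same dimensions.
#' @param path output path (`.tif`).
#' @param fps frame rate in frames per second.
#' @param source_id stream identifier recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(frames, path, fps, source_id = "stream") {
  stopifnot(length(frames) >= 1, fps > 0)
  dims <- dim(frames[[1]])
  pages <- lapply(frames, function(f) {
    if (!identical(dim(f), dims)) stop("all frames must share dimensions")
    f / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "deflate")
  jsonlite::write_json(list(fps = fps, source_id = source_id,
                            n_frames = length(frames)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Define and validate per-cage analysis zones
#'
#' A cage zone is the sub-rectangle of the frame corresponding to one
#' animal's cubicle; the left and right cages are analyzed separately.
#' Zones come from a YAML config of the form:
#'
#' ```yaml
#' frame: {width: 320, height: 180}
#' zones:
#'   - {label: left,  x: 0,   y: 0, width: 160, height: 180}
#'   - {label: right, x: 160, y: 0, width: 160, height: 180}
#' ```
#'
#' @param config path to a YAML zone config, or an already-parsed list of the
#'   same shape.
#' @return A list of `cage_zone` objects (fields `label`, `x`, `y`, `width`,
#'   `height`).
#' @export
load_zones <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$zones) || length(cfg$zones) == 0) {
    stop("zone config must declare at least one zone")
  }
  frame_w <- cfg$frame$width
  frame_h <- cfg$frame$height
  zones <- lapply(cfg$zones, function(z) {
    cage_zone(z$label, z$x, z$y, z$width, z$height)
  })
  validate_zones(zones, frame_w, frame_h)
  zones
}

#' @rdname load_zones
#' @param label zone label, e.g. `"left"` or `"right"`.
#' @param x,y,width,height zone rectangle (0-based, half-open).
#' @export
cage_zone <- function(label, x, y, width, height) {
  if (is.null(label) || !nzchar(label)) stop("zone label must be non-empty")
  if (x < 0 || y < 0) stop("zone '", label, "': origin must be non-negative")
  if (width <= 0 || height <= 0) {
    stop("zone '", label, "': width and height must be positive")
  }
  structure(
    list(label = as.character(label), x = as.integer(x), y = as.integer(y),
         width = as.integer(width), height = as.integer(height)),
    class = "cage_zone"
  )
}

zone_rect <- function(zone) rect(zone$x, zone$y, zone$width, zone$height)

# Shared zone validation: in-bounds (if frame dims known), unique labels,
# pairwise non-overlap. Errors name the offending zone labels.
validate_zones <- function(zones, frame_w = NULL, frame_h = NULL) {
  labels <- vapply(zones, `[[`, "", "label")
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0) {
    stop("duplicate zone labels: ", paste(unique(dup), collapse = ", "))
  }
  if (!is.null(frame_w) && !is.null(frame_h)) {
    frame <- rect(0, 0, frame_w, frame_h)
    for (z in zones) {
      if (!rect_inside(zone_rect(z), frame)) {
        stop("zone '", z$label, "' extends outside the ", frame_w, "x",
             frame_h, " frame")
      }
    }
  }
  if (length(zones) > 1) {
    for (i in seq_len(length(zones) - 1)) {
      for (j in seq(i + 1, length(zones))) {
        if (!is.null(rect_intersect(zone_rect(zones[[i]]),
                                    zone_rect(zones[[j]])))) {
          stop("zones '", zones[[i]]$label, "' and '", zones[[j]]$label,
               "' overlap")
        }
      }
    }
  }
  invisible(zones)
}

# Check a zone fits a given frame matrix.
check_zone_in_frame <- function(zone, pixels) {
  frame <- rect(0, 0, ncol(pixels), nrow(pixels))
  if (!rect_inside(zone_rect(zone), frame)) {
    stop("zone '", zone$label, "' lies outside the frame")
  }
  invisible(TRUE)
}

#' Export a cropped frame region as a lossless image
#'
#' Writes the region pixels as 8-bit grayscale PNG (lossless; a write→read
#' round trip is bit-exact). No source metadata — timestamps, condition,
#' animal identity — is embedded, so exported images are safe to hand to
#' blinded scorers.
#'
#' @param frame a [frame_ref()].
#' @param region rectangle ([rect()]) inside the frame.
#' @param out_path output file; format chosen by extension (`.png` lossless
#'   default; `.jpg`/`.jpeg` optional lossy export).
#' @param jpeg_quality quality in `(0, 1]` for JPEG output.
#' @return `out_path`, invisibly.
#' @export
export_image <- function(frame, region, out_path, jpeg_quality = 0.95) {
  stopifnot(inherits(frame, "frame_ref"))
  frame_rect <- rect(0, 0, ncol(frame$pixels), nrow(frame$pixels))
  region <- rect(region[["x"]], region[["y"]], region[["w"]], region[["h"]])
  if (!rect_inside(region, frame_rect)) {
    stop("export region lies outside the frame")
  }
  px <- rect_pixels(frame$pixels, region) / 255
  ext <- tolower(tools::file_ext(out_path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("JPEG export requires the 'jpeg' package; use PNG")
    }
    jpeg::writeJPEG(px, out_path, quality = jpeg_quality)
  } else {
    png::writePNG(px, out_path)
  }
  invisible(out_path)
}

#' Read an exported grayscale image back as a pixel matrix
#'
#' @param path a PNG written by [export_image()] or [make_crop_set()].
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  round(px * 255)
}
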