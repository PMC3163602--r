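#' Rectangle helpers
#'
#' All rectangles in the package use one convention: 0-based integer
#' coordinates with the origin at the top-left of the frame, and half-open
#' extents, so a rectangle `c(x, y, w, h)` covers columns `[x, x + w)` and
#' rows `[y, y + h)`.
#'
#' @param x,y top-left corner (0-based).
#' @param w,h width and height (must be > 0).
#' @return A named numeric vector `c(x =, y =, w =, h =)`.
#' @export
rect <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) stop("rectangle width and height must be positive")
  c(x = as.numeric(x), y = as.numeric(y), w = as.numeric(w), h = as.numeric(h))
}

rect_x2 <- function(r) unname(r[["x"]] + r[["w"]])
rect_y2 <- function(r) unname(r[["y"]] + r[["h"]])

rect_center <- function(r) {
  c(x = unname(r[["x"]] + r[["w"]] / 2), y = unname(r[["y"]] + r[["h"]] / 2))
}

rect_area <- function(r) unname(r[["w"]] * r[["h"]])

#' @rdname rect
#' @param a,b rectangles as returned by [rect()].
#' @export
rect_intersect <- function(a, b) {
  x1 <- max(a[["x"]], b[["x"]])
  y1 <- max(a[["y"]], b[["y"]])
  x2 <- min(rect_x2(a), rect_x2(b))
  y2 <- min(rect_y2(a), rect_y2(b))
  if (x2 <= x1 || y2 <= y1) return(NULL)
  rect(x1, y1, x2 - x1, y2 - y1)
}

#' @rdname rect
#' @export
rect_union_bbox <- function(a, b) {
  x1 <- min(a[["x"]], b[["x"]])
  y1 <- min(a[["y"]], b[["y"]])
  x2 <- max(rect_x2(a), rect_x2(b))
  y2 <- max(rect_y2(a), rect_y2(b))
  rect(x1, y1, x2 - x1, y2 - y1)
}

#' Intersection-over-union of two rectangles
#' @param a,b rectangles.
#' @return IoU in `[0, 1]`.
#' @export
rect_iou <- function(a, b) {
  i <- rect_intersect(a, b)
  if (is.null(i)) return(0)
  ia <- rect_area(i)
  ia / (rect_area(a) + rect_area(b) - ia)
}

# TRUE iff inner lies fully inside outer (half-open containment)
rect_inside <- function(inner, outer) {
  inner[["x"]] >= outer[["x"]] && inner[["y"]] >= outer[["y"]] &&
    rect_x2(inner) <= rect_x2(outer) && rect_y2(inner) <= rect_y2(outer)
}

# Clip a rectangle to an outer rectangle; errors if the result is empty.
rect_clip <- function(r, outer) {
  i <- rect_intersect(r, outer)
  if (is.null(i)) stop("rectangle lies entirely outside the clipping region")
  i
}

# Extract the pixels of a rectangle from a frame matrix (rows = y, cols = x).
rect_pixels <- function(pixels, r) {
  pixels[(r[["y"]] + 1):rect_y2(r), (r[["x"]] + 1):rect_x2(r), drop = FALSE]
}
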