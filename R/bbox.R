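#' Axis-aligned bounding box
#'
#' The tracker's unit of annotation and output. Coordinates are continuous
#' pixels in a 0-based frame with the origin at the top-left corner, `x`
#' running along columns and `y` along rows. A box covers the half-open
#' region `[x, x + w) x [y, y + h)`, so its area is exactly `w * h` and two
#' boxes sharing only an edge do not intersect.
#'
#' @param x Left edge (px).
#' @param y Top edge (px).
#' @param w Width (px), strictly positive.
#' @param h Height (px), strictly positive.
#' @return An object of class `bbox` with fields `x`, `y`, `w`, `h`.
#' @examples
#' b <- bbox(10, 20, 8, 8)
#' bbox_center(b)
#' @export
bbox <- function(x, y, w, h) {
  vals <- c(x = as.numeric(x), y = as.numeric(y),
            w = as.numeric(w), h = as.numeric(h))
  if (any(!is.finite(vals))) stopf("bbox: all fields must be finite")
  if (vals[["w"]] <= 0 || vals[["h"]] <= 0) {
    stopf("bbox: width and height must be > 0 (got w=%g, h=%g)",
          vals[["w"]], vals[["h"]])
  }
  structure(as.list(vals), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%.3f y=%.3f w=%.3f h=%.3f>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

is_bbox <- function(b) inherits(b, "bbox")

#' Center of a bounding box
#'
#' @param b A [bbox()].
#' @return Numeric `c(x, y)` of the box center.
#' @export
bbox_center <- function(b) {
  stopifnot(is_bbox(b))
  c(b$x + b$w / 2, b$y + b$h / 2)
}

# Build a box from its center and size.
bbox_from_center <- function(cx, cy, w, h) bbox(cx - w / 2, cy - h / 2, w, h)

# Is the box center inside a height x width frame?
center_in_frame <- function(b, height, width) {
  ctr <- bbox_center(b)
  ctr[1] >= 0 && ctr[1] <= width && ctr[2] >= 0 && ctr[2] <= height
}
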