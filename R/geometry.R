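# Crop geometry and ROI alignment.

# Crop a square region of side `side` centered at (cx, cy) from a frame and
# resample it to out_size x out_size by bilinear interpolation; out-of-frame
# pixels are padded with the frame's mean intensity.
crop_patch <- function(frame, cx, cy, side, out_size) {
  out_size <- as.integer(out_size)
  if (out_size < 8L) stopf("crop: out_size must be >= 8")
  if (side <= 0) stopf("crop: side must be > 0")
  scale <- side / out_size
  x0 <- cx - side / 2
  y0 <- cy - side / 2
  xs <- x0 + (seq_len(out_size) - 0.5) * scale
  ys <- y0 + (seq_len(out_size) - 0.5) * scale
  pad <- mean(frame$pixels)
  gx <- rep(xs, each = out_size)
  gy <- rep(ys, times = out_size)
  patch <- matrix(bilinear_sample(frame$pixels, gx, gy, pad = pad),
                  out_size, out_size)
  list(patch = patch, affine = list(scale = scale, x0 = x0, y0 = y0),
       side = side)
}

# Context-augmented crop side for a box: s = sqrt((w + p) (h + p)) with
# p = context_factor * (w + h).
crop_side <- function(box, context_factor) {
  p <- context_factor * (box$w + box$h)
  sqrt((box$w + p) * (box$h + p))
}

#' Crop a context-padded square patch around a box
#'
#' Crops the square of side `s = sqrt((w + p)(h + p))`, `p = context_factor *
#' (w + h)`, centered on the box center, pads out-of-frame regions with the
#' frame's mean intensity, and resamples to `out_size` x `out_size` by
#' bilinear interpolation. The returned `affine` (`image = patch * scale +
#' offset`) maps patch coordinates back to image coordinates exactly.
#'
#' @param frame A [frame_image()].
#' @param box A [bbox()].
#' @param context_factor Context amount (see [tracker_config()]).
#' @param out_size Output side in pixels, >= 8.
#' @return `list(patch, affine = list(scale, x0, y0), side)`.
#' @export
crop_and_resize <- function(frame, box, context_factor, out_size) {
  stopifnot(inherits(frame, "frame_image"), is_bbox(box))
  ctr <- bbox_center(box)
  crop_patch(frame, ctr[1], ctr[2], crop_side(box, context_factor), out_size)
}

#' ROI align: continuous bilinear resampling of a feature map
#'
#' Each output cell is the bilinear sample of the input feature grid at the
#' cell's center, computed in continuous feature coordinates without integer
#' snapping; samples beyond the grid replicate the border cells. The output
#' geometry (`stride`, `origin`) is recomputed from the ROI.
#'
#' @param fmap A [feature_map()].
#' @param roi A [bbox()] in image coordinates; must overlap the feature
#'   map's spatial extent.
#' @param out_rows,out_cols Output grid shape.
#' @return A [feature_map()] of shape `out_rows` x `out_cols`.
#' @export
roi_align <- function(fmap, roi, out_rows, out_cols) {
  stopifnot(inherits(fmap, "feature_map"), is_bbox(roi))
  d <- fmap_dims(fmap)
  # spatial extent of the grid in image coordinates (cell edges)
  ex0 <- fmap$origin[1] - fmap$stride / 2
  ex1 <- fmap$origin[1] + (d[2] - 0.5) * fmap$stride
  ey0 <- fmap$origin[2] - fmap$stride / 2
  ey1 <- fmap$origin[2] + (d[1] - 0.5) * fmap$stride
  if (roi$x >= ex1 || roi$x + roi$w <= ex0 || roi$y >= ey1 || roi$y + roi$h <= ey0) {
    stopf("roi_align: roi is disjoint from the feature map extent")
  }
  xs <- roi$x + (seq_len(out_cols) - 0.5) * roi$w / out_cols
  ys <- roi$y + (seq_len(out_rows) - 0.5) * roi$h / out_rows
  # continuous feature coordinates (cell j center at j)
  fc <- (xs - fmap$origin[1]) / fmap$stride + 1
  fr <- (ys - fmap$origin[2]) / fmap$stride + 1
  gc <- rep(fc, each = out_rows)
  gr <- rep(fr, times = out_cols)
  grid <- array(0, dim = c(out_rows, out_cols, d[3]))
  for (ch in seq_len(d[3])) {
    grid[, , ch] <- matrix(bilinear_at(fmap$grid[, , ch], gc, gr, pad = NULL),
                           out_rows, out_cols)
  }
  feature_map(grid,
              stride = sqrt((roi$w / out_cols) * (roi$h / out_rows)),
              origin = c(xs[1], ys[1]))
}
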