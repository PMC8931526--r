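# Handcrafted feature extraction.
#
# The feature extractor is pluggable through a registry so that a learned
# extractor can be swapped in without touching the matching pipeline. The
# default "pix-grad" extractor is deterministic and translation-equivariant:
# shifting patch content by k * stride pixels shifts the feature grid by k
# cells (away from boundaries).

#' Feature map
#'
#' A rows x cols x channels array of features together with the geometry
#' linking feature cells back to image coordinates: `stride` (image px per
#' feature cell) and `origin`, the image `(x, y)` coordinate of the center of
#' cell (1, 1).
#'
#' @param grid 3-d numeric array (rows x cols x channels), finite.
#' @param stride Image pixels per cell, > 0.
#' @param origin Numeric `c(x, y)` image coordinate of cell (1, 1) center.
#' @return Object of class `feature_map`.
#' @export
feature_map <- function(grid, stride, origin = c(0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    stopf("feature_map: grid must be a rows x cols x channels array")
  }
  if (any(!is.finite(grid))) stopf("feature_map: non-finite feature values")
  if (stride <= 0) stopf("feature_map: stride must be > 0")
  structure(list(grid = grid, stride = as.numeric(stride),
                 origin = as.numeric(origin)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<feature_map %d x %d x %d, stride %.3f, origin (%.2f, %.2f)>\n",
              d[1], d[2], d[3], x$stride, x$origin[1], x$origin[2]))
  invisible(x)
}

fmap_dims <- function(f) dim(f$grid)

# Image coordinate of feature cell (row, col) center.
fmap_cell_coord <- function(f, row, col) {
  c(f$origin[1] + (col - 1) * f$stride, f$origin[2] + (row - 1) * f$stride)
}

# --- extractor registry ------------------------------------------------------

.extractors <- new.env(parent = emptyenv())

#' Register a feature extractor
#'
#' An extractor is a `function(patch, stride, seed)` returning a rows x cols
#' x channels array with cell (i, j) centered at patch pixel coordinate
#' `((j - 0.5) * stride, (i - 0.5) * stride)`.
#'
#' @param id Extractor name.
#' @param fn Extractor function.
#' @export
register_extractor <- function(id, fn) {
  stopifnot(is.character(id), is.function(fn))
  assign(id, fn, envir = .extractors)
  invisible(id)
}

get_extractor <- function(id) {
  if (!exists(id, envir = .extractors, inherits = FALSE)) {
    stopf("unknown feature extractor '%s' (registered: %s)", id,
          paste(ls(.extractors), collapse = ", "))
  }
  get(id, envir = .extractors, inherits = FALSE)
}

# Block-mean downsample a matrix by an integer factor (trailing remainder
# rows/cols are dropped).
block_mean <- function(mat, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(mat)
  nr <- (nrow(mat) %/% factor) * factor
  nc <- (ncol(mat) %/% factor) * factor
  m <- mat[seq_len(nr), seq_len(nc), drop = FALSE]
  ar <- matrix(0, nr %/% factor, nr)
  ar[cbind(rep(seq_len(nr %/% factor), each = factor), seq_len(nr))] <- 1 / factor
  ac <- matrix(0, nc %/% factor, nc)
  ac[cbind(rep(seq_len(nc %/% factor), each = factor), seq_len(nc))] <- 1 / factor
  ar %*% m %*% t(ac)
}

# pix-grad: {locally mean-subtracted intensity, horizontal gradient, vertical
# gradient}, each 3x3 box smoothed. Local mean uses a 7-cell box so blob-scale
# structure survives; gradients are central differences with replicated edges.
pix_grad_extractor <- function(patch, stride, seed = 0L) {
  d <- block_mean(patch, stride)
  nr <- nrow(d)
  nc <- ncol(d)
  gx <- (d[, c(seq_len(nc)[-1], nc), drop = FALSE] -
           d[, c(1, seq_len(nc)[-nc]), drop = FALSE]) / 2
  gy <- (d[c(seq_len(nr)[-1], nr), , drop = FALSE] -
           d[c(1, seq_len(nr)[-nr]), , drop = FALSE]) / 2
  ch <- list(d - box_mean(d, 7L), gx, gy)
  ch <- lapply(ch, box_mean, k = 3L)
  array(unlist(ch, use.names = FALSE), dim = c(nr, nc, 3L))
}

#' Extract features from a square patch
#'
#' Runs the registered extractor on `patch` and wraps the result in a
#' [feature_map()] whose geometry maps cells back to image coordinates via
#' `affine` (as returned by [crop_and_resize()]); without `affine` the
#' geometry is expressed in patch coordinates. With `normalize = TRUE` the
#' whole per-cell feature tensor is scaled to unit Frobenius norm (all-zero
#' features, e.g. from a constant patch, are left at zero). Extraction is
#' deterministic for a fixed `(patch, extractor_id, seed)`.
#'
#' @param patch Square numeric matrix.
#' @param extractor_id Registered extractor id (default `"pix-grad"`).
#' @param stride Pixels per feature cell within the patch.
#' @param seed Integer forwarded to the extractor (ignored by `"pix-grad"`).
#' @param normalize Scale the feature tensor to unit Frobenius norm.
#' @param affine Optional `list(scale, x0, y0)` patch-to-image map
#'   (`image = patch * scale + offset`).
#' @return A [feature_map()].
#' @export
extract_features <- function(patch, extractor_id = "pix-grad", stride = 4L,
                             seed = 0L, normalize = TRUE, affine = NULL) {
  if (!is.matrix(patch)) stopf("extract_features: patch must be a matrix")
  if (nrow(patch) != ncol(patch)) stopf("extract_features: patch must be square")
  fn <- get_extractor(extractor_id)
  grid <- fn(patch, as.integer(stride), as.integer(seed))
  if (normalize) {
    nrm <- frobenius_norm(grid)
    if (nrm > 1e-12) grid <- grid / nrm
  }
  if (is.null(affine)) affine <- list(scale = 1, x0 = 0, y0 = 0)
  cell_stride <- stride * affine$scale
  origin <- c(affine$x0 + 0.5 * cell_stride, affine$y0 + 0.5 * cell_stride)
  feature_map(grid, stride = cell_stride, origin = origin)
}

# Bilinearly resize a rows x cols x channels array so the output grid spans
# the same extent (output cell centers sample the input in its own cell
# units, borders replicated).
resize_feature_grid <- function(grid, out_rows, out_cols) {
  d <- dim(grid)
  if (out_rows == d[1] && out_cols == d[2]) return(grid)
  rr <- (seq_len(out_rows) - 0.5) * d[1] / out_rows + 0.5
  cc <- (seq_len(out_cols) - 0.5) * d[2] / out_cols + 0.5
  cx <- rep(cc, each = out_rows)
  ry <- rep(rr, times = out_cols)
  out <- array(0, dim = c(out_rows, out_cols, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- matrix(bilinear_at(grid[, , ch], cx, ry, pad = NULL),
                          out_rows, out_cols)
  }
  out
}
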