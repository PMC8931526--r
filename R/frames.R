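# Frame container and frame-sequence reading.

#' Grayscale video frame
#'
#' Wraps a rows x cols matrix of intensities in `[0, 1]` together with its
#' 0-based frame index. Color input is converted to grayscale on read with
#' fixed luma weights (0.299, 0.587, 0.114) so results are reproducible.
#'
#' @param pixels Numeric matrix, values in `[0, 1]`, at least 16 x 16.
#' @param index 0-based frame number.
#' @return An object of class `frame_image` with fields `pixels`, `height`,
#'   `width`, `index`.
#' @export
frame_image <- function(pixels, index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("frame_image: pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 16L || ncol(pixels) < 16L) {
    stopf("frame_image: frames must be at least 16 x 16 (got %d x %d)",
          nrow(pixels), ncol(pixels))
  }
  if (any(!is.finite(pixels))) stopf("frame_image: non-finite pixel values")
  if (min(pixels) < 0 || max(pixels) > 1) {
    stopf("frame_image: pixel values must lie in [0, 1]")
  }
  structure(list(pixels = pixels, height = nrow(pixels),
                 width = ncol(pixels), index = as.integer(index)),
            class = "frame_image")
}

#' @export
print.frame_image <- function(x, ...) {
  cat(sprintf("<frame_image %d x %d, index %d>\n", x$height, x$width, x$index))
  invisible(x)
}

luma_weights <- c(r = 0.299, g = 0.587, b = 0.114)

# Collapse an image array (h x w, h x w x 1..4) to a grayscale matrix.
to_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  d <- dim(arr)
  if (length(d) == 3L) {
    if (d[3] == 1L) return(arr[, , 1L])
    # ignore any alpha channel
    arr[, , 1L] * luma_weights[["r"]] + arr[, , 2L] * luma_weights[["g"]] +
      arr[, , 3L] * luma_weights[["b"]]
  } else {
    stopf("unsupported image array with %d dimensions", length(d))
  }
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stopf("reading JPEG frames requires the EBImage package: %s", path)
      }
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      # EBImage stores x (cols) first; transpose to rows x cols
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stopf("unsupported image extension '%s' in %s", ext, path)
  )
  to_gray(arr)
}

#' Read an image sequence as a list of frames
#'
#' Reads either a directory of PNG/JPEG images (ordered by plain lexicographic
#' filename order -- zero-pad frame numbers, e.g. `f_0001.png`, since `f_10.png`
#' sorts before `f_2.png`) or a multi-page TIFF stack (native page order,
#' requires the `tiff` package). Frames are converted to grayscale in `[0, 1]`
#' and assigned indices `0 .. N-1`. Re-reading the same path always yields
#' identical objects.
#'
#' @param path Directory of images, or a `.tif`/`.tiff` stack file.
#' @return List of [frame_image()] objects.
#' @export
read_frame_sequence <- function(path) {
  if (!file.exists(path)) stopf("frame source does not exist: %s", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L) stopf("no readable frames found in %s", path)
    mats <- lapply(files, read_image_file)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tif", "tiff")) {
      stopf("frame stacks must be multi-page TIFF files: %s", path)
    }
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stopf("reading TIFF stacks requires the tiff package")
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) == 0L) stopf("no readable frames found in %s", path)
    mats <- lapply(pages, to_gray)
  }
  dims <- vapply(mats, function(m) dim(m), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("frames have differing shapes (first is %d x %d)",
          dims[1, 1], dims[2, 1])
  }
  mats <- lapply(mats, function(m) {
    m[m < 0] <- 0
    m[m > 1] <- 1
    m
  })
  Map(function(m, i) frame_image(m, i), mats, seq_along(mats) - 1L)
}

#' Translate frames by an integer pixel offset
#'
#' Circularly shifts every frame `dx` pixels rightwards and `dy` pixels
#' downwards (contents wrap around the frame borders). Useful for testing the
#' tracker's translation invariance on synthetic scenes whose target stays
#' away from the borders.
#'
#' @param frames List of [frame_image()] objects.
#' @param dx,dy Integer shifts in pixels.
#' @return List of shifted frames with the same indices.
#' @export
translate_frames <- function(frames, dx, dy) {
  dx <- as.integer(dx)
  dy <- as.integer(dy)
  lapply(frames, function(f) {
    nr <- f$height
    nc <- f$width
    ri <- ((seq_len(nr) - 1L - dy) %% nr) + 1L
    ci <- ((seq_len(nc) - 1L - dx) %% nc) + 1L
    frame_image(f$pixels[ri, ci, drop = FALSE], f$index)
  })
}
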