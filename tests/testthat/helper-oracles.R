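# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles are deliberately naive (triple loops, pointwise
# formulas) and never call the implementation paths they check.

# valid-mode cross-correlation, triple loop over offsets and channels
oracle_xcorr <- function(tmpl, search) {
  dt <- dim(tmpl)
  ds <- dim(search)
  out <- matrix(0, ds[1] - dt[1] + 1, ds[2] - dt[2] + 1)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      acc <- 0
      for (ch in seq_len(dt[3])) {
        acc <- acc + sum(tmpl[, , ch] *
                           search[i:(i + dt[1] - 1), j:(j + dt[2] - 1), ch])
      }
      out[i, j] <- acc
    }
  }
  out
}

# pointwise bilinear interpolation at a single continuous cell coordinate
# (cell (i, j) center at (row = i, col = j)), border replicated
oracle_bilinear <- function(mat, row, col) {
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  g <- function(r, c) mat[min(max(r, 1), nrow(mat)), min(max(c, 1), ncol(mat))]
  (1 - fr) * ((1 - fc) * g(r0, c0) + fc * g(r0, c0 + 1)) +
    fr * ((1 - fc) * g(r0 + 1, c0) + fc * g(r0 + 1, c0 + 1))
}

# softmax-mass confidence, computed directly from the definition
oracle_confidence <- function(scores, temperature) {
  den <- max(scores) - min(scores)
  if (den <= 0) {
    z <- matrix(0, nrow(scores), ncol(scores))
    cell <- c((nrow(scores) + 1L) %/% 2L, (ncol(scores) + 1L) %/% 2L)
  } else {
    z <- (scores - min(scores)) / den
    idx <- which(scores == max(scores), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    cell <- idx[1, ]
  }
  p <- exp(z / temperature - max(z / temperature))
  p <- p / sum(p)
  rows <- max(1, cell[1] - 1):min(nrow(scores), cell[1] + 1)
  cols <- max(1, cell[2] - 1):min(ncol(scores), cell[2] + 1)
  sum(p[rows, cols])
}

# IoU by counting unit pixels on a rasterized grid (integer boxes only)
oracle_iou_raster <- function(a, b, lim = 64L) {
  grid_a <- matrix(FALSE, lim, lim)
  grid_b <- matrix(FALSE, lim, lim)
  fill <- function(g, bx) {
    cols <- seq.int(bx$x + 1, bx$x + bx$w)
    rows <- seq.int(bx$y + 1, bx$y + bx$h)
    g[rows, cols] <- TRUE
    g
  }
  grid_a <- fill(grid_a, a)
  grid_b <- fill(grid_b, b)
  sum(grid_a & grid_b) / sum(grid_a | grid_b)
}

mk_fmap <- function(arr, stride = 1, origin = c(0.5, 0.5)) {
  feature_map(arr, stride = stride, origin = origin)
}

mk_resp <- function(scores, stride = 1, origin = c(0, 0)) {
  response_map(scores, stride = stride, origin = origin)
}

# a small static textured scene with one blob, shared by tracker tests
static_blob_scene <- function(n_frames = 3L, seed = 11L, center = c(48, 48)) {
  generate_scene(scene_config(
    n_frames = n_frames, frame_size = c(96L, 96L),
    target = list(shape = "disc", width = 14, height = 14),
    motion = list(type = "linear", start = center, velocity = c(0, 0)),
    seed = seed))
}

small_cfg <- function(...) fixture_tracker_config("small", ...)

# seeded pure-noise frame, uncorrelated with any scene
noise_frame <- function(index = 1L, seed = 99L, size = 96L) {
  m <- siamtrack:::with_seed(seed, matrix(stats::runif(size * size), size, size))
  frame_image(m, index)
}
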