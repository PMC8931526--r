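# Shared numerical helpers: bilinear sampling, box filtering, seeded evaluation.
#
# Continuous image coordinates are 0-based with origin at the top-left corner:
# pixel (row i, col j) of a matrix (both 1-based) covers the half-open square
# [j-1, j) x [i-1, i) and has its center at (x, y) = (j - 0.5, i - 0.5).

# Bilinear interpolation in "center units": column position `cx` such that the
# center of matrix column j sits at cx = j, likewise `ry` for rows. `pad`
# is either a constant used outside the matrix or NULL for border replication.
bilinear_at <- function(mat, cx, ry, pad = NULL) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  c0 <- floor(cx)
  r0 <- floor(ry)
  fc <- cx - c0
  fr <- ry - r0
  pick <- function(ri, ci) {
    if (is.null(pad)) {
      ri <- pmin.int(pmax.int(ri, 1L), nr)
      ci <- pmin.int(pmax.int(ci, 1L), nc)
      mat[cbind(ri, ci)]
    } else {
      ok <- ri >= 1L & ri <= nr & ci >= 1L & ci <= nc
      v <- rep.int(pad, length(ri))
      if (any(ok)) v[ok] <- mat[cbind(ri[ok], ci[ok])]
      v
    }
  }
  v00 <- pick(r0, c0)
  v01 <- pick(r0, c0 + 1)
  v10 <- pick(r0 + 1, c0)
  v11 <- pick(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Bilinear sample at continuous image coordinates (pixel j center at x = j-0.5).
bilinear_sample <- function(mat, x, y, pad = NULL) {
  bilinear_at(mat, x + 0.5, y + 0.5, pad = pad)
}

# k x k box (moving-average) filter with edge replication, via integral image.
box_mean <- function(mat, k) {
  k <- as.integer(k)
  if (k <= 1L) return(mat)
  h <- (k - 1L) %/% 2L
  h2 <- k - 1L - h
  nr <- nrow(mat)
  nc <- ncol(mat)
  ri <- pmin.int(pmax.int(seq.int(1L - h, nr + h2), 1L), nr)
  ci <- pmin.int(pmax.int(seq.int(1L - h, nc + h2), 1L), nc)
  p <- mat[ri, ci, drop = FALSE]
  s <- apply(p, 2L, cumsum)
  s <- rbind(0, s)
  s <- t(apply(s, 1L, cumsum))
  s <- cbind(0, s)
  i <- seq_len(nr)
  j <- seq_len(nc)
  (s[i + k, j + k, drop = FALSE] - s[i, j + k, drop = FALSE] -
     s[i + k, j, drop = FALSE] + s[i, j, drop = FALSE]) / (k * k)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. Keeps generators pure w.r.t. global state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

frobenius_norm <- function(a) sqrt(sum(a * a))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
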