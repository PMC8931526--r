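# Cross-correlation of template features over search features.

#' Response map
#'
#' The 2-d grid of similarity scores obtained by valid-mode cross-correlation
#' of template features over search features, plus the geometry mapping each
#' score back to the image coordinate of its template-window center.
#'
#' @param scores Numeric matrix of similarity scores (finite).
#' @param stride Image px per response cell.
#' @param origin Image `(x, y)` coordinate of the window center of score
#'   cell (1, 1).
#' @return Object of class `response_map`.
#' @export
response_map <- function(scores, stride, origin) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stopf("response_map: scores must be a numeric matrix")
  }
  if (any(!is.finite(scores))) stopf("response_map: non-finite scores")
  if (stride <= 0) stopf("response_map: stride must be > 0")
  structure(list(scores = scores, stride = as.numeric(stride),
                 origin = as.numeric(origin)),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("<response_map %d x %d, stride %.3f, origin (%.2f, %.2f)>\n",
              nrow(x$scores), ncol(x$scores), x$stride, x$origin[1], x$origin[2]))
  invisible(x)
}

# Image coordinate of the window center for response cell (row, col).
response_cell_coord <- function(resp, row, col) {
  c(resp$origin[1] + (col - 1) * resp$stride,
    resp$origin[2] + (row - 1) * resp$stride)
}

# Nearest response cell to an image coordinate, clamped into the map.
response_nearest_cell <- function(resp, xy) {
  nr <- nrow(resp$scores)
  nc <- ncol(resp$scores)
  col <- round((xy[1] - resp$origin[1]) / resp$stride) + 1
  row <- round((xy[2] - resp$origin[2]) / resp$stride) + 1
  c(min(max(row, 1), nr), min(max(col, 1), nc))
}

# Valid-mode 2-d cross-correlation of a single channel, via FFT:
# out[i, j] = sum_{u, v} t[u, v] * s[i + u - 1, j + v - 1].
xcorr2_valid <- function(s, t) {
  sr <- nrow(s); sc <- ncol(s)
  tr <- nrow(t); tc <- ncol(t)
  tp <- matrix(0, sr, sc)
  tp[seq_len(tr), seq_len(tc)] <- t
  cc <- Re(stats::fft(stats::fft(s) * Conj(stats::fft(tp)), inverse = TRUE)) / (sr * sc)
  cc[seq_len(sr - tr + 1), seq_len(sc - tc + 1), drop = FALSE]
}

#' Cross-correlate template features over search features
#'
#' Computes the sliding inner product of the template feature tensor over the
#' search feature tensor (valid mode, no padding), summed over channels:
#' `scores[i, j] = sum_{u,v,c} template[u, v, c] * search[i+u-1, j+v-1, c]`.
#' The response geometry is set so each score maps to the image coordinate of
#' its template-window center.
#'
#' @param template_feat,search_feat [feature_map()]s with equal channel
#'   counts; the template grid must fit inside the search grid.
#' @return A [response_map()].
#' @export
cross_correlate <- function(template_feat, search_feat) {
  stopifnot(inherits(template_feat, "feature_map"),
            inherits(search_feat, "feature_map"))
  dt <- fmap_dims(template_feat)
  ds <- fmap_dims(search_feat)
  if (dt[3] != ds[3]) {
    stopf("cross_correlate: channel mismatch (%d vs %d)", dt[3], ds[3])
  }
  if (dt[1] > ds[1] || dt[2] > ds[2]) {
    stopf("cross_correlate: template grid (%d x %d) larger than search (%d x %d)",
          dt[1], dt[2], ds[1], ds[2])
  }
  scores <- 0
  for (ch in seq_len(dt[3])) {
    scores <- scores + xcorr2_valid(
      matrix(search_feat$grid[, , ch], ds[1], ds[2]),
      matrix(template_feat$grid[, , ch], dt[1], dt[2]))
  }
  ctr_row <- (1 + dt[1]) / 2
  ctr_col <- (1 + dt[2]) / 2
  origin <- c(search_feat$origin[1] + (ctr_col - 1) * search_feat$stride,
              search_feat$origin[2] + (ctr_row - 1) * search_feat$stride)
  response_map(scores, stride = search_feat$stride, origin = origin)
}
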