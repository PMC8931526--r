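# The Siamese matching core: template state, distractor suppression, peak and
# box-candidate selection, output confidence, per-frame stepping.

#' Tracking state
#'
#' Everything needed to advance the tracker one frame: the template feature
#' (replaced only by a human correction), the box that defined it, the
#' current box, the distractor feature memory, and the last confidence.
#'
#' @param template_feature [feature_map()] of the template crop.
#' @param template_box [bbox()] that defined the template.
#' @param current_box Current [bbox()].
#' @param distractors Distractor memory: list of `list(feat, center)`
#'   entries, each a template-shaped [feature_map()] plus the image
#'   coordinate it was mined at (oldest first).
#' @param last_confidence Last confidence in `[0, 1]`.
#' @return Object of class `track_state`.
#' @export
track_state <- function(template_feature, template_box, current_box,
                        distractors = list(), last_confidence = 1.0) {
  stopifnot(inherits(template_feature, "feature_map"),
            is_bbox(template_box), is_bbox(current_box))
  structure(list(template_feature = template_feature,
                 template_box = template_box,
                 current_box = current_box,
                 distractors = distractors,
                 last_confidence = as.numeric(last_confidence)),
            class = "track_state")
}

#' Initialize tracking from a first-frame annotation
#'
#' Crops the context-padded template patch around `box`, extracts its
#' features (unit Frobenius norm) and returns the initial [track_state()].
#'
#' @param frame First [frame_image()].
#' @param box Initial [bbox()] (the user's "snapshot" of the target).
#' @param cfg A [tracker_config()].
#' @return A [track_state()].
#' @export
track_init <- function(frame, box, cfg = tracker_config()) {
  cr <- crop_and_resize(frame, box, cfg$context_factor, cfg$template_size)
  tf <- extract_features(cr$patch, cfg$extractor, cfg$feature_stride,
                         normalize = TRUE, affine = cr$affine)
  track_state(tf, box, box)
}

#' Suppress distractor responses
#'
#' Subtracts the mean cross-correlation response of the memorized distractor
#' features from a response map, scaled by `alpha`:
#' `scores' = scores - (alpha / max(1, n)) * sum_i xcorr(d_i, search)`.
#' With `alpha = 0` or an empty distractor list the map is returned
#' unchanged, bit-exactly. This pushes the response at distractor locations
#' down so the target peak stays dominant when a look-alike approaches.
#'
#' @param resp [response_map()] of the template over `search_feat`.
#' @param search_feat Search-region [feature_map()].
#' @param distractors List of [feature_map()]s, each shaped like the
#'   template feature used to produce `resp`.
#' @param alpha Suppression strength, >= 0.
#' @return A [response_map()].
#' @export
suppress_distractors <- function(resp, search_feat, distractors, alpha) {
  stopifnot(inherits(resp, "response_map"))
  if (alpha == 0 || length(distractors) == 0L) return(resp)
  acc <- 0
  for (d in distractors) {
    dr <- cross_correlate(d, search_feat)
    if (!all(dim(dr$scores) == dim(resp$scores))) {
      stopf("suppress_distractors: distractor response shape %d x %d != %d x %d",
            nrow(dr$scores), ncol(dr$scores), nrow(resp$scores), ncol(resp$scores))
    }
    acc <- acc + dr$scores
  }
  response_map(resp$scores - (alpha / length(distractors)) * acc,
               stride = resp$stride, origin = resp$origin)
}

# 2-d raised-cosine window centered on cell (r0, c0), value 1 at the center
# decaying to 0 at `nr` (`nc`) cells away.
cosine_window <- function(nr, nc, r0, c0) {
  wr <- 0.5 * (1 + cos(pi * pmin(abs(seq_len(nr) - r0) / nr, 1)))
  wc <- 0.5 * (1 + cos(pi * pmin(abs(seq_len(nc) - c0) / nc, 1)))
  outer(wr, wc)
}

# First (smallest row, then smallest col) among the maxima of a matrix.
argmax_cell <- function(m) {
  idx <- which(m == max(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  as.integer(idx[1, ])
}

#' Locate the response peak under a motion prior
#'
#' Scores are min-max normalized to `[0, 1]` (over `norm_range`, by default
#' the map's own range) and blended with a 2-d raised-cosine window centered
#' on the cell nearest `prev_center`:
#' `s' = (1 - window_weight) * s_norm + window_weight * window`. The peak is
#' the argmax of `s'`, ties broken by smallest row then smallest column. A
#' degenerate all-equal map with `window_weight = 0` returns the center cell.
#'
#' @param resp A [response_map()].
#' @param prev_center Image `(x, y)` of the previous box center.
#' @param window_weight Motion-prior weight in `[0, 1)`.
#' @param norm_range Optional `c(lo, hi)` normalization range shared across
#'   several candidate maps so their peaks stay comparable.
#' @return `list(cell = c(row, col), windowed_score, raw_score)`.
#' @export
locate_peak <- function(resp, prev_center, window_weight, norm_range = NULL) {
  stopifnot(inherits(resp, "response_map"))
  s <- resp$scores
  nr <- nrow(s)
  nc <- ncol(s)
  if (is.null(norm_range)) norm_range <- range(s)
  den <- norm_range[2] - norm_range[1]
  if (den <= 0) {
    if (window_weight == 0) {
      cell <- c((nr + 1L) %/% 2L, (nc + 1L) %/% 2L)
      return(list(cell = cell, windowed_score = 0,
                  raw_score = s[cell[1], cell[2]]))
    }
    sn <- matrix(0, nr, nc)
  } else {
    sn <- (s - norm_range[1]) / den
  }
  cell0 <- response_nearest_cell(resp, prev_center)
  sp <- (1 - window_weight) * sn +
    window_weight * cosine_window(nr, nc, cell0[1], cell0[2])
  cell <- argmax_cell(sp)
  list(cell = cell, windowed_score = sp[cell[1], cell[2]],
       raw_score = s[cell[1], cell[2]])
}

#' Output confidence of a response map
#'
#' Treats localization as classification of the target against background:
#' scores are min-max normalized (so the temperature is scale-free),
#' softmaxed over all cells at `temperature`, and the confidence is the
#' probability mass in the 3 x 3 neighborhood of the raw argmax (clipped at
#' the borders; on an all-equal map the center cell is used). The value is
#' strictly in `(0, 1]` and equals `min(9, N) / N` exactly on a constant map
#' of `N` cells. A sharp, isolated peak gives confidence near 1; a flat or
#' fragmented map -- the target lost or occluded -- gives a small value.
#'
#' @param resp A [response_map()].
#' @param temperature Softmax temperature, > 0.
#' @return Confidence in `(0, 1]`.
#' @export
compute_confidence <- function(resp, temperature) {
  stopifnot(inherits(resp, "response_map"))
  if (temperature <= 0) stopf("compute_confidence: temperature must be > 0")
  s <- resp$scores
  nr <- nrow(s)
  nc <- ncol(s)
  den <- max(s) - min(s)
  if (den <= 0) {
    z <- matrix(0, nr, nc)
    cell <- c((nr + 1L) %/% 2L, (nc + 1L) %/% 2L)
  } else {
    z <- (s - min(s)) / den
    cell <- argmax_cell(s)
  }
  zz <- z / temperature
  p <- exp(zz - max(zz))
  p <- p / sum(p)
  rows <- max(1L, cell[1] - 1L):min(nr, cell[1] + 1L)
  cols <- max(1L, cell[2] - 1L):min(nc, cell[2] + 1L)
  sum(p[rows, cols])
}

# Ordered box-shape candidates: identity (ratio 1, scale 1) first, then
# ratios in config order crossed with scales in config order.
candidate_set <- function(cfg) {
  cands <- list(list(ratio = 1, scale = 1, id = "r=1,s=1"))
  for (r in cfg$anchor_ratios) {
    for (s in cfg$scale_candidates) {
      if (r == 1 && s == 1) next
      cands[[length(cands) + 1L]] <- list(
        ratio = r, scale = s, id = sprintf("r=%g,s=%g", r, s))
    }
  }
  cands
}

# Candidate box size for (ratio, scale) applied to a previous box: area
# scales by scale^2, aspect w/h by ratio.
candidate_size <- function(prev_box, ratio, scale) {
  c(w = prev_box$w * scale * sqrt(ratio), h = prev_box$h * scale / sqrt(ratio))
}

#' Select the winning box candidate across per-candidate response maps
#'
#' Each candidate's peak is located with [locate_peak()] under a shared
#' min-max normalization range (so windowed peak scores are comparable
#' across candidates); the winner is the candidate with the largest windowed
#' peak score, ties broken by candidate order (identity first). The new box
#' is centered at the image coordinate of the winning peak, its size a
#' damped blend `(1 - size_damping) * prev + size_damping * candidate`, and
#' its center clamped inside the frame when `frame_size` is given.
#'
#' @param responses List of `list(resp = response_map, ratio, scale)`.
#' @param prev_box Previous [bbox()].
#' @param size_damping Blend factor in `(0, 1]`.
#' @param window_weight Motion-prior weight forwarded to [locate_peak()].
#' @param frame_size Optional `c(height, width)` for center clamping.
#' @param shape_penalty Non-identity candidates' windowed scores are
#'   multiplied by `exp(-shape_penalty * (|log ratio| + |log scale|))`
#'   (default 0: pure argmax).
#' @return `list(box, candidate, peak, resp)` where `candidate` indexes the
#'   winning entry of `responses`.
#' @export
select_box_candidate <- function(responses, prev_box, size_damping,
                                 window_weight = 0, frame_size = NULL,
                                 shape_penalty = 0) {
  if (length(responses) == 0L) stopf("select_box_candidate: empty candidate set")
  rng <- range(vapply(responses, function(cand) range(cand$resp$scores),
                      numeric(2)))
  ctr <- bbox_center(prev_box)
  peaks <- lapply(responses, function(cand) {
    locate_peak(cand$resp, ctr, window_weight, norm_range = rng)
  })
  scores <- vapply(seq_along(responses), function(k) {
    pen <- exp(-shape_penalty * (abs(log(responses[[k]]$ratio)) +
                                   abs(log(responses[[k]]$scale))))
    peaks[[k]]$windowed_score * pen
  }, 0)
  k <- which.max(scores)
  peak <- peaks[[k]]
  resp <- responses[[k]]$resp
  new_ctr <- response_cell_coord(resp, peak$cell[1], peak$cell[2])
  cs <- candidate_size(prev_box, responses[[k]]$ratio, responses[[k]]$scale)
  w_new <- (1 - size_damping) * prev_box$w + size_damping * cs[["w"]]
  h_new <- (1 - size_damping) * prev_box$h + size_damping * cs[["h"]]
  if (!is.null(frame_size)) {
    new_ctr[1] <- min(max(new_ctr[1], 0), frame_size[2])
    new_ctr[2] <- min(max(new_ctr[2], 0), frame_size[1])
  }
  list(box = bbox_from_center(new_ctr[1], new_ctr[2], w_new, h_new),
       candidate = k, peak = peak, resp = resp)
}

# Resample a score matrix to a new shape (bilinear, spanning the same extent).
resize_scores <- function(m, out_rows, out_cols) {
  resize_feature_grid(array(m, dim = c(dim(m), 1L)), out_rows, out_cols)[, , 1L]
}

#' Advance the tracker by one frame
#'
#' Crops the search region around the current box, extracts features,
#' cross-correlates the template (and its anchor-ratio/scale resamplings)
#' over them, suppresses memorized distractors, selects the winning peak and
#' box candidate under the motion prior, computes the output confidence, and
#' mines new distractors: secondary raw-response peaks of at least
#' `distractor_peak_fraction` of the primary peak, at least one target-box
#' width away, have their ROI-aligned features appended to the memory (the
#' newest entries are evicted once `distractor_memory` is exceeded, so crops
#' mined before any possible drift are retained). The template itself is never
#' updated automatically -- only a human correction replaces it.
#'
#' @param state A [track_state()].
#' @param frame The next [frame_image()].
#' @param cfg A [tracker_config()].
#' @return `list(state, record)` where `record` is a one-row trajectory
#'   data.frame with source `"auto"`.
#' @export
track_step <- function(state, frame, cfg = tracker_config()) {
  stopifnot(inherits(state, "track_state"), inherits(frame, "frame_image"))
  b <- state$current_box
  ctr <- bbox_center(b)
  s_t <- crop_side(b, cfg$context_factor)
  s_s <- s_t * cfg$search_size / cfg$template_size
  sc <- crop_patch(frame, ctr[1], ctr[2], s_s, cfg$search_size)
  search_feat <- extract_features(sc$patch, cfg$extractor, cfg$feature_stride,
                                  normalize = TRUE, affine = sc$affine)
  tmpl <- state$template_feature
  dt <- fmap_dims(tmpl)
  ds <- fmap_dims(search_feat)

  # Aggregate distractor response at the identity candidate's shape. Each
  # remembered distractor is refreshed from the CURRENT search features at
  # the image location it was mined at: the refreshed crop shares the
  # current sampling grid, so its correlation peaks sharply at that location
  # (a stale stored crop would be decorrelated by the sub-stride phase
  # difference between frames and lose all spatial selectivity). If the
  # object has left that location the refreshed crop is plain background,
  # which correlates weakly everywhere and is harmless.
  # every correlation this frame shares the search-channel FFTs
  fs <- lapply(seq_len(ds[3]), function(ch) {
    stats::fft(matrix(search_feat$grid[, , ch], ds[1], ds[2]))
  })

  dmap <- NULL
  if (length(state$distractors) > 0L && cfg$distractor_alpha > 0) {
    acc <- NULL
    nref <- 0L
    for (d in state$distractors) {
      rf <- refresh_distractor(d, search_feat, s_t, dt)
      if (is.null(rf)) next
      sc_d <- xcorr_fft(fs, conj_fft_pad(rf$grid, ds[1], ds[2]),
                        dim(rf$grid), ds[1], ds[2])
      acc <- if (is.null(acc)) sc_d else acc + sc_d
      nref <- nref + 1L
    }
    if (nref > 0L) dmap <- (cfg$distractor_alpha / nref) * acc
  }

  cands <- candidate_set(cfg)
  # the resized candidate templates (and their padded conjugate FFTs) depend
  # only on the template and the config, so they are built once per template
  # and carried in the state; a correction starts a fresh state
  cache <- state$cand_cache
  key <- list(ds = ds, n = length(cands))
  if (is.null(cache) || !identical(cache$key, key)) {
    entries <- vector("list", length(cands))
    for (k in seq_along(cands)) {
      cd <- cands[[k]]
      if (cd$ratio == 1 && cd$scale == 1) {
        g <- tmpl$grid
      } else {
        rows2 <- min(max(round(dt[1] * cd$scale / sqrt(cd$ratio)), 2L), ds[1] - 1L)
        cols2 <- min(max(round(dt[2] * cd$scale * sqrt(cd$ratio)), 2L), ds[2] - 1L)
        g <- resize_feature_grid(tmpl$grid, rows2, cols2)
        nrm <- frobenius_norm(g)
        if (nrm > 1e-12) g <- g / nrm
      }
      entries[[k]] <- list(fft = conj_fft_pad(g, ds[1], ds[2]), dims = dim(g))
    }
    cache <- list(key = key, entries = entries)
  }

  responses <- vector("list", length(cands))
  raw_identity <- NULL
  for (k in seq_along(cands)) {
    e <- cache$entries[[k]]
    scores <- xcorr_fft(fs, e$fft, e$dims, ds[1], ds[2])
    r <- response_from(scores, search_feat, e$dims)
    if (k == 1L) raw_identity <- r
    if (!is.null(dmap)) {
      sub <- if (all(dim(r$scores) == dim(dmap))) dmap else {
        resize_scores(dmap, nrow(r$scores), ncol(r$scores))
      }
      r <- response_map(r$scores - sub, r$stride, r$origin)
    }
    responses[[k]] <- list(resp = r, ratio = cands[[k]]$ratio,
                           scale = cands[[k]]$scale)
  }

  sel <- select_box_candidate(responses, b, cfg$size_damping,
                              window_weight = cfg$window_weight,
                              frame_size = c(frame$height, frame$width),
                              shape_penalty = cfg$shape_penalty)
  conf <- compute_confidence(sel$resp, cfg$confidence_temperature)

  distractors <- mine_distractors(state, raw_identity, search_feat,
                                  bbox_center(sel$box), b, s_t, cfg)

  new_state <- track_state(tmpl, state$template_box, sel$box,
                           distractors, conf)
  new_state$cand_cache <- cache
  list(state = new_state,
       record = trajectory_row(frame$index, sel$box, conf, "auto"))
}

# Conjugate FFTs of a template grid zero-padded to the search grid size,
# one per channel.
conj_fft_pad <- function(grid, nr, nc) {
  d <- dim(grid)
  lapply(seq_len(d[3]), function(ch) {
    tp <- matrix(0, nr, nc)
    tp[seq_len(d[1]), seq_len(d[2])] <- grid[, , ch]
    Conj(stats::fft(tp))
  })
}

# Valid-mode multi-channel cross-correlation from precomputed FFTs: channels
# are summed in the frequency domain so one inverse transform suffices.
xcorr_fft <- function(fs, tf, tdim, nr, nc) {
  acc <- fs[[1]] * tf[[1]]
  for (ch in seq_along(fs)[-1]) acc <- acc + fs[[ch]] * tf[[ch]]
  cc <- Re(stats::fft(acc, inverse = TRUE)) / (nr * nc)
  cc[seq_len(nr - tdim[1] + 1), seq_len(nc - tdim[2] + 1), drop = FALSE]
}

# Response-map geometry for a template of shape tdim slid over search_feat.
response_from <- function(scores, search_feat, tdim) {
  ctr_row <- (1 + tdim[1]) / 2
  ctr_col <- (1 + tdim[2]) / 2
  response_map(scores, stride = search_feat$stride,
               origin = c(search_feat$origin[1] + (ctr_col - 1) * search_feat$stride,
                          search_feat$origin[2] + (ctr_row - 1) * search_feat$stride))
}

# Re-extract a remembered distractor's template-shaped feature from the
# current search features at its mined image location; NULL when that
# location is outside the current search span (the entry stays in memory and
# becomes active again if the location re-enters the span).
refresh_distractor <- function(entry, search_feat, side, dims) {
  d <- fmap_dims(search_feat)
  ex0 <- search_feat$origin[1] - search_feat$stride / 2
  ex1 <- search_feat$origin[1] + (d[2] - 0.5) * search_feat$stride
  ey0 <- search_feat$origin[2] - search_feat$stride / 2
  ey1 <- search_feat$origin[2] + (d[1] - 0.5) * search_feat$stride
  cx <- entry$center[1]
  cy <- entry$center[2]
  if (cx < ex0 || cx > ex1 || cy < ey0 || cy > ey1) return(NULL)
  roi <- bbox_from_center(cx, cy, side, side)
  df <- tryCatch(roi_align(search_feat, roi, dims[1], dims[2]),
                 error = function(e) NULL)
  if (is.null(df)) return(NULL)
  nrm <- frobenius_norm(df$grid)
  if (nrm <= 1e-12) return(NULL)
  df$grid <- df$grid / nrm
  df
}

# Greedy non-maximum selection of secondary raw-response peaks; each accepted
# peak's template-shaped neighborhood is ROI-aligned out of the search
# features and appended to the distractor memory together with its image
# location (used for per-frame refreshing).
mine_distractors <- function(state, raw_resp, search_feat, target_ctr,
                             prev_box, template_side, cfg) {
  distractors <- state$distractors
  if (cfg$distractor_memory <= 0L || cfg$distractor_alpha == 0) return(distractors)
  s <- raw_resp$scores
  primary_cell <- response_nearest_cell(raw_resp, target_ctr)
  primary <- s[primary_cell[1], primary_cell[2]]
  if (!is.finite(primary) || primary <= 0) return(distractors)
  sep <- max(2L, round(min(prev_box$w, prev_box$h) / raw_resp$stride))
  thr <- cfg$distractor_peak_fraction * primary
  hits <- which(s >= thr, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(distractors)
  cheb <- pmax(abs(hits[, 1] - primary_cell[1]), abs(hits[, 2] - primary_cell[2]))
  hits <- hits[cheb >= sep, , drop = FALSE]
  if (nrow(hits) == 0L) return(distractors)
  # never mine near the response-map border: apparent maxima there are
  # truncation artifacts of objects only partially inside the search span,
  # and their ROI crops are mis-centered
  border <- max(2L, sep %/% 2L)
  inside <- hits[, 1] > border & hits[, 1] <= nrow(s) - border &
    hits[, 2] > border & hits[, 2] <= ncol(s) - border
  hits <- hits[inside, , drop = FALSE]
  if (nrow(hits) == 0L) return(distractors)
  # strict local maxima only: a qualifying cell must dominate its whole
  # sep-neighborhood, so diffuse background fluctuations are not mined
  nr <- nrow(s)
  nc <- ncol(s)
  is_local_max <- vapply(seq_len(nrow(hits)), function(i) {
    r0 <- hits[i, 1]
    c0 <- hits[i, 2]
    nb <- s[max(1L, r0 - sep):min(nr, r0 + sep),
            max(1L, c0 - sep):min(nc, c0 + sep)]
    s[r0, c0] >= max(nb)
  }, logical(1))
  hits <- hits[is_local_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(distractors)
  hits <- hits[order(s[hits], decreasing = TRUE), , drop = FALSE]
  accepted <- matrix(numeric(0), 0, 2)
  dt <- fmap_dims(state$template_feature)
  new_d <- list()
  for (i in seq_len(nrow(hits))) {
    if (length(new_d) >= 1L) break  # one mined distractor per frame
    cell <- hits[i, ]
    if (nrow(accepted) > 0L) {
      d2 <- pmax(abs(accepted[, 1] - cell[1]), abs(accepted[, 2] - cell[2]))
      if (any(d2 < sep)) next
    }
    accepted <- rbind(accepted, cell)
    cc <- response_cell_coord(raw_resp, cell[1], cell[2])
    roi <- bbox_from_center(cc[1], cc[2], template_side, template_side)
    df <- tryCatch(roi_align(search_feat, roi, dt[1], dt[2]),
                   error = function(e) NULL)
    if (is.null(df)) next
    nrm <- frobenius_norm(df$grid)
    if (nrm > 1e-12) df$grid <- df$grid / nrm
    new_d[[length(new_d) + 1L]] <- list(feat = df, center = cc)
  }
  # eviction drops the newest entries once the memory is full: the crops
  # mined while the tracker was still solidly on the target are the trusted
  # ones, and must not be displaced by crops mined after a possible drift
  # (which may be the target itself)
  out <- c(distractors, new_d)
  if (length(out) > cfg$distractor_memory) out <- out[seq_len(cfg$distractor_memory)]
  out
}

#' Track a whole frame sequence
#'
#' Runs the tracker from a first-frame annotation across all frames. Record
#' 0 is the initial box with source `"corrected"` and confidence 1. At
#' frames with a matching [correction_event()] the correction is applied
#' (template replaced, distractor memory cleared) and a `"corrected"` record
#' emitted. When a detector `bank` is supplied, frames whose tracking
#' confidence falls below `detection_cfg$activation_threshold` consult the
#' exemplar detector ([gated_step()]); successful detections re-seed the box
#' and emit `"detected"` records. The run is a pure function of
#' `(frames, initial_box, cfg, corrections, bank, detection_cfg, seed)`.
#'
#' @param frames List of [frame_image()]s.
#' @param initial_box First-frame [bbox()].
#' @param cfg A [tracker_config()].
#' @param corrections Optional list of [correction_event()]s. An event at
#'   frame 0 is ignored with a warning: the initial box takes precedence.
#' @param bank Optional [exemplar_bank()] enabling tracking-with-detection.
#' @param detection_cfg A [detection_config()].
#' @param seed Integer seed for any stochastic component.
#' @param video_id Identifier stored on the trajectory.
#' @return A [trajectory()] with attributes `detector_invocations` (number
#'   of frames on which the detector was consulted), `step_confidence` (the
#'   per-frame tracking confidence before any detection gating; `NA` at
#'   corrected frames and frame 0) and `final_state`.
#' @export
track_sequence <- function(frames, initial_box, cfg = tracker_config(),
                           corrections = NULL, bank = NULL,
                           detection_cfg = detection_config(), seed = 0L,
                           video_id = "") {
  if (length(frames) == 0L) stopf("track_sequence: no frames")
  stopifnot(is_bbox(initial_box))
  corr_map <- list()
  for (ev in corrections %||% list()) {
    key <- as.character(ev$frame_index)
    if (ev$frame_index == frames[[1]]$index) {
      warning("correction at frame 0 ignored: the initial box takes precedence")
      next
    }
    corr_map[[key]] <- ev$box
  }
  with_seed(seed, {
    state <- track_init(frames[[1]], initial_box, cfg)
    rows <- vector("list", length(frames))
    rows[[1]] <- trajectory_row(frames[[1]]$index, initial_box, 1.0, "corrected")
    invocations <- 0L
    step_conf <- rep(NA_real_, length(frames))
    for (i in seq_along(frames)[-1]) {
      fr <- frames[[i]]
      key <- as.character(fr$index)
      if (!is.null(corr_map[[key]])) {
        state <- apply_correction(state, fr, corr_map[[key]], cfg)
        rows[[i]] <- trajectory_row(fr$index, corr_map[[key]], 1.0, "corrected")
      } else if (!is.null(bank)) {
        res <- gated_step(state, fr, cfg, bank, detection_cfg)
        state <- res$state
        rows[[i]] <- res$record
        invocations <- invocations + res$invoked
        step_conf[i] <- res$step_confidence
      } else {
        res <- track_step(state, fr, cfg)
        state <- res$state
        rows[[i]] <- res$record
        step_conf[i] <- res$record$confidence[1]
      }
    }
    traj <- trajectory(do.call(rbind, rows), video_id = video_id)
    attr(traj, "detector_invocations") <- invocations
    attr(traj, "step_confidence") <- step_conf
    attr(traj, "final_state") <- state
    traj
  })
}
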