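# Tracking-with-detection: harvesting exemplars from confident tracker
# output, a whole-frame exemplar detector, and the confidence-gated step.

#' Exemplar bank
#'
#' The detector's training set: feature maps of the tracker's own confident
#' automatic outputs, with the source box size of each. Bounded by
#' `max_size` via seeded reservoir downsampling so long runs keep a
#' representative sample.
#'
#' @param max_size Maximum number of stored exemplars (default 50).
#' @param min_harvest_confidence Minimum record confidence for harvesting
#'   (default 0.6).
#' @return Object of class `exemplar_bank`.
#' @export
exemplar_bank <- function(max_size = 50L, min_harvest_confidence = 0.6) {
  structure(list(exemplars = list(), max_size = as.integer(max_size),
                 min_harvest_confidence = as.numeric(min_harvest_confidence),
                 n_seen = 0L),
            class = "exemplar_bank")
}

#' @export
print.exemplar_bank <- function(x, ...) {
  cat(sprintf("<exemplar_bank %d/%d exemplars (%d seen), min confidence %.2f>\n",
              length(x$exemplars), x$max_size, x$n_seen,
              x$min_harvest_confidence))
  invisible(x)
}

bank_size <- function(bank) length(bank$exemplars)

# Feature of a record's box: the same context-padded template crop the
# tracker itself would use, unit Frobenius norm.
exemplar_feature <- function(frame, box, cfg) {
  cr <- crop_and_resize(frame, box, cfg$context_factor, cfg$template_size)
  extract_features(cr$patch, cfg$extractor, cfg$feature_stride,
                   normalize = TRUE, affine = cr$affine)
}

#' Harvest detector exemplars from a trajectory
#'
#' Appends, for every record with source `"auto"` and confidence at least
#' `bank$min_harvest_confidence`, the feature of the record's box to the
#' bank. Only automatic records qualify -- corrected and detected records
#' are never harvested. When the bank overflows `max_size`, seeded
#' reservoir sampling keeps a uniform subsample of everything seen.
#'
#' @param traj A [trajectory()].
#' @param frames The frames the trajectory was tracked on.
#' @param bank An [exemplar_bank()].
#' @param cfg The [tracker_config()] used for tracking (crop geometry).
#' @param seed Integer seed for the reservoir.
#' @return The updated [exemplar_bank()].
#' @export
harvest_exemplars <- function(traj, frames, bank, cfg = tracker_config(),
                              seed = 0L) {
  stopifnot(inherits(bank, "exemplar_bank"))
  frame_by_index <- stats::setNames(frames,
                                    vapply(frames, function(f) as.character(f$index), ""))
  qual <- which(traj$source == "auto" &
                  traj$confidence >= bank$min_harvest_confidence)
  with_seed(seed + bank$n_seen, {
    for (i in qual) {
      fr <- frame_by_index[[as.character(traj$frame[i])]]
      if (is.null(fr)) stopf("harvest_exemplars: no frame with index %d", traj$frame[i])
      ex <- list(feat = exemplar_feature(fr, trajectory_box(traj, i), cfg),
                 box_size = c(traj$w[i], traj$h[i]))
      bank$n_seen <- bank$n_seen + 1L
      if (length(bank$exemplars) < bank$max_size) {
        bank$exemplars[[length(bank$exemplars) + 1L]] <- ex
      } else {
        # reservoir sampling: replace a random slot with probability
        # max_size / n_seen
        j <- sample.int(bank$n_seen, 1L)
        if (j <= bank$max_size) bank$exemplars[[j]] <- ex
      }
    }
    bank
  })
}

#' Detection configuration
#'
#' @param activation_threshold Tracking confidence below which the detector
#'   is consulted (default 0.3).
#' @param accept_score_fraction A detection is accepted if its normalized
#'   correlation reaches this fraction of the bank's mean self-match score
#'   (default 0.7).
#' @param scan_stride Coarse scan stride over the frame, px (default 8).
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(activation_threshold = 0.3,
                             accept_score_fraction = 0.7,
                             scan_stride = 8L) {
  if (activation_threshold < 0 || activation_threshold > 1) {
    stopf("detection_config: activation_threshold must lie in [0, 1]")
  }
  if (scan_stride < 1L) stopf("detection_config: scan_stride must be >= 1")
  structure(list(activation_threshold = as.numeric(activation_threshold),
                 accept_score_fraction = as.numeric(accept_score_fraction),
                 scan_stride = as.integer(scan_stride)),
            class = "detection_config")
}

# Cosine score of a candidate window center against the bank: the window
# feature is extracted exactly like an exemplar and compared by normalized
# correlation (both unit Frobenius norm); score = max over exemplars.
window_score <- function(frame, cx, cy, w, h, bank, cfg) {
  box <- bbox_from_center(cx, cy, w, h)
  f <- exemplar_feature(frame, box, cfg)$grid
  best <- -Inf
  for (ex in bank$exemplars) {
    sc <- sum(f * ex$feat$grid)
    if (sc > best) best <- sc
  }
  best
}

#' Detect the target anywhere in a frame
#'
#' Scans the whole frame with windows of the bank's median source-box size:
#' a coarse grid at `scan_stride`, then a fine local refinement (2 px steps)
#' around the best coarse windows. Each window is scored by the maximum
#' normalized correlation of its feature against the bank's exemplars; the
#' best window is returned only if its score reaches
#' `accept_score_fraction` times the bank's mean self-match score.
#'
#' @param frame A [frame_image()].
#' @param bank A non-empty [exemplar_bank()].
#' @param cfg A [detection_config()].
#' @param tracker_cfg The [tracker_config()] defining crop geometry.
#' @return `NULL` if nothing acceptable is found, else
#'   `list(box = bbox, score, confidence)` with `confidence` the score
#'   divided by the self-match score, clipped to `[0, 1]`.
#' @export
detect <- function(frame, bank, cfg = detection_config(),
                   tracker_cfg = tracker_config()) {
  stopifnot(inherits(bank, "exemplar_bank"))
  if (bank_size(bank) == 0L) stopf("detect: empty exemplar bank")
  sizes <- vapply(bank$exemplars, function(e) e$box_size, numeric(2))
  w_med <- stats::median(sizes[1, ])
  h_med <- stats::median(sizes[2, ])
  st <- cfg$scan_stride
  xs <- seq(st / 2, frame$width - st / 2, by = st)
  ys <- seq(st / 2, frame$height - st / 2, by = st)
  # self-match: each exemplar against itself, averaged
  self_match <- mean(vapply(bank$exemplars,
                            function(e) sum(e$feat$grid^2), 0))
  if (self_match <= 0) return(NULL)

  # coarse scan
  grid <- expand.grid(cx = xs, cy = ys)
  coarse <- vapply(seq_len(nrow(grid)), function(i) {
    window_score(frame, grid$cx[i], grid$cy[i], w_med, h_med, bank, tracker_cfg)
  }, 0)
  # a window centered up to scan_stride/2 off the object scores far below a
  # centered one, so refine around the top coarse candidates, not just the
  # best: first at 2 px steps, then at 1 px around the running best
  top <- order(coarse, decreasing = TRUE)[seq_len(min(5L, length(coarse)))]
  best <- list(score = -Inf, cx = NA_real_, cy = NA_real_)
  probe <- function(cx, cy) {
    cx <- min(max(cx, 0), frame$width)
    cy <- min(max(cy, 0), frame$height)
    sc <- window_score(frame, cx, cy, w_med, h_med, bank, tracker_cfg)
    if (sc > best$score) best <<- list(score = sc, cx = cx, cy = cy)
  }
  offs2 <- seq(-st / 2, st / 2, by = 2)
  for (k in top) {
    for (dy in offs2) for (dx in offs2) probe(grid$cx[k] + dx, grid$cy[k] + dy)
  }
  ctr <- best
  for (dy in -1:1) for (dx in -1:1) {
    if (dx != 0 || dy != 0) probe(ctr$cx + dx, ctr$cy + dy)
  }
  if (best$score < cfg$accept_score_fraction * self_match) return(NULL)
  list(box = bbox_from_center(best$cx, best$cy, w_med, h_med),
       score = best$score,
       confidence = min(max(best$score / self_match, 0), 1))
}

#' Confidence-gated tracking step with detection fallback
#'
#' Runs [track_step()]; if the resulting confidence is at least
#' `cfg$activation_threshold` the result is returned unchanged (source
#' `"auto"`). Otherwise the detector is consulted: on success the current
#' box is re-seeded to the detection (distractor memory cleared, template
#' untouched) and a `"detected"` record emitted with the detection
#' confidence; on no-detection the tracker's own output is kept -- the
#' detector is advisory, it guides but never blocks tracking.
#'
#' @param state A [track_state()].
#' @param frame The next [frame_image()].
#' @param tracker_cfg A [tracker_config()].
#' @param bank An [exemplar_bank()] (may be empty; an empty bank is never
#'   consulted).
#' @param cfg A [detection_config()].
#' @return `list(state, record, invoked)` where `invoked` is 1 if the
#'   detector was consulted, else 0.
#' @export
gated_step <- function(state, frame, tracker_cfg, bank,
                       cfg = detection_config()) {
  res <- track_step(state, frame, tracker_cfg)
  conf <- res$record$confidence[1]
  if (conf >= cfg$activation_threshold || bank_size(bank) == 0L) {
    return(list(state = res$state, record = res$record, invoked = 0L,
                step_confidence = conf))
  }
  det <- detect(frame, bank, cfg, tracker_cfg)
  if (is.null(det)) {
    return(list(state = res$state, record = res$record, invoked = 1L,
                step_confidence = conf))
  }
  st <- res$state
  st$current_box <- det$box
  st$distractors <- list()
  st$last_confidence <- det$confidence
  list(state = st,
       record = trajectory_row(frame$index, det$box, det$confidence, "detected"),
       invoked = 1L, step_confidence = conf)
}

#' Write / read an exemplar bank as JSON
#'
#' The bank is persisted as a JSON document with a manifest (exemplar count,
#' feature shape, sizes) and the flattened feature values, so banks are
#' portable, diffable text.
#'
#' @param bank An [exemplar_bank()].
#' @param path File path.
#' @export
write_exemplar_bank <- function(bank, path) {
  stopifnot(inherits(bank, "exemplar_bank"))
  shape <- if (bank_size(bank) > 0L) dim(bank$exemplars[[1]]$feat$grid) else integer(3)
  doc <- list(
    manifest = list(n_exemplars = bank_size(bank), feature_shape = shape,
                    max_size = bank$max_size,
                    min_harvest_confidence = bank$min_harvest_confidence,
                    n_seen = bank$n_seen),
    exemplars = lapply(bank$exemplars, function(e) {
      list(box_size = e$box_size, stride = e$feat$stride,
           origin = e$feat$origin, values = as.numeric(e$feat$grid))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_exemplar_bank
#' @export
read_exemplar_bank <- function(path) {
  if (!file.exists(path)) stopf("bank file does not exist: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  bank <- exemplar_bank(max_size = doc$manifest$max_size,
                        min_harvest_confidence = doc$manifest$min_harvest_confidence)
  bank$n_seen <- as.integer(doc$manifest$n_seen)
  shape <- as.integer(doc$manifest$feature_shape)
  n <- as.integer(doc$manifest$n_exemplars)
  if (n > 0L) {
    bank$exemplars <- lapply(seq_len(n), function(i) {
      e <- if (is.data.frame(doc$exemplars)) {
        list(box_size = doc$exemplars$box_size[[i]],
             stride = doc$exemplars$stride[[i]],
             origin = doc$exemplars$origin[[i]],
             values = doc$exemplars$values[[i]])
      } else {
        doc$exemplars[[i]]
      }
      list(feat = feature_map(array(as.numeric(e$values), dim = shape),
                              stride = as.numeric(e$stride),
                              origin = as.numeric(e$origin)),
           box_size = as.numeric(e$box_size))
    })
  }
  bank
}
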