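# Trajectory, annotation and correction I/O.
#
# All CSV dialects are UTF-8, comma-separated, with a mandatory header:
#   trajectory:  frame,x,y,w,h,confidence,source
#   annotations: frame,x,y,w,h
#   corrections: frame,x,y,w,h

trajectory_sources <- c("auto", "corrected", "detected")

#' Tracking trajectory
#'
#' One record per tracked frame: the output box, the tracker's confidence in
#' `[0, 1]`, and the record source -- `"auto"` (tracker), `"corrected"`
#' (human annotation, including the defining first-frame box), or
#' `"detected"` (re-seeded by the detection module). Frame indices must be
#' strictly increasing and record 1 must have source `"corrected"`: the
#' initial user annotation is bookkept as a correction (but excluded from
#' label-effort percentages, see [label_effort()]).
#'
#' @param records `data.frame` with columns `frame`, `x`, `y`, `w`, `h`,
#'   `confidence`, `source`.
#' @param video_id Identifier string carried along with the trajectory.
#' @return Object of class `trajectory` (a data.frame).
#' @export
trajectory <- function(records, video_id = "") {
  req <- c("frame", "x", "y", "w", "h", "confidence", "source")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stopf("trajectory: records must have columns %s", paste(req, collapse = ","))
  }
  if (nrow(records) == 0L) stopf("trajectory: records must be non-empty")
  records <- records[, req]
  records$frame <- as.integer(records$frame)
  for (col in c("x", "y", "w", "h", "confidence")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records$source <- as.character(records$source)
  if (any(diff(records$frame) <= 0L)) {
    stopf("trajectory: frame indices must be strictly increasing")
  }
  if (any(records$w <= 0) || any(records$h <= 0)) {
    stopf("trajectory: all boxes must have positive size")
  }
  if (any(records$confidence < 0 | records$confidence > 1)) {
    stopf("trajectory: confidence must lie in [0, 1]")
  }
  if (!all(records$source %in% trajectory_sources)) {
    stopf("trajectory: sources must be one of %s",
          paste(trajectory_sources, collapse = "/"))
  }
  if (records$source[1] != "corrected") {
    stopf("trajectory: record 1 must have source 'corrected' (the initial annotation)")
  }
  structure(records, class = c("trajectory", "data.frame"),
            video_id = as.character(video_id))
}

trajectory_row <- function(frame, box, confidence, source) {
  data.frame(frame = as.integer(frame), x = box$x, y = box$y,
             w = box$w, h = box$h, confidence = confidence, source = source,
             stringsAsFactors = FALSE)
}

# Box of the i-th record (1-based row).
trajectory_box <- function(traj, i) {
  bbox(traj$x[i], traj$y[i], traj$w[i], traj$h[i])
}

#' Write / read a trajectory CSV
#'
#' CSV with header `frame,x,y,w,h,confidence,source`; numeric fields are
#' written with 15 significant digits so that a read/write round trip
#' reproduces every field to well below 1e-6.
#'
#' @param traj A [trajectory()].
#' @param path Output/input file path.
#' @return `read_trajectory()` returns a [trajectory()]; `write_trajectory()`
#'   returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  traj <- trajectory(as.data.frame(traj), attr(traj, "video_id") %||% "")
  df <- as.data.frame(traj)
  for (col in c("x", "y", "w", "h", "confidence")) {
    df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  }
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stopf("trajectory file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("frame", "x", "y", "w", "h", "confidence", "source")
  if (!all(req %in% names(df))) {
    stopf("malformed trajectory CSV (header must be %s): %s",
          paste(req, collapse = ","), path)
  }
  for (col in c("frame", "x", "y", "w", "h", "confidence")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stopf("malformed trajectory CSV: non-numeric '%s' on data line %d of %s",
            col, bad[1], path)
    }
    df[[col]] <- v
  }
  trajectory(df, video_id = basename(path))
}

#' Read ground-truth annotations
#'
#' CSV with header `frame,x,y,w,h`; frames may be sparse (not every frame
#' annotated). Duplicate frame indices are rejected as ambiguous ground
#' truth, as are non-positive box sizes.
#'
#' @param path Annotation CSV path.
#' @return Named list mapping frame index (as character) to [bbox()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("frame", "x", "y", "w", "h")
  if (!all(req %in% names(df))) {
    stopf("malformed annotation CSV (header must be %s): %s",
          paste(req, collapse = ","), path)
  }
  bad <- which(df$w <= 0 | df$h <= 0)
  if (length(bad) > 0L) {
    stopf("annotation row %d has non-positive box size in %s", bad[1], path)
  }
  if (anyDuplicated(df$frame)) {
    stopf("duplicate frame index %d in annotations %s (ambiguous ground truth)",
          df$frame[anyDuplicated(df$frame)], path)
  }
  boxes <- lapply(seq_len(nrow(df)), function(i) {
    bbox(df$x[i], df$y[i], df$w[i], df$h[i])
  })
  names(boxes) <- as.character(as.integer(df$frame))
  boxes
}

#' Write annotations (frame -> box map) as CSV
#'
#' @param truth Named list mapping frame index to [bbox()] (as produced by
#'   [read_annotations()] or [generate_scene()]).
#' @param path Output CSV path.
#' @export
write_annotations <- function(truth, path) {
  frames <- as.integer(names(truth))
  df <- data.frame(
    frame = frames,
    x = vapply(truth, function(b) b$x, 0),
    y = vapply(truth, function(b) b$y, 0),
    w = vapply(truth, function(b) b$w, 0),
    h = vapply(truth, function(b) b$h, 0)
  )
  df <- df[order(df$frame), ]
  for (col in c("x", "y", "w", "h")) {
    df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  }
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Correction event
#'
#' A human re-annotation at a given frame: the tracker's template is replaced
#' by the features of `box` on that frame and tracking resumes from there.
#'
#' @param frame_index 0-based frame index.
#' @param box A [bbox()].
#' @return Object of class `correction_event`.
#' @export
correction_event <- function(frame_index, box) {
  stopifnot(is_bbox(box))
  structure(list(frame_index = as.integer(frame_index), box = box),
            class = "correction_event")
}

#' Read correction events from CSV
#'
#' Same dialect as annotations: header `frame,x,y,w,h`.
#'
#' @param path Corrections CSV path.
#' @return List of [correction_event()] sorted by frame index.
#' @export
read_corrections <- function(path) {
  boxes <- read_annotations(path)
  idx <- as.integer(names(boxes))
  ord <- order(idx)
  Map(correction_event, idx[ord], boxes[ord])
}
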