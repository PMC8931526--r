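# Human-in-the-loop correction and label-effort bookkeeping.

#' Apply a human correction to the tracking state
#'
#' Replaces the template with the features of `box` on the current frame --
#' the correction becomes the new defining annotation of the target -- sets
#' the current box to `box`, clears the distractor memory, and resets the
#' confidence to 1. Tracking then resumes forward from this breaking point.
#'
#' @param state A [track_state()].
#' @param frame The [frame_image()] being corrected.
#' @param box The corrected [bbox()].
#' @param cfg A [tracker_config()].
#' @return A fresh [track_state()].
#' @export
apply_correction <- function(state, frame, box, cfg = tracker_config()) {
  stopifnot(inherits(state, "track_state"))
  track_init(frame, box, cfg)
}

#' Correction log
#'
#' The corrections applied during a run, for label-effort accounting.
#' Events must be sorted by frame index with no duplicates; the defining
#' first-frame annotation is not an event.
#'
#' @param events List of [correction_event()]s.
#' @param total_frames Total number of tracked frames, >= 1.
#' @return Object of class `correction_log`.
#' @export
correction_log <- function(events, total_frames) {
  total_frames <- as.integer(total_frames)
  if (total_frames < 1L) stopf("correction_log: total_frames must be >= 1")
  idx <- vapply(events, function(e) e$frame_index, integer(1))
  if (is.unsorted(idx, strictly = TRUE) && length(idx) > 1L) {
    stopf("correction_log: events must be sorted by frame index, no duplicates")
  }
  structure(list(events = events, total_frames = total_frames),
            class = "correction_log")
}

#' Label effort of a run
#'
#' The percentage of frames a human had to correct:
#' `100 * n_corrections / total_frames`. The defining first-frame
#' annotation is excluded -- it is the "snapshot" that starts tracking, not
#' a correction of it.
#'
#' @param log A [correction_log()].
#' @return Percentage in `[0, 100]`.
#' @examples
#' ev <- lapply(c(10L, 20L, 30L), correction_event, box = bbox(0, 0, 5, 5))
#' label_effort(correction_log(ev, 300L))  # 1 %
#' @export
label_effort <- function(log) {
  stopifnot(inherits(log, "correction_log"))
  100 * length(log$events) / log$total_frames
}

#' Track with an oracle corrector
#'
#' Emulates the attentive human of a correction workflow: the sequence is
#' tracked forward and whenever a frame's overlap rate against ground truth
#' falls below `or_threshold`, the frame is immediately re-annotated with
#' the true box (template replacement, as [apply_correction()]), and
#' tracking resumes. Used to measure label effort -- the fraction of frames
#' needing correction to keep every frame's overlap above threshold --
#' unattended on synthetic scenes.
#'
#' @param frames List of [frame_image()]s.
#' @param truth Named list mapping frame index to true [bbox()] (every
#'   frame must be present).
#' @param cfg A [tracker_config()].
#' @param or_threshold Overlap-rate threshold triggering a correction.
#' @param seed Integer seed.
#' @return `list(trajectory, log)`: the corrected [trajectory()] and the
#'   [correction_log()] of oracle interventions.
#' @export
track_with_oracle <- function(frames, truth, cfg = tracker_config(),
                              or_threshold = 0.5, seed = 0L) {
  if (length(frames) == 0L) stopf("track_with_oracle: no frames")
  truth_box <- function(idx) {
    b <- truth[[as.character(idx)]]
    if (is.null(b)) stopf("no ground truth for frame %d", idx)
    b
  }
  with_seed(seed, {
    init <- truth_box(frames[[1]]$index)
    state <- track_init(frames[[1]], init, cfg)
    rows <- vector("list", length(frames))
    rows[[1]] <- trajectory_row(frames[[1]]$index, init, 1.0, "corrected")
    events <- list()
    for (i in seq_along(frames)[-1]) {
      fr <- frames[[i]]
      res <- track_step(state, fr, cfg)
      tb <- truth_box(fr$index)
      if (overlap_rate(trajectory_box(res$record, 1L), tb) < or_threshold) {
        state <- apply_correction(state, fr, tb, cfg)
        rows[[i]] <- trajectory_row(fr$index, tb, 1.0, "corrected")
        events[[length(events) + 1L]] <- correction_event(fr$index, tb)
      } else {
        state <- res$state
        rows[[i]] <- res$record
      }
    }
    list(trajectory = trajectory(do.call(rbind, rows), video_id = "oracle"),
         log = correction_log(events, length(frames)))
  })
}
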