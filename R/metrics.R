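# Evaluation criteria: overlap rate, pixel error, success/accuracy/error
# rates, report assembly, and the box-size sensitivity sweep.

#' Overlap rate (intersection over union)
#'
#' The ratio of intersection area to union area of two boxes under the
#' half-open region convention, so `area = w * h` exactly and boxes sharing
#' only an edge have overlap 0. Symmetric; 1 iff the boxes are identical;
#' invariant under joint translation.
#'
#' @param a,b [bbox()]es.
#' @return Overlap in `[0, 1]`.
#' @examples
#' overlap_rate(bbox(0, 0, 4, 4), bbox(2, 0, 4, 4))  # 8/24 = 1/3
#' @export
overlap_rate <- function(a, b) {
  stopifnot(is_bbox(a), is_bbox(b))
  ix <- min(a$x + a$w, b$x + b$w) - max(a$x, b$x)
  iy <- min(a$y + a$h, b$y + b$h) - max(a$y, b$y)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Pixel error (center distance)
#'
#' Euclidean distance between two centers; [bbox()] inputs are reduced to
#' their centers.
#'
#' @param result,truth Numeric `c(x, y)` centers or [bbox()]es.
#' @return Distance in pixels.
#' @export
pixel_error <- function(result, truth) {
  p <- if (is_bbox(result)) bbox_center(result) else as.numeric(result)
  q <- if (is_bbox(truth)) bbox_center(truth) else as.numeric(truth)
  if (any(!is.finite(c(p, q)))) stopf("pixel_error: non-finite coordinates")
  sqrt(sum((p - q)^2))
}

#' Evaluate a trajectory against ground truth
#'
#' Computes per-frame overlap-rate (OR) and pixel-error (PE) series over the
#' frames present in both trajectory and truth, and the derived rates:
#' `success_rate` is the fraction of frames with `OR >= or_threshold`
#' (inclusive at the boundary), `error_rate = 1 - success_rate` exactly, and
#' `accuracy` is the fraction of frames with `PE < pe_threshold` (strict:
#' a PE exactly at the threshold is not successful). Frames missing from
#' the truth are excluded and counted in `n_excluded`.
#'
#' @param traj A [trajectory()].
#' @param truth Named list mapping frame index to [bbox()].
#' @param log Optional [correction_log()] for label-effort reporting.
#' @param or_threshold OR success threshold (default 0.5).
#' @param pe_threshold PE success threshold in px (default 20).
#' @return Object of class `eval_report` with fields `or_series`,
#'   `pe_series`, `frames`, `success_rate`, `accuracy`, `error_rate`,
#'   `label_effort_percent`, `n_frames`, `n_excluded`, and the thresholds.
#' @export
evaluate <- function(traj, truth, log = NULL, or_threshold = 0.5,
                     pe_threshold = 20) {
  stopifnot(inherits(traj, "trajectory") || is.data.frame(traj))
  have <- as.character(traj$frame) %in% names(truth)
  if (!any(have)) stopf("evaluate: no trajectory frame has ground truth")
  idx <- which(have)
  ors <- numeric(length(idx))
  pes <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    tb <- truth[[as.character(traj$frame[i])]]
    rb <- trajectory_box(traj, i)
    ors[k] <- overlap_rate(rb, tb)
    pes[k] <- pixel_error(rb, tb)
  }
  success <- mean(ors >= or_threshold)
  report <- list(
    or_series = ors,
    pe_series = pes,
    frames = traj$frame[idx],
    success_rate = success,
    accuracy = mean(pes < pe_threshold),
    error_rate = 1 - success,
    label_effort_percent = if (is.null(log)) NA_real_ else label_effort(log),
    n_frames = length(idx),
    n_excluded = sum(!have),
    or_threshold = or_threshold,
    pe_threshold = pe_threshold
  )
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report over %d frames (%d without truth)>\n",
              x$n_frames, x$n_excluded))
  cat(sprintf("  success rate (OR >= %.2f): %.4f\n", x$or_threshold, x$success_rate))
  cat(sprintf("  error rate:                %.4f\n", x$error_rate))
  cat(sprintf("  accuracy (PE < %g px):     %.4f\n", x$pe_threshold, x$accuracy))
  if (!is.na(x$label_effort_percent)) {
    cat(sprintf("  label effort:              %.4f %%\n", x$label_effort_percent))
  }
  invisible(x)
}

#' Box-size sensitivity sweep
#'
#' The overlap-rate criterion is sensitive to how tightly the annotation
#' circumscribes the target (the tightest circumscribing rectangle is the
#' recommended convention). This helper re-evaluates a trajectory against
#' ground-truth boxes inflated or deflated about their centers by each
#' factor, reporting the resulting success rates.
#'
#' @param traj A [trajectory()].
#' @param truth Named list mapping frame index to [bbox()].
#' @param factors Multiplicative size factors to sweep.
#' @param or_threshold OR success threshold.
#' @return `data.frame(factor, success_rate)`.
#' @export
box_size_sensitivity <- function(traj, truth,
                                 factors = c(0.6, 0.8, 1, 1.25, 1.5),
                                 or_threshold = 0.5) {
  rates <- vapply(factors, function(f) {
    scaled <- lapply(truth, function(b) {
      ctr <- bbox_center(b)
      bbox_from_center(ctr[1], ctr[2], b$w * f, b$h * f)
    })
    evaluate(traj, scaled, or_threshold = or_threshold)$success_rate
  }, 0)
  data.frame(factor = factors, success_rate = rates)
}
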