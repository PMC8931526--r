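# Seeded synthetic-scene generator with exact ground truth.
#
# Scenes emulate the experimental axes behavioral tracking is exposed to: a
# textured background, a soft-edged moving target blob, visually identical
# distractor blobs that approach or cross the target's path (rendered on top
# of the target -- the hardest case), multiplicative illumination drift,
# brief occlusion, and sudden fast motion. Ground-truth boxes are the
# circumscribed rectangles of the rendered target, exact by construction.

#' Synthetic scene configuration
#'
#' @param n_frames Number of frames, >= 1.
#' @param frame_size `c(height, width)` in px.
#' @param background `list(type = "texture"|"flat", base, amplitude, grain)`:
#'   a static background at intensity `base`, for `"texture"` overlaid with
#'   seeded smooth noise of standard deviation `amplitude` and correlation
#'   length ~`grain` px.
#' @param target `list(shape = "disc"|"ellipse"|"rounded-rect", width,
#'   height, intensity, texture_amp, ramp)`: blob size in px, its intensity,
#'   the amplitude of its internal texture (which moves with it), and the
#'   anti-aliasing edge ramp in px (~1 px so sub-pixel motion changes pixel
#'   values smoothly).
#' @param motion `list(type = "linear"|"sinusoidal"|"random-walk", start,
#'   velocity, amplitude, period, step_sd, jump)`: `start` is the initial
#'   center `c(x, y)`; `velocity` the px/frame drift; sinusoidal motion adds
#'   `amplitude * sin(2 pi t / period)`; random walks integrate seeded
#'   velocity noise of sd `step_sd`; `jump = list(frame, offset)` teleports
#'   the center by `offset` at `frame` (fast motion between two frames).
#'   Paths are reflected off the frame borders so the target always stays
#'   at least 1 px inside; truth is recorded after reflection.
#' @param distractors List of `list(start, velocity, step_sd)` blobs rendered
#'   from the identical target sprite, drawn over the target.
#' @param illumination `list(amplitude, period)`: multiplicative drift
#'   `1 + amplitude * sin(2 pi t / period)`, clipped to `[0, 1]` after
#'   application.
#' @param occluder `list(frames = c(t0, t1), coverage, value)`: a rectangle
#'   `coverage` times the target size, drawn over the target's true position
#'   during frames `t0..t1` (`value = NULL` uses the background base).
#' @param seed Integer seed; scenes are bit-identical for a fixed config.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(n_frames,
                         frame_size = c(96L, 96L),
                         background = list(),
                         target = list(),
                         motion = list(),
                         distractors = list(),
                         illumination = list(),
                         occluder = NULL,
                         seed = 1L) {
  background <- utils::modifyList(
    list(type = "texture", base = 0.4, amplitude = 0.06, grain = 3L), background)
  target <- utils::modifyList(
    list(shape = "ellipse", width = 16, height = 12, intensity = 0.85,
         texture_amp = 0.35, ramp = 1), target)
  motion <- utils::modifyList(
    list(type = "linear", start = c(frame_size[2] / 2, frame_size[1] / 2),
         velocity = c(0, 0), amplitude = c(0, 0), period = max(n_frames, 2L),
         step_sd = 0, jump = NULL), motion)
  illumination <- utils::modifyList(list(amplitude = 0, period = max(n_frames, 2L)),
                                    illumination)
  cfg <- structure(list(
    n_frames = as.integer(n_frames), frame_size = as.integer(frame_size),
    background = background, target = target, motion = motion,
    distractors = distractors, illumination = illumination,
    occluder = occluder, seed = as.integer(seed)), class = "scene_config")
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (cfg$n_frames < 1L) stopf("scene_config: n_frames must be >= 1")
  if (any(cfg$frame_size < 16L)) stopf("scene_config: frames must be >= 16 px")
  tg <- cfg$target
  if (!tg$shape %in% c("disc", "ellipse", "rounded-rect")) {
    stopf("scene_config: unknown target shape '%s'", tg$shape)
  }
  if (tg$width <= 2 || tg$height <= 2) stopf("scene_config: target too small")
  hw <- tg$width / 2
  hh <- tg$height / 2
  lo <- c(hw + 1, hh + 1)
  hi <- c(cfg$frame_size[2] - hw - 1, cfg$frame_size[1] - hh - 1)
  if (any(hi <= lo)) stopf("scene_config: target cannot fit inside the frame")
  st <- cfg$motion$start
  if (st[1] < lo[1] || st[1] > hi[1] || st[2] < lo[2] || st[2] > hi[2]) {
    stopf("scene_config: motion start places the target outside the frame")
  }
  invisible(cfg)
}

# Reflect positions into [lo, hi] (triangle-wave folding), keeping blobs
# at least 1 px inside the frame.
reflect_into <- function(p, lo, hi) {
  r <- hi - lo
  if (r <= 0) return(rep(lo, length(p)))
  q <- (p - lo) %% (2 * r)
  lo + pmin(q, 2 * r - q)
}

# Per-frame center positions (n x 2 matrix of x, y) for a motion spec.
# Consumes RNG for random walks; call inside with_seed().
motion_path <- function(motion, n, lo, hi) {
  t <- seq_len(n) - 1
  pos <- switch(motion$type,
    linear = cbind(motion$start[1] + t * motion$velocity[1],
                   motion$start[2] + t * motion$velocity[2]),
    sinusoidal = cbind(
      motion$start[1] + t * motion$velocity[1] +
        motion$amplitude[1] * sin(2 * pi * t / motion$period),
      motion$start[2] + t * motion$velocity[2] +
        motion$amplitude[2] * sin(2 * pi * t / motion$period)),
    `random-walk` = {
      vx <- motion$velocity[1] + cumsum(stats::rnorm(n, 0, motion$step_sd))
      vy <- motion$velocity[2] + cumsum(stats::rnorm(n, 0, motion$step_sd))
      cbind(motion$start[1] + cumsum(vx) - vx[1],
            motion$start[2] + cumsum(vy) - vy[1])
    },
    stopf("unknown motion type '%s'", motion$type)
  )
  if (!is.null(motion$jump)) {
    j <- motion$jump
    late <- t >= j$frame
    pos[late, 1] <- pos[late, 1] + j$offset[1]
    pos[late, 2] <- pos[late, 2] + j$offset[2]
  }
  cbind(reflect_into(pos[, 1], lo[1], hi[1]),
        reflect_into(pos[, 2], lo[2], hi[2]))
}

# Signed-edge alpha mask of a blob over pixel-center grids xg, yg.
blob_alpha <- function(shape, xg, yg, cx, cy, hw, hh, ramp) {
  if (shape %in% c("disc", "ellipse")) {
    rho <- sqrt(((xg - cx) / hw)^2 + ((yg - cy) / hh)^2)
    pmin(pmax((1 - rho) * min(hw, hh) / ramp + 0.5, 0), 1)
  } else {
    r <- 0.3 * min(hw, hh)
    dx <- abs(xg - cx) - (hw - r)
    dy <- abs(yg - cy) - (hh - r)
    d <- sqrt(pmax(dx, 0)^2 + pmax(dy, 0)^2) + pmin(pmax(dx, dy), 0) - r
    pmin(pmax(0.5 - d / ramp, 0), 1)
  }
}

# Composite a textured blob onto `mat` at continuous center (cx, cy).
render_blob <- function(mat, cx, cy, tg, sprite_tex) {
  hw <- tg$width / 2
  hh <- tg$height / 2
  pad <- ceiling(max(hw, hh) + tg$ramp + 1)
  rows <- max(1L, floor(cy - pad)):min(nrow(mat), ceiling(cy + pad))
  cols <- max(1L, floor(cx - pad)):min(ncol(mat), ceiling(cx + pad))
  if (length(rows) == 0L || length(cols) == 0L) return(mat)
  xg <- matrix(rep(cols - 0.5, each = length(rows)), length(rows))
  yg <- matrix(rep(rows - 0.5, times = length(cols)), length(rows))
  alpha <- blob_alpha(tg$shape, xg, yg, cx, cy, hw, hh, tg$ramp)
  fg <- tg$intensity
  if (tg$texture_amp > 0) {
    # texture sampled in sprite coordinates: it travels with the blob
    tu <- (xg - cx) / (2 * hw) + 0.5
    tv <- (yg - cy) / (2 * hh) + 0.5
    tex <- matrix(bilinear_at(sprite_tex,
                              tu * (ncol(sprite_tex) - 1) + 1,
                              tv * (nrow(sprite_tex) - 1) + 1, pad = NULL),
                  length(rows))
    fg <- pmin(pmax(tg$intensity * (1 + tg$texture_amp * (tex - 0.5)), 0), 1)
  }
  mat[rows, cols] <- mat[rows, cols] * (1 - alpha) + fg * alpha
  mat
}

#' Generate a synthetic scene
#'
#' Renders the configured scene deterministically (bit-identical frames for
#' a fixed config) and returns the frames together with exact ground truth:
#' the circumscribed rectangle of the target blob on every frame, and the
#' boxes of all distractors. Distractors are rendered from the identical
#' target sprite, drawn over the target, so a crossing fully occludes it.
#' Illumination drift is applied multiplicatively and frames clipped to
#' `[0, 1]`.
#'
#' @param cfg A [scene_config()].
#' @return `list(frames, truth, distractor_truth)`: frames as
#'   [frame_image()]s, `truth` a named list mapping frame index to [bbox()],
#'   `distractor_truth` a named list of lists of [bbox()].
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  h <- cfg$frame_size[1]
  w <- cfg$frame_size[2]
  n <- cfg$n_frames
  tg <- cfg$target
  hw <- tg$width / 2
  hh <- tg$height / 2
  lo <- c(hw + 1, hh + 1)
  hi <- c(w - hw - 1, h - hh - 1)
  with_seed(cfg$seed, {
    bg <- matrix(cfg$background$base, h, w)
    if (cfg$background$type == "texture") {
      noise <- box_mean(matrix(stats::runif(h * w), h, w),
                        max(1L, as.integer(cfg$background$grain)))
      noise <- (noise - mean(noise)) / max(stats::sd(noise), 1e-9)
      bg <- bg + cfg$background$amplitude * noise
    }
    bg <- pmin(pmax(bg, 0.02), 0.98)
    sprite_tex <- box_mean(matrix(stats::runif(24 * 24), 24, 24), 3L)
    sprite_tex <- (sprite_tex - min(sprite_tex)) /
      max(max(sprite_tex) - min(sprite_tex), 1e-9)
    path <- motion_path(cfg$motion, n, lo, hi)
    dpaths <- lapply(cfg$distractors, function(d) {
      dm <- utils::modifyList(
        list(type = if ((d$step_sd %||% 0) > 0) "random-walk" else "linear",
             start = d$start, velocity = d$velocity %||% c(0, 0),
             amplitude = c(0, 0), period = max(n, 2L),
             step_sd = d$step_sd %||% 0, jump = NULL), list())
      motion_path(dm, n, lo, hi)
    })
    frames <- vector("list", n)
    truth <- vector("list", n)
    dtruth <- vector("list", n)
    for (t in seq_len(n)) {
      m <- bg
      m <- render_blob(m, path[t, 1], path[t, 2], tg, sprite_tex)
      for (dp in dpaths) m <- render_blob(m, dp[t, 1], dp[t, 2], tg, sprite_tex)
      if (!is.null(cfg$occluder)) {
        oc <- cfg$occluder
        if (t - 1 >= oc$frames[1] && t - 1 <= oc$frames[2]) {
          ow <- oc$coverage * tg$width / 2
          oh <- oc$coverage * tg$height / 2
          rows <- max(1L, floor(path[t, 2] - oh)):min(h, ceiling(path[t, 2] + oh))
          cols <- max(1L, floor(path[t, 1] - ow)):min(w, ceiling(path[t, 1] + ow))
          m[rows, cols] <- oc$value %||% cfg$background$base
        }
      }
      if (cfg$illumination$amplitude > 0) {
        m <- m * (1 + cfg$illumination$amplitude *
                    sin(2 * pi * (t - 1) / cfg$illumination$period))
      }
      m <- pmin(pmax(m, 0), 1)
      frames[[t]] <- frame_image(m, t - 1L)
      truth[[t]] <- bbox(path[t, 1] - hw, path[t, 2] - hh, tg$width, tg$height)
      dtruth[[t]] <- lapply(dpaths, function(dp) {
        bbox(dp[t, 1] - hw, dp[t, 2] - hh, tg$width, tg$height)
      })
    }
    names(truth) <- as.character(seq_len(n) - 1L)
    names(dtruth) <- as.character(seq_len(n) - 1L)
    list(frames = frames, truth = truth, distractor_truth = dtruth)
  })
}

#' Standard benchmark fixtures
#'
#' Named scene configurations exercising the failure modes the tracker is
#' built around, each with a documented seed:
#' * `"easy"` -- 200 frames, textured background, 16 x 12 ellipse bouncing
#'   at 2 px/frame, no distractors.
#' * `"crossing"` -- the target's path runs straight through a parked,
#'   visually identical distractor that occludes it mid-sequence; the
#'   classic drift-inducing encounter.
#' * `"crossing-easy"` -- same geometry but the distractor is parked about
#'   1.5 target widths beside the path (approach without contact).
#' * `"drifty-light"` -- the easy scene under strong sinusoidal
#'   illumination drift.
#' * `"occluded"` -- brief full occlusion by a background-colored patch.
#' * `"jump"` -- sudden fast motion: the target teleports beyond any
#'   plausible search region mid-sequence (the confidence-collapse failure
#'   mode that detection rescue addresses).
#' * `"long"` -- 3000 frames of random-walk target plus an identical
#'   random-walk distractor, for endurance/error-accumulation runs.
#'
#' @param name Fixture name.
#' @param seed Optional seed override (fixtures have stable default seeds).
#' @param n_frames Optional length override.
#' @return A [scene_config()].
#' @export
fixture_scene <- function(name = c("easy", "crossing", "crossing-easy",
                                   "drifty-light", "occluded", "jump", "long"),
                          seed = NULL, n_frames = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    easy = scene_config(
      n_frames = 200L, frame_size = c(96L, 96L),
      target = list(shape = "ellipse", width = 16, height = 12),
      motion = list(type = "linear", start = c(30, 30), velocity = c(1.6, 1.2)),
      seed = 101L),
    crossing = scene_config(
      n_frames = 80L, frame_size = c(96L, 96L),
      target = list(shape = "disc", width = 14, height = 14),
      motion = list(type = "linear", start = c(40, 18), velocity = c(0.2, 0.85)),
      distractors = list(list(start = c(48, 52))),
      seed = 202L),
    `crossing-easy` = scene_config(
      n_frames = 80L, frame_size = c(96L, 96L),
      target = list(shape = "disc", width = 14, height = 14),
      motion = list(type = "linear", start = c(40, 18), velocity = c(0.2, 0.85)),
      distractors = list(list(start = c(69, 52))),
      seed = 203L),
    `drifty-light` = scene_config(
      n_frames = 200L, frame_size = c(96L, 96L),
      target = list(shape = "ellipse", width = 16, height = 12),
      motion = list(type = "linear", start = c(30, 30), velocity = c(1.6, 1.2)),
      illumination = list(amplitude = 0.25, period = 200L),
      seed = 304L),
    occluded = scene_config(
      n_frames = 100L, frame_size = c(96L, 96L),
      target = list(shape = "disc", width = 14, height = 14),
      motion = list(type = "linear", start = c(30, 40), velocity = c(0.5, 0.2)),
      occluder = list(frames = c(60L, 64L), coverage = 1.5, value = NULL),
      seed = 405L),
    jump = scene_config(
      n_frames = 120L, frame_size = c(128L, 128L),
      target = list(shape = "disc", width = 14, height = 14),
      motion = list(type = "linear", start = c(30, 40), velocity = c(0.5, 0.3),
                    jump = list(frame = 60L, offset = c(55, 48))),
      seed = 506L),
    long = scene_config(
      n_frames = 3000L, frame_size = c(96L, 96L),
      target = list(shape = "disc", width = 12, height = 12),
      motion = list(type = "random-walk", start = c(48, 48),
                    velocity = c(0, 0), step_sd = 0.25),
      distractors = list(list(start = c(24, 24), velocity = c(0, 0),
                              step_sd = 0.35)),
      seed = 607L)
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(n_frames)) {
    cfg$n_frames <- as.integer(n_frames)
    cfg <- do.call(scene_config, unclass(cfg))
  }
  cfg
}

#' Write / read a scene configuration as YAML
#'
#' @param cfg A [scene_config()].
#' @param path YAML file path.
#' @export
write_scene_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stopf("scene config does not exist: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(scene_config, vals)
}

#' Write a scene to disk as a frame directory plus ground-truth CSVs
#'
#' Writes zero-padded PNG frames under `dir/frames/`, the target truth as
#' `dir/gt.csv` and, when distractors exist, `dir/distractors.csv` (with a
#' `distractor` id column appended to the annotation dialect).
#'
#' @param scene Result of [generate_scene()].
#' @param dir Output directory (created if missing).
#' @export
write_scene <- function(scene, dir) {
  frame_dir <- file.path(dir, "frames")
  dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in scene$frames) {
    png::writePNG(f$pixels,
                  file.path(frame_dir, sprintf("frame_%06d.png", f$index)))
  }
  write_annotations(scene$truth, file.path(dir, "gt.csv"))
  nd <- length(scene$distractor_truth[[1]])
  if (nd > 0L) {
    rows <- list()
    for (key in names(scene$distractor_truth)) {
      for (d in seq_len(nd)) {
        b <- scene$distractor_truth[[key]][[d]]
        rows[[length(rows) + 1L]] <- data.frame(
          frame = as.integer(key), x = b$x, y = b$y, w = b$w, h = b$h,
          distractor = d)
      }
    }
    utils::write.table(do.call(rbind, rows), file.path(dir, "distractors.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
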