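# Tracking-with-detection: harvest, whole-frame detection, gating.

mk_auto_traj <- function(box, n, conf = 0.9) {
  rows <- lapply(seq_len(n) - 1L, function(f) {
    data.frame(frame = f, x = box$x, y = box$y, w = box$w, h = box$h,
               confidence = if (f == 0L) 1.0 else conf,
               source = if (f == 0L) "corrected" else "auto")
  })
  trajectory(do.call(rbind, rows))
}

test_that("harvesting skips unqualified records and counts qualified ones", {
  scene <- static_blob_scene(n_frames = 12L)
  cfg <- small_cfg()
  b <- scene$truth[["0"]]
  low <- mk_auto_traj(b, 12L, conf = 0.3)
  bank <- harvest_exemplars(low, scene$frames, exemplar_bank(), cfg)
  expect_equal(siamtrack:::bank_size(bank), 0L)   # all below min confidence
  good <- mk_auto_traj(b, 11L, conf = 0.8)
  bank2 <- harvest_exemplars(good, scene$frames[1:11], exemplar_bank(), cfg)
  expect_equal(siamtrack:::bank_size(bank2), 10L)  # 10 qualifying auto records
  # harvest purity: corrected record 0 never enters
  expect_true(all(vapply(bank2$exemplars,
                         function(e) is.numeric(e$box_size), logical(1))))
})

test_that("reservoir downsampling caps the bank reproducibly", {
  scene <- static_blob_scene(n_frames = 1L)
  fr <- scene$frames[[1]]
  frames <- lapply(0:199, function(i) frame_image(fr$pixels, i))
  traj <- mk_auto_traj(scene$truth[["0"]], 200L, conf = 0.9)
  # wobble the boxes so every exemplar crop is distinct
  traj$x <- traj$x + 0.05 * (seq_len(200L) - 1L)
  cfg <- small_cfg()
  b1 <- harvest_exemplars(traj, frames, exemplar_bank(max_size = 50L), cfg, seed = 5L)
  b2 <- harvest_exemplars(traj, frames, exemplar_bank(max_size = 50L), cfg, seed = 5L)
  expect_equal(siamtrack:::bank_size(b1), 50L)
  expect_equal(b1$n_seen, 199L)
  expect_identical(b1$exemplars, b2$exemplars)  # seeded, reproducible
  b3 <- harvest_exemplars(traj, frames, exemplar_bank(max_size = 50L), cfg, seed = 6L)
  expect_false(identical(b1$exemplars, b3$exemplars))
})

test_that("detection finds a planted target and scores self-matches at 1", {
  # blob parked at an integer scan-grid center so the coarse scan can land
  # exactly on it
  scene <- generate_scene(scene_config(
    n_frames = 2L, frame_size = c(96L, 96L),
    target = list(shape = "disc", width = 14, height = 14),
    motion = list(type = "linear", start = c(60, 60), velocity = c(0, 0)),
    seed = 61L))
  cfg <- small_cfg()
  bank <- harvest_exemplars(mk_auto_traj(scene$truth[["0"]], 2L),
                            scene$frames, exemplar_bank(), cfg)
  det <- detect(scene$frames[[2]], bank, detection_config(), cfg)
  expect_false(is.null(det))
  ctr <- bbox_center(det$box)
  expect_lt(max(abs(ctr - c(60, 60))), 8)   # within scan_stride
  expect_equal(det$score, 1, tolerance = 1e-6)  # static scene: exact self-match
  expect_equal(det$confidence, 1, tolerance = 1e-6)
})

test_that("detection declines on an uncorrelated noise frame and empty banks error", {
  scene <- static_blob_scene(n_frames = 2L)
  cfg <- small_cfg()
  bank <- harvest_exemplars(mk_auto_traj(scene$truth[["0"]], 2L),
                            scene$frames, exemplar_bank(), cfg)
  expect_null(detect(noise_frame(0L), bank, detection_config(), cfg))
  expect_error(detect(scene$frames[[1]], exemplar_bank(), detection_config(), cfg),
               "empty exemplar bank")
})

test_that("gating: confident steps never consult the detector; empty banks are advisory", {
  scene <- static_blob_scene(n_frames = 3L)
  cfg <- small_cfg()
  bank <- harvest_exemplars(mk_auto_traj(scene$truth[["0"]], 3L),
                            scene$frames, exemplar_bank(), cfg)
  st <- track_init(scene$frames[[1]], scene$truth[["0"]], cfg)
  res <- gated_step(st, scene$frames[[2]], cfg, bank)
  expect_equal(res$invoked, 0L)             # confidence is high: not invoked
  expect_identical(res$record$source, "auto")
  # low-confidence step with an EMPTY bank: pipeline keeps the auto record
  res2 <- gated_step(st, noise_frame(1L), cfg, exemplar_bank())
  expect_equal(res2$invoked, 0L)
  expect_identical(res2$record$source, "auto")
  expect_lt(res2$step_confidence, 0.5)
})

test_that("a low-confidence step with a loaded bank re-seeds from detection", {
  # the fast-motion scene: the target teleports far beyond the search span
  scene <- generate_scene(fixture_scene("jump"))
  cfg <- small_cfg()
  rows <- lapply(0:19, function(f) {
    b <- scene$truth[[as.character(f)]]
    data.frame(frame = f, x = b$x, y = b$y, w = b$w, h = b$h,
               confidence = if (f == 0L) 1 else 0.9,
               source = if (f == 0L) "corrected" else "auto")
  })
  prefix <- trajectory(do.call(rbind, rows))
  bank <- harvest_exemplars(prefix, scene$frames[1:20], exemplar_bank(), cfg)
  # state locked on the pre-jump position, stepping onto the jump frame
  st <- track_init(scene$frames[[60]], scene$truth[["59"]], cfg)
  res <- gated_step(st, scene$frames[[61]], cfg, bank)
  expect_equal(res$invoked, 1L)
  expect_lt(res$step_confidence, 0.3)
  expect_identical(res$record$source, "detected")
  tb <- scene$truth[["60"]]
  expect_lt(pixel_error(trajectory_box(res$record, 1L), tb), 8)
  expect_length(res$state$distractors, 0L)
})

test_that("exemplar banks round-trip through their JSON archive", {
  scene <- static_blob_scene(n_frames = 3L)
  cfg <- small_cfg()
  bank <- harvest_exemplars(mk_auto_traj(scene$truth[["0"]], 3L),
                            scene$frames, exemplar_bank(), cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_exemplar_bank(bank, path)
  back <- read_exemplar_bank(path)
  expect_equal(siamtrack:::bank_size(back), siamtrack:::bank_size(bank))
  expect_equal(back$exemplars[[1]]$feat$grid, bank$exemplars[[1]]$feat$grid,
               tolerance = 1e-12)
  expect_equal(back$exemplars[[2]]$box_size, bank$exemplars[[2]]$box_size)
})
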