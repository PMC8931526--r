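# Synthetic-scene generator: determinism, ground-truth exactness, motion.

test_that("a static scene renders identical frames with constant truth", {
  scene <- static_blob_scene(n_frames = 4L)
  expect_length(scene$frames, 4L)
  for (i in 2:4) expect_identical(scene$frames[[i]]$pixels, scene$frames[[1]]$pixels)
  for (i in 2:4) expect_identical(scene$truth[[i]], scene$truth[[1]])
})

test_that("generation is bit-deterministic for a fixed config", {
  cfg <- fixture_scene("crossing")
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$frames[[40]]$pixels, s2$frames[[40]]$pixels)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_scene(fixture_scene("crossing", seed = 9L))
  expect_false(identical(s1$frames[[40]]$pixels, s3$frames[[40]]$pixels))
})

test_that("unclamped linear motion is an exact arithmetic progression", {
  scene <- generate_scene(scene_config(
    n_frames = 50L, frame_size = c(160L, 160L),
    target = list(shape = "disc", width = 10, height = 10),
    motion = list(type = "linear", start = c(20, 20), velocity = c(2, 1)),
    seed = 71L))
  cx <- vapply(scene$truth, function(b) b$x + b$w / 2, 0)
  cy <- vapply(scene$truth, function(b) b$y + b$h / 2, 0)
  expect_equal(cx, 20 + 2 * (0:49), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cy, 20 + 1 * (0:49), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("truth boxes always lie fully inside the frame", {
  for (name in c("easy", "crossing", "long")) {
    cfg <- fixture_scene(name)
    cfg$n_frames <- min(cfg$n_frames, 300L)
    cfg <- do.call(scene_config, unclass(cfg))
    scene <- generate_scene(cfg)
    for (b in scene$truth) {
      expect_gte(b$x, 0); expect_gte(b$y, 0)
      expect_lte(b$x + b$w, cfg$frame_size[2])
      expect_lte(b$y + b$h, cfg$frame_size[1])
    }
  }
})

test_that("ground truth evaluated against itself is perfect", {
  scene <- generate_scene(fixture_scene("easy", n_frames = 30L))
  rows <- Map(function(key, b) data.frame(frame = as.integer(key), x = b$x,
                                          y = b$y, w = b$w, h = b$h,
                                          confidence = 1,
                                          source = if (key == "0") "corrected" else "auto"),
              names(scene$truth), scene$truth)
  traj <- trajectory(do.call(rbind, rows))
  rep <- evaluate(traj, scene$truth)
  expect_equal(rep$success_rate, 1)
  expect_equal(rep$error_rate, 0)
  expect_equal(max(rep$pe_series), 0)
})

test_that("the standard fixtures exist under stable names", {
  for (name in c("easy", "crossing", "crossing-easy", "drifty-light",
                 "occluded", "jump", "long")) {
    cfg <- fixture_scene(name)
    expect_s3_class(cfg, "scene_config")
    expect_gte(cfg$n_frames, 60L)
  }
  expect_equal(fixture_scene("long")$n_frames, 3000L)
  expect_error(fixture_scene("no-such"))
})

test_that("impossible motion specs fail at construction", {
  expect_error(scene_config(n_frames = 10L, frame_size = c(32L, 32L),
                            target = list(width = 40, height = 40)),
               "cannot fit")
  expect_error(scene_config(n_frames = 10L,
                            motion = list(start = c(-5, 10))),
               "outside the frame")
})

test_that("scene configs round-trip through YAML", {
  cfg <- fixture_scene("occluded")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_config(cfg, path)
  back <- read_scene_config(path)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(back)
  expect_identical(s1$frames[[50]]$pixels, s2$frames[[50]]$pixels)
})

test_that("illumination drift and occlusion change pixels but not truth", {
  base <- fixture_scene("easy", n_frames = 40L)
  lit <- fixture_scene("drifty-light", n_frames = 40L)
  lit$seed <- base$seed
  s1 <- generate_scene(base)
  s2 <- generate_scene(do.call(scene_config, unclass(lit)))
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$frames[[20]]$pixels, s2$frames[[20]]$pixels))
  occ <- generate_scene(fixture_scene("occluded"))
  # during occlusion the target pixels are hidden: frames 60..64 differ from 59
  expect_false(identical(occ$frames[[61]]$pixels, occ$frames[[60]]$pixels))
})
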