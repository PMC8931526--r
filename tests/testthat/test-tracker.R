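# Matching core: suppression, peak location, confidence, candidate
# selection, and the per-frame / per-sequence drivers.

test_that("suppression with alpha 0 or empty memory is the bit-exact identity", {
  set.seed(41)
  resp <- mk_resp(matrix(rnorm(25), 5, 5))
  sf <- mk_fmap(array(rnorm(9 * 9 * 2), dim = c(9, 9, 2)))
  d <- mk_fmap(array(rnorm(5 * 5 * 2), dim = c(5, 5, 2)))
  expect_identical(suppress_distractors(resp, sf, list(d), 0), resp)
  expect_identical(suppress_distractors(resp, sf, list(), 0.7), resp)
})

test_that("a distractor identical to the template scales the map by (1 - alpha)", {
  set.seed(42)
  tmpl <- mk_fmap(array(rnorm(4 * 4 * 2), dim = c(4, 4, 2)))
  sf <- mk_fmap(array(rnorm(9 * 9 * 2), dim = c(9, 9, 2)))
  resp <- cross_correlate(tmpl, sf)
  sup <- suppress_distractors(resp, sf, list(tmpl), alpha = 0.3)
  expect_equal(sup$scores, 0.7 * resp$scores, tolerance = 1e-12)
})

test_that("suppressing the second of two identical blobs hits its location harder", {
  scene <- generate_scene(scene_config(
    n_frames = 1L, frame_size = c(96L, 96L),
    target = list(shape = "disc", width = 14, height = 14),
    motion = list(type = "linear", start = c(30, 48), velocity = c(0, 0)),
    distractors = list(list(start = c(66, 48))),
    seed = 43L))
  fr <- scene$frames[[1]]
  patch <- siamtrack:::crop_patch(fr, 48, 48, 80, 160L)
  sf <- extract_features(patch$patch, stride = 2L, affine = patch$affine)
  # grab template-shaped crops at the search grid's own cell pitch so the
  # kernel and search features live on the same scale
  cell <- sf$stride
  grab <- function(ctr) {
    f <- roi_align(sf, bbox(ctr[1] - 14, ctr[2] - 14, 28, 28),
                   as.integer(round(28 / cell)), as.integer(round(28 / cell)))
    f$grid <- f$grid / sqrt(sum(f$grid^2))
    f
  }
  tmpl <- grab(c(30, 48))
  dis <- grab(c(66, 48))
  resp <- cross_correlate(tmpl, sf)
  sup <- suppress_distractors(resp, sf, list(dis), alpha = 0.5)
  at <- function(m, xy) {
    cell <- siamtrack:::response_nearest_cell(resp, xy)
    m[cell[1], cell[2]]
  }
  drop_target <- at(resp$scores, c(30, 48)) - at(sup$scores, c(30, 48))
  drop_distr <- at(resp$scores, c(66, 48)) - at(sup$scores, c(66, 48))
  expect_gt(drop_distr, 0)
  expect_gt(drop_distr, drop_target)
})

test_that("suppression rejects mis-shaped distractors", {
  tmpl <- mk_fmap(array(1, dim = c(4, 4, 2)))
  sf <- mk_fmap(array(1, dim = c(9, 9, 2)))
  resp <- cross_correlate(tmpl, sf)
  bad <- mk_fmap(array(1, dim = c(3, 3, 2)))
  expect_error(suppress_distractors(resp, sf, list(bad), 0.5), "shape")
})

test_that("locate_peak finds strict maxima and honors the tie-break rule", {
  s <- matrix(0, 5, 6)
  s[3, 4] <- 1
  expect_equal(locate_peak(mk_resp(s), c(0, 0), 0)$cell, c(3L, 4L))
  s2 <- matrix(0, 5, 6)
  s2[2, 5] <- 1; s2[4, 1] <- 1
  expect_equal(locate_peak(mk_resp(s2), c(0, 0), 0)$cell, c(2L, 5L))
  # all-equal degenerate map returns the center cell
  expect_equal(locate_peak(mk_resp(matrix(2, 5, 6)), c(0, 0), 0)$cell, c(3L, 3L))
})

test_that("a strong motion prior prefers a nearby slightly-smaller peak", {
  s <- matrix(0, 9, 9)
  s[5, 5] <- 0.95   # at the previous center
  s[1, 9] <- 1.00   # global max, far away
  resp <- mk_resp(s, stride = 1, origin = c(0, 0))
  prev <- siamtrack:::response_cell_coord(resp, 5, 5)
  far <- locate_peak(resp, prev, window_weight = 0)
  near <- locate_peak(resp, prev, window_weight = 0.8)
  expect_equal(far$cell, c(1L, 9L))
  expect_equal(near$cell, c(5L, 5L))
})

test_that("confidence matches its closed forms and the softmax oracle", {
  expect_equal(compute_confidence(mk_resp(matrix(2, 5, 5)), 0.1), 9 / 25)
  expect_equal(compute_confidence(mk_resp(matrix(0, 2, 2)), 0.1), 1)
  # one dominant cell -> confidence ~ 1
  s <- matrix(0, 9, 9); s[4, 6] <- 5
  expect_gt(compute_confidence(mk_resp(s), 0.01), 0.999)
  set.seed(44)
  for (k in 1:25) {
    s <- matrix(runif(17 * 17), 17, 17)
    expect_equal(compute_confidence(mk_resp(s), 0.1),
                 oracle_confidence(s, 0.1), tolerance = 1e-9)
    cc <- compute_confidence(mk_resp(s), 0.1)
    expect_gt(cc, 0)
    expect_lte(cc, 1)
  }
  expect_error(compute_confidence(mk_resp(matrix(1, 3, 3)), 0), "temperature")
})

test_that("select_box_candidate honors damping, ties and the empty-set error", {
  s <- matrix(0, 7, 7); s[4, 4] <- 1
  mk_cand <- function(r, sc) list(resp = mk_resp(s, origin = c(10, 10)),
                                  ratio = r, scale = sc)
  prev <- bbox(8, 8, 6, 6)
  expect_error(select_box_candidate(list(), prev, 0.3), "empty candidate")
  # identical responses: candidate order (identity first) breaks the tie
  sel <- select_box_candidate(list(mk_cand(1, 1), mk_cand(2, 1), mk_cand(1/2, 1)),
                              prev, size_damping = 1)
  expect_equal(sel$candidate, 1L)
  expect_equal(c(sel$box$w, sel$box$h), c(6, 6))
  # size_damping 0 is not allowed by config, but the op accepts it: size frozen
  sel2 <- select_box_candidate(list(mk_cand(2, 1.1)), prev, size_damping = 0)
  expect_equal(c(sel2$box$w, sel2$box$h), c(6, 6))
  # full damping adopts the winning candidate size
  sel3 <- select_box_candidate(list(mk_cand(2, 1)), prev, size_damping = 1)
  expect_equal(sel3$box$w / sel3$box$h, 2 * (6 / 6) * 1, tolerance = 1e-9)
})

test_that("a stationary target keeps the identity candidate and its box", {
  scene <- static_blob_scene(n_frames = 2L)
  cfg <- small_cfg()
  st <- track_init(scene$frames[[1]], scene$truth[["0"]], cfg)
  res <- track_step(st, scene$frames[[2]], cfg)
  prev_ctr <- bbox_center(scene$truth[["0"]])
  new_ctr <- bbox_center(trajectory_box(res$record, 1L))
  expect_lt(sqrt(sum((new_ctr - prev_ctr)^2)), 1)
  expect_gt(res$record$confidence, 0.5)
  expect_equal(res$record$w, scene$truth[["0"]]$w, tolerance = 0.1 * 14)
})

test_that("an uncorrelated noise frame yields low confidence", {
  scene <- static_blob_scene(n_frames = 2L)
  cfg <- small_cfg()
  st <- track_init(scene$frames[[1]], scene$truth[["0"]], cfg)
  res <- track_step(st, noise_frame(1L), cfg)
  expect_lt(res$record$confidence, 0.5)
})

test_that("track_sequence on one frame is exactly the initial record", {
  scene <- static_blob_scene(n_frames = 1L)
  traj <- track_sequence(scene$frames, scene$truth[["0"]], small_cfg())
  expect_equal(nrow(traj), 1L)
  expect_identical(traj$source, "corrected")
  expect_equal(traj$confidence, 1.0)
  expect_equal(trajectory_box(traj, 1L)$x, scene$truth[["0"]]$x)
})

test_that("a correction event at frame 0 is ignored with a warning", {
  scene <- static_blob_scene(n_frames = 2L)
  ev <- list(correction_event(0L, bbox(1, 1, 5, 5)))
  expect_warning(
    traj <- track_sequence(scene$frames, scene$truth[["0"]], small_cfg(),
                           corrections = ev),
    "initial box takes precedence")
  expect_equal(trajectory_box(traj, 1L)$x, scene$truth[["0"]]$x)
})

test_that("tracker configuration validation catches bad values", {
  expect_error(tracker_config(template_size = 300), "template_size")
  expect_error(tracker_config(anchor_ratios = c(1, 2)), "5 anchor_ratios")
  expect_error(tracker_config(window_weight = 1), "window_weight")
  expect_error(tracker_config(confidence_temperature = 0), "temperature")
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- fixture_tracker_config("small", distractor_alpha = 0.25)
  write_tracker_config(cfg, path)
  back <- read_tracker_config(path)
  expect_equal(unclass(back), unclass(cfg))
})
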