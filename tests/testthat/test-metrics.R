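# Evaluation criteria: overlap rate, pixel error, report bookkeeping.

test_that("overlap rate closed-form cases", {
  a <- bbox(0, 0, 4, 4)
  expect_equal(overlap_rate(a, a), 1)
  expect_equal(overlap_rate(a, bbox(10, 10, 4, 4)), 0)
  expect_equal(overlap_rate(a, bbox(2, 0, 4, 4)), 1 / 3)
  # boxes sharing only an edge do not intersect (half-open semantics)
  expect_equal(overlap_rate(a, bbox(4, 0, 4, 4)), 0)
})

test_that("overlap rate equals the rasterized pixel-count oracle on integer boxes", {
  set.seed(51)
  for (k in 1:100) {
    a <- bbox(sample(0:20, 1), sample(0:20, 1), sample(1:20, 1), sample(1:20, 1))
    b <- bbox(sample(0:20, 1), sample(0:20, 1), sample(1:20, 1), sample(1:20, 1))
    expect_equal(overlap_rate(a, b), oracle_iou_raster(a, b), tolerance = 1e-9)
    # symmetry and joint-translation invariance
    expect_equal(overlap_rate(a, b), overlap_rate(b, a))
    sh <- bbox(a$x + 3.7, a$y - 2.2, a$w, a$h)
    sh2 <- bbox(b$x + 3.7, b$y - 2.2, b$w, b$h)
    expect_equal(overlap_rate(sh, sh2), overlap_rate(a, b), tolerance = 1e-12)
  }
})

test_that("pixel error is the center distance", {
  expect_equal(pixel_error(c(0, 0), c(0, 0)), 0)
  expect_equal(pixel_error(c(0, 0), c(3, 4)), 5)
  expect_equal(pixel_error(bbox(0, 0, 2, 2), bbox(3, 4, 2, 2)), 5)
  set.seed(52)
  for (k in 1:50) {
    p <- runif(2, -50, 50); q <- runif(2, -50, 50)
    expect_equal(pixel_error(p, q), sqrt(sum((p - q)^2)), tolerance = 1e-12)
  }
  expect_error(pixel_error(c(NA, 0), c(0, 0)), "non-finite")
})

mk_traj <- function(boxes, frames = seq_along(boxes) - 1L) {
  rows <- Map(function(b, f, s) data.frame(frame = f, x = b$x, y = b$y,
                                           w = b$w, h = b$h, confidence = 0.9,
                                           source = s),
              boxes, frames, c("corrected", rep("auto", length(boxes) - 1L)))
  trajectory(do.call(rbind, rows))
}

test_that("success, error and accuracy follow the threshold rules", {
  truth <- list("0" = bbox(0, 0, 10, 10), "1" = bbox(0, 0, 10, 10),
                "2" = bbox(0, 0, 10, 10))
  # OR series engineered: 1.0, ~0.33, 0.0 at threshold 0.5
  traj <- mk_traj(list(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10), bbox(40, 40, 10, 10)))
  rep <- evaluate(traj, truth)
  expect_equal(rep$success_rate, 1 / 3)
  expect_equal(rep$error_rate, 2 / 3)
  expect_equal(rep$success_rate + rep$error_rate, 1)
  # identity trajectory
  rep2 <- evaluate(mk_traj(truth), truth)
  expect_equal(rep2$success_rate, 1)
  expect_equal(rep2$accuracy, 1)
  expect_equal(rep2$error_rate, 0)
})

test_that("OR boundary is inclusive; PE boundary is strict", {
  # 2x3 boxes offset by 1 along y: intersection 4, union 8, IoU exactly 0.5
  # in floating point (all quantities are small integers)
  truth <- list("0" = bbox(0, 0, 2, 3))
  traj <- mk_traj(list(bbox(0, 1, 2, 3)))
  rep <- evaluate(traj, truth)
  expect_identical(rep$or_series[1], 0.5)
  expect_equal(rep$success_rate, 1)  # inclusive at the OR threshold
  # PE exactly at the threshold counts as NOT successful
  truth2 <- list("0" = bbox(0, 0, 10, 10))
  traj2 <- mk_traj(list(bbox(20, 0, 10, 10)))  # center distance exactly 20
  rep2 <- evaluate(traj2, truth2)
  expect_equal(rep2$pe_series[1], 20)
  expect_equal(rep2$accuracy, 0)
})

test_that("success is non-increasing in the OR threshold, accuracy non-decreasing in PE", {
  set.seed(53)
  truth <- lapply(1:20, function(i) bbox(runif(1, 0, 30), runif(1, 0, 30), 10, 10))
  names(truth) <- as.character(0:19)
  boxes <- lapply(truth, function(b) bbox(b$x + runif(1, 0, 8), b$y, 10, 10))
  traj <- mk_traj(unname(boxes))
  s <- vapply(c(0.2, 0.4, 0.6, 0.8),
              function(t) evaluate(traj, truth, or_threshold = t)$success_rate, 0)
  expect_true(all(diff(s) <= 0))
  a <- vapply(c(2, 5, 10, 20),
              function(t) evaluate(traj, truth, pe_threshold = t)$accuracy, 0)
  expect_true(all(diff(a) >= 0))
})

test_that("frames missing from the truth are excluded and counted", {
  truth <- list("0" = bbox(0, 0, 10, 10), "2" = bbox(0, 0, 10, 10))
  traj <- mk_traj(list(bbox(0, 0, 10, 10), bbox(0, 0, 10, 10), bbox(0, 0, 10, 10)))
  rep <- evaluate(traj, truth)
  expect_equal(rep$n_frames, 2L)
  expect_equal(rep$n_excluded, 1L)
  expect_error(evaluate(traj, list("99" = bbox(0, 0, 1, 1))), "no trajectory frame")
})

test_that("box-size sensitivity sweeps ground-truth inflation factors", {
  truth <- list("0" = bbox(10, 10, 10, 10))
  traj <- mk_traj(list(bbox(10, 10, 10, 10)))
  sens <- box_size_sensitivity(traj, truth, factors = c(0.5, 1, 2))
  expect_equal(sens$success_rate[sens$factor == 1], 1)
  # halving or doubling the truth size gives IoU 0.25 -> failure
  expect_equal(sens$success_rate[sens$factor == 2], 0)
})

test_that("label effort arithmetic", {
  ev <- function(idx) lapply(idx, correction_event, box = bbox(0, 0, 5, 5))
  expect_equal(label_effort(correction_log(ev(c(10L, 20L, 30L)), 300L)), 1.0)
  expect_equal(label_effort(correction_log(list(), 100L)), 0.0)
  expect_equal(label_effort(correction_log(ev(c(1L, 5L, 9L, 11L, 40L)), 137L)),
               100 * 5 / 137)
  expect_error(correction_log(list(), 0L), "total_frames")
})
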