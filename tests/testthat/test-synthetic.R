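test_that("zero-corruption scenes reproduce ground truth exactly", {
  sc <- scene_config(n_pigs = 5, duration_s = 10, det_noise_px = 0,
                     fp_rate = 0, miss_rate = 0, occlusion_rate = 0, seed = 1)
  scene <- generate_scene(sc)
  det <- scene$detections[order(scene$detections$frame, scene$detections$left), ]
  gt <- scene$gt[order(scene$gt$frame, scene$gt$left), ]
  expect_equal(nrow(det), nrow(gt))
  for (col in c("frame", "left", "top", "width", "height", "class")) {
    expect_equal(unname(det[[col]]), unname(gt[[col]]), info = col)
  }
  inj <- attr(scene$detections, "injected")
  expect_equal(inj$n_missed + inj$n_fp, 0L)
})

test_that("scene bookkeeping: ids, row counts, seed determinism", {
  sc <- scene_config(n_pigs = 8, duration_s = 60, seed = 13)
  scene <- generate_scene(sc)
  expect_setequal(unique(scene$gt$id), 1:8)
  expect_equal(nrow(scene$gt), 8 * 300)
  expect_true(all(scene$gt$width > 0 & scene$gt$height > 0))
  # pigs stay inside the pen
  expect_true(all(scene$gt$left >= -1 &
                  scene$gt$left + scene$gt$width <= sc$pen_width + 1))

  scene2 <- generate_scene(sc)
  expect_identical(scene$gt, scene2$gt)
  expect_identical(scene$detections, scene2$detections)

  expect_error(scene_config(n_pigs = 200, pen_width = 400, pen_height = 300),
               "cannot fit")
})

test_that("false-positive injection concentrates around its rate", {
  sc <- scene_config(n_pigs = 1, duration_s = 200, fps = 5, fp_rate = 0.5,
                     miss_rate = 0, occlusion_rate = 0, det_noise_px = 0,
                     seed = 99)
  scene <- generate_scene(sc)  # 1000 frames
  n_fp <- attr(scene$detections, "injected")$n_fp
  expect_lt(abs(n_fp - 500), 3 * sqrt(500))
})

test_that("behaviour occupancy follows the stationary distribution", {
  # fast-mixing chain so a chi-square on thinned frames is well calibrated
  pi <- c(0.4, 0.3, 0.2, 0.1)
  sc <- scene_config(n_pigs = 1, duration_s = 2000, fps = 5,
                     behavior_transition = behavior_markov(pi, leave = 0.5),
                     det_noise_px = 0, fp_rate = 0, miss_rate = 0,
                     occlusion_rate = 0, seed = 7)
  scene <- generate_scene(sc)  # 10,000 frames
  thin <- scene$gt$behavior[seq(1, nrow(scene$gt), by = 10)]
  obs <- table(factor(thin, levels = behavior_levels()))
  p <- stats::chisq.test(obs, p = pi)$p.value
  expect_gt(p, 0.01)
})

test_that("deterministic surgery drops and injects exactly what was asked", {
  gt <- make_two_track_gt(20)
  det <- inject_errors(gt, drop = data.frame(id = 1L, frame = 10:14))
  inj <- attr(det, "injected")
  expect_equal(inj$n_missed, 5L)
  frames_id1 <- sort(gt$frame[gt$left == 100])
  got <- sort(det$frame[det$left == 100])
  expect_equal(setdiff(frames_id1, got), 10:14)

  det2 <- inject_errors(gt, add_fp = data.frame(frame = c(1, 1, 2),
                                                left = 900, top = 600,
                                                width = 50, height = 40))
  expect_equal(attr(det2, "injected")$n_fp, 3L)
  expect_equal(nrow(det2), nrow(gt) + 3L)

  # zero corruption is the identity (up to detection bookkeeping columns)
  det3 <- inject_errors(gt)
  expect_equal(det3[c("frame", "left", "top", "width", "height", "class")],
               gt[order(gt$frame), c("frame", "left", "top", "width",
                                     "height", "class")],
               ignore_attr = TRUE)
})

test_that("generated streams round-trip through the io module", {
  sc <- scene_config(n_pigs = 3, duration_s = 5, seed = 3)
  scene <- generate_scene(sc)
  gt_path <- withr::local_tempfile()
  det_path <- withr::local_tempfile()
  write_tracks(scene$gt, gt_path)
  back <- read_tracks(gt_path)
  expect_equal(back[c("frame", "id", "class")],
               scene$gt[c("frame", "id", "class")], ignore_attr = TRUE)
  expect_equal(back$left, scene$gt$left, tolerance = 1e-12)

  write_detections(scene$detections, det_path)
  det_back <- read_detections(det_path)
  expect_equal(nrow(det_back), nrow(scene$detections))
  expect_equal(det_back$conf, scene$detections$conf, tolerance = 1e-12)
})

test_that("regime presets move the knobs in the right direction", {
  day <- scene_regime("day", "sparse", "M", seed = 1)
  night <- scene_regime("night", "dense", "H", seed = 1)
  expect_lt(day$det_noise_px, night$det_noise_px)
  expect_lt(day$occlusion_rate, night$occlusion_rate)
  expect_lt(day$speed_by_behavior[["other"]],
            night$speed_by_behavior[["other"]])
  expect_equal(rowSums(night$behavior_transition), rep(1, 4))
})
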