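test_that("background estimation recovers the static scene", {
  cfg <- desk_render_cfg()
  # moving fish across frames
  tr <- static_trace(n = 30)
  tr$x <- seq(-3, 3, length.out = 30); tr$z <- seq(-2, 2, length.out = 30)
  fs <- render_frames(tr, cfg, seed = 2)
  bg <- estimate_background(fs$frames, mode = "median")
  expect_lt(max(abs(bg - fs$background)), cfg$noise_sd)
  # constant frames: background equals the frame, either mode
  const <- list(fs$frames[[1]], fs$frames[[1]], fs$frames[[1]])
  expect_equal(estimate_background(const, "median"), fs$frames[[1]],
               ignore_attr = TRUE)
  expect_equal(estimate_background(const, "first_n_mean"), fs$frames[[1]],
               ignore_attr = TRUE)
  expect_equal(estimate_background(fs$frames[1], "median"), fs$frames[[1]],
               ignore_attr = TRUE)
  expect_error(estimate_background(list()), "no frames")
})

test_that("rendering is deterministic and respects animal count", {
  cfg <- desk_render_cfg()
  tr <- static_trace(n = 2, pitch = 15)
  a <- render_frames(tr, cfg, seed = 5)
  b <- render_frames(tr, cfg, seed = 5)
  expect_identical(a$frames, b$frames)
  cfg0 <- desk_render_cfg(); cfg0$n_animals <- 0L
  empty <- render_frames(tr, cfg0, seed = 5)
  expect_identical(empty$frames[[1]], empty$background)
  # pitched fish: head centroid sits above the body centroid
  gt <- a$ground_truth
  dz <- -(gt$head_row[1] - gt$body_row[1])
  dx <- gt$head_col[1] - gt$body_col[1]
  expect_equal(atan2(dz, abs(dx)) * 180 / pi, 15, tolerance = 2)
  expect_error(render_config(background_level = 100, body_intensity = 101,
                             head_intensity = 120, noise_sd = 2),
               "head_intensity")
})

test_that("single-frame detection recovers pose and rejects bad frames", {
  cfg <- desk_render_cfg()
  thr <- desk_thresholds()
  tr <- static_trace(n = 1, pitch = 15)
  fs <- render_frames(tr, cfg, seed = 3)
  det <- detect_frame(fs$frames[[1]], fs$background, thr)
  expect_equal(det$status, "ok")
  expect_equal(det$pitch, 15, tolerance = 2)
  gt <- fs$ground_truth
  expect_lt(abs(det$body_centroid[1] - gt$body_col[1]), 1)
  expect_lt(abs(det$body_centroid[2] - gt$body_row[1]), 1)
  # blank frame
  expect_equal(detect_frame(fs$background, fs$background, thr)$status,
               "no_animal")
  # two fish in view
  cfg2 <- desk_render_cfg(); cfg2$n_animals <- 2L
  fs2 <- render_frames(static_trace(n = 1, x = -3), cfg2, seed = 3)
  expect_equal(detect_frame(fs2$frames[[1]], fs2$background, thr)$status,
               "multiple_animals")
  # size bounds
  thr_small <- desk_thresholds(); thr_small$size_high <- 50
  thr_small$size_low <- 10
  expect_equal(detect_frame(fs$frames[[1]], fs$background, thr_small)$status,
               "size_out_of_range")
  expect_error(detect_frame(fs$frames[[1]], fs$background[1:10, 1:10], thr),
               "shape")
})

test_that("published threshold presets are available verbatim", {
  z <- tracker_preset("zebrafish")
  expect_equal(z$body_low, 14); expect_equal(z$head_low, 45)
  expect_equal(z$initial_cut_low, 25); expect_equal(z$initial_cut_high, 120)
  expect_equal(z$size_low, 180); expect_equal(z$size_high, 260)
  expect_equal(tracker_preset("zebrafish_old")$size_high, 450)
  fly <- tracker_preset("fly")
  expect_equal(fly$body_low, 100); expect_equal(fly$size_high, 180)
  worm <- tracker_preset("worm")
  expect_equal(worm$initial_cut_low, 3); expect_equal(worm$size_low, 30)
})

test_that("tracking a rendered session recovers the trace", {
  cfg <- desk_render_cfg()
  fps <- 166
  n <- 60
  # a gentle bout: pitch ramps 0 -> 12 deg while the fish translates
  tr <- structure(list(times = (seq_len(n) - 1) / fps,
                       x = seq(0, 2, length.out = n),
                       z = seq(0, 0.8, length.out = n),
                       pitch = seq(0, 12, length.out = n),
                       epoch_id = rep(1L, n), frame_rate = fps,
                       ground_truth = data.frame()),
                  class = "pose_trace")
  fs <- render_frames(tr, cfg, seed = 7)
  rec <- track_frames(fs$frames, desk_thresholds(),
                      mm_per_pixel = cfg$mm_per_pixel, frame_rate = fps,
                      background = fs$background)
  expect_equal(nrow(rec), n)
  expect_equal(unique(rec$epoch_id), 1L)
  rms <- sqrt(mean((rec$pitch - tr$pitch)^2))
  expect_lt(rms, 1)
  gt <- fs$ground_truth
  err_px <- sqrt((rec$body_x / cfg$mm_per_pixel - gt$body_col)^2 +
                 ((nrow(fs$frames[[1]]) - rec$body_z / cfg$mm_per_pixel) -
                    gt$body_row)^2)
  expect_lt(max(err_px), 0.5)
  # head above body implies positive pitch, always
  expect_true(all(rec$pitch[rec$head_z > rec$body_z] > 0))
})

test_that("detection gaps split epochs and empty stacks warn", {
  cfg <- desk_render_cfg()
  tr <- static_trace(n = 9)
  fs <- render_frames(tr, cfg, seed = 9)
  frames <- fs$frames
  frames[[4]] <- fs$background; frames[[5]] <- fs$background
  rec <- track_frames(frames, desk_thresholds(), cfg$mm_per_pixel,
                      background = fs$background)
  expect_equal(unique(rec$epoch_id), c(1L, 2L))
  expect_equal(sum(rec$epoch_id == 1L), 3)
  blank <- list(fs$background, fs$background)
  expect_warning(out <- track_frames(blank, desk_thresholds(),
                                     cfg$mm_per_pixel,
                                     background = fs$background), "no frame")
  expect_equal(nrow(out), 0)
})
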