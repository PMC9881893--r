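cfg_nosmooth <- extraction_config(speed_smoothing = 1)

test_that("speed is displacement over the frame interval, per epoch", {
  fps <- 166
  t <- seq(0, 1, by = 1 / fps)
  n <- length(t)
  # stationary fish
  rec <- raw_records(t, body_x = 0 * t, body_z = 0 * t, head_x = 2, head_z = 0,
                     pitch = 0, epoch_id = rep(1L, n), length = rep(4, n))
  expect_equal(compute_speed(rec, cfg_nosmooth)$speed, rep(0, n))
  # 0.03 mm per frame at 166 Hz is 4.98 mm/s: sub-threshold
  rec2 <- raw_records(t, body_x = 0.03 * seq_len(n), body_z = 0 * t,
                      head_x = 2, head_z = 0, pitch = 0,
                      epoch_id = rep(1L, n), length = rep(4, n))
  sp <- compute_speed(rec2, cfg_nosmooth)$speed
  expect_equal(unique(round(sp, 10)), 4.98)
  expect_lt(max(sp), 5)
})

test_that("speed never bridges epoch boundaries; single-frame epochs drop", {
  t <- c(0, 0.006, 0.012, 1, 1.006, 1.012)
  rec <- raw_records(t, body_x = c(0, 0, 0, 5, 5, 5), body_z = 0,
                     head_x = 2, head_z = 0, pitch = 0,
                     epoch_id = c(1L, 1L, 1L, 2L, 2L, 2L), length = 4)
  sp <- compute_speed(rec, cfg_nosmooth)$speed
  expect_equal(sp, rep(0, 6))   # the 5 mm jump between epochs is not a speed
  rec1 <- raw_records(c(0, 1, 1.006), body_x = c(0, 1, 1), body_z = 0,
                      head_x = 2, head_z = 0, pitch = 0,
                      epoch_id = c(1L, 2L, 2L), length = 4)
  expect_warning(out <- compute_speed(rec1, cfg_nosmooth), "single-frame")
  expect_equal(unique(out$epoch_id), 2L)
})

test_that("epoch selection enforces duration, swim and QC rules", {
  short_sw <- bump_records(duration = 2.0, center = 1.0, epoch_id = 1L)
  long_slow <- bump_records(duration = 3, center = 1.5, peak_speed = 4,
                            epoch_id = 2L, t0 = 10)
  good <- bump_records(duration = 3, center = 1.5, epoch_id = 3L, t0 = 20)
  teleport <- bump_records(duration = 3, center = 1.5, epoch_id = 4L, t0 = 30)
  teleport$body_x[200] <- teleport$body_x[200] + 30   # 30 mm jump artifact
  rec <- raw_records()
  for (s in list(short_sw, long_slow, good, teleport)) rec <- rbind(rec, s)
  rec <- raw_records(rec$time, rec$body_x, rec$body_z, rec$head_x, rec$head_z,
                     rec$pitch, rec$epoch_id, rec$length)
  sel <- select_epochs(compute_speed(rec, cfg_nosmooth), cfg_nosmooth)
  expect_equal(unique(sel$epoch_id), 3L)
  excl <- attr(sel, "excluded")
  expect_setequal(excl$reason[match(c(1, 2, 4), excl$epoch_id)],
                  c("too_short", "no_swim", "jump"))
})

test_that("aligned windows span -500/+300 ms with the maximum at t = 0", {
  rec <- bump_records(duration = 3, center = 1.5, peak_speed = 15)
  eps <- select_epochs(compute_speed(rec, cfg_nosmooth), cfg_nosmooth)
  b <- extract_bouts(eps, cfg_nosmooth)
  expect_equal(nrow(b$bouts), 1)
  s <- b$samples
  n_expected <- round(0.5 * 166) + round(0.3 * 166) + 1
  expect_equal(nrow(s), n_expected)
  expect_equal(min(s$t_ms), -round(0.5 * 166) / 166 * 1000)
  expect_equal(max(s$t_ms), round(0.3 * 166) / 166 * 1000)
  expect_equal(s$speed[s$t_ms == 0], max(s$speed))
  # a bout whose pre-window sticks out of the epoch is dropped
  early <- bump_records(duration = 3, center = 0.2)
  b2 <- extract_bouts(select_epochs(compute_speed(early, cfg_nosmooth),
                                    cfg_nosmooth), cfg_nosmooth)
  expect_equal(nrow(b2$bouts), 0)
})

test_that("IBI durations lose a 100 ms buffer at each end", {
  fps <- 166
  # two bumps; sub-threshold gap between super-threshold spans close to 1 s
  rec <- bump_records(duration = 4, center = 1.4, width = 0.2)
  rec2 <- bump_records(duration = 4, center = 1.4 + 0.15 + 1.0 + 0.15 - 0.1,
                       width = 0.2)
  # construct directly: speeds via two bumps in one epoch
  t <- seq(0, 4, by = 1 / fps)
  bump <- function(center, width = 0.2, pk = 15)
    ifelse(abs(t - center) <= width / 2,
           pk * 0.5 * (1 + cos(2 * pi * (t - center) / width)), 0)
  v <- bump(1.0) + bump(2.2)
  x <- cumsum(v) / fps
  rec <- raw_records(t, x, 0 * t, x + 2, 0 * t, rep(12, length(t)),
                     rep(1L, length(t)), rep(4, length(t)))
  eps <- select_epochs(compute_speed(rec, cfg_nosmooth), cfg_nosmooth)
  ibis <- extract_ibis(eps, cfg_nosmooth)
  expect_equal(nrow(ibis), 1)
  gap <- ibis$duration + 0.2    # raw sub-threshold time
  expect_equal(ibis$bout_frequency * ibis$duration, 1)
  expect_equal(ibis$mean_pitch, 12)
  # the raw gap equals peak separation minus the super-threshold half-spans
  expect_equal(gap, 1.2 - 2 * (0.2 / (2 * pi)) * acos(2 * 5 / 15 - 1),
               tolerance = 0.02)
  # a short gap is discarded once buffers make it non-positive
  v2 <- bump(1.0) + bump(1.3)
  x2 <- cumsum(v2) / fps
  rec2 <- raw_records(t, x2, 0 * t, x2 + 2, 0 * t, rep(0, length(t)),
                      rep(1L, length(t)), rep(4, length(t)))
  eps2 <- select_epochs(compute_speed(rec2, cfg_nosmooth), cfg_nosmooth)
  expect_equal(nrow(extract_ibis(eps2, cfg_nosmooth)), 0)
})

test_that("lowering the speed threshold never removes candidate spans", {
  tr <- simulate_session(make_profile("7dpf"), 120, seed = 8)
  rec <- trace_to_records(tr)
  n_spans <- function(thr) {
    cfg <- extraction_config(speed_threshold = thr, speed_smoothing = 1)
    sp <- compute_speed(rec, cfg)
    sum(vapply(split(sp$speed, sp$epoch_id),
               function(v) { r <- rle(v > thr); sum(r$values) }, 0L))
  }
  expect_gte(n_spans(3), n_spans(5))
  expect_gte(n_spans(5), n_spans(8))
})

test_that("daytime filtering keeps the 14 h light phase", {
  meta <- session_metadata(light_on = "09:00", light_off = "23:00",
                           session_start = "2026-01-01 09:00:00")
  t <- seq(0, 24 * 3600 - 1, by = 60)
  rec <- raw_records(t, 0 * t, 0 * t, 2 + 0 * t, 0 * t, 0 * t,
                     rep(1L, length(t)), rep(4, length(t)))
  day <- filter_daytime(rec, meta)
  expect_equal(nrow(day) / length(t), 14 / 24, tolerance = 0.001)
  # all-night data yields an empty subset
  night <- raw_records(3600 * 15, 0, 0, 2, 0, 0, 1L, 4)
  expect_equal(nrow(filter_daytime(night, meta)), 0)
  # absent schedule: unchanged with a warning
  meta2 <- session_metadata()
  meta2$light_on <- ""
  expect_warning(out <- filter_daytime(rec, meta2), "schedule")
  expect_equal(nrow(out), nrow(rec))
})
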