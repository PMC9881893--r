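# One synthetic repeat: targeted draws re-expressed as feature/IBI tables.
fake_repeat <- function(rid, seed, n = 400, profile = make_profile("7dpf")) {
  pr <- relationship_params(profile, "righting")
  st <- relationship_params(profile, "steering")
  fb <- relationship_params(profile, "finbody")
  tm <- relationship_params(profile, "timing")
  r <- generate_relationship_samples("righting", pr, n, seed)
  s <- generate_relationship_samples("steering", st, n, seed + 1)
  f <- generate_relationship_samples("finbody", fb, n, seed + 2)
  t <- generate_relationship_samples("timing", tm, n, seed + 3)
  features <- data.frame(
    initial_pitch = r$x, righting_rotation = r$y,
    trajectory = s$x, pitch_at_peak = s$y,
    steering_related_rotation = f$x, steering_rotation = f$x,
    attack_angle = f$y, peak_speed = rep(12, n), repeat_id = rid)
  ibis <- data.frame(mean_pitch = t$x, bout_frequency = t$y,
                     duration = 1 / pmax(t$y, 0.05), repeat_id = rid)
  list(features = features, ibis = ibis)
}

test_that("per-repeat analysis reports mean (SD) across repeats", {
  reps <- lapply(1:3, function(i) fake_repeat(paste0("r", i), seed = 100 + i))
  features <- do.call(rbind, lapply(reps, `[[`, "features"))
  ibis <- do.call(rbind, lapply(reps, `[[`, "ibis"))
  rep_report <- analyze_repeats(features, ibis)
  expect_equal(nrow(rep_report$per_repeat), 3)
  sg <- rep_report$summary
  expect_equal(sg$mean[sg$parameter == "steering_gain"],
               mean(rep_report$per_repeat$steering_gain), tolerance = 1e-12)
  expect_equal(sg$n_repeats, rep(3, nrow(sg)))
  # pooled fits close to the generating values
  expect_equal(rep_report$pooled$steering$slope, 0.67, tolerance = 0.05)
  expect_equal(rep_report$pooled$righting$righting_gain, 0.18,
               tolerance = 0.05)
})

test_that("a single repeat yields its own values with zero SD", {
  one <- fake_repeat("solo", seed = 200)
  rep_report <- analyze_repeats(one$features, one$ibis)
  expect_equal(nrow(rep_report$per_repeat), 1)
  expect_true(all(rep_report$summary$sd == 0))
  expect_equal(rep_report$summary$mean[
    rep_report$summary$parameter == "righting_gain"],
    rep_report$per_repeat$righting_gain)
})

test_that("repeats with too few bouts are skipped with a warning", {
  big <- fake_repeat("big", seed = 300)
  tiny <- fake_repeat("tiny", seed = 301, n = 4)
  features <- rbind(big$features, tiny$features)
  ibis <- rbind(big$ibis, tiny$ibis)
  expect_warning(rep_report <- analyze_repeats(features, ibis), "tiny")
  expect_equal(rep_report$per_repeat$repeat_id, "big")
})

test_that("percent differences reproduce the reference-table contrasts", {
  ref7 <- c(ibi_pitch_sd = 12.66, sensitivity = 1.06)
  v4 <- c(ibi_pitch_sd = 17.48, sensitivity = 0.61)
  v14 <- c(ibi_pitch_sd = 11.23, sensitivity = 1.31)
  c4 <- compare_profiles(ref7, v4)
  c14 <- compare_profiles(ref7, v14)
  expect_equal(round(c4$percent[c4$parameter == "ibi_pitch_sd"], 1), 38.1)
  expect_equal(round(c14$percent[c14$parameter == "ibi_pitch_sd"], 1), -11.3)
  expect_equal(round(c4$percent[c4$parameter == "sensitivity"], 1), -42.5)
  expect_equal(round(c14$percent[c14$parameter == "sensitivity"], 1), 23.6)
  # identical inputs: zero percent everywhere
  expect_true(all(compare_profiles(ref7, ref7)$percent == 0))
  # zero reference is flagged
  expect_warning(out <- compare_profiles(c(a = 0), c(a = 1)), "undefined")
  expect_true(is.na(out$percent))
})
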