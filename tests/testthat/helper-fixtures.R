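# Shared fixtures, built in code at test time.

# A noise-free profile: every residual SD zero, lognormal IBI noise off.
noise_free_profile <- function(age = "7dpf", ...) {
  make_profile(age,
               ibi_pitch_sd = 0, ibi_lognoise_sigma = 0,
               peak_speed_sd = 0, timing_resid_sd = 0,
               steering_resid_sd = 0, finbody_resid_sd = 0,
               righting_resid_sd = 0, initial_pitch_jitter_sd = 0,
               residual_rotation_sd = 0, srr_sd = 0, ...)
}

# Hand-built record series: one epoch, stationary fish except a raised-cosine
# speed bump of peak `peak_speed` centered at `center` (s).
bump_records <- function(duration = 3, center = 1.5, peak_speed = 15,
                         width = 0.2, fps = 166, pitch = 5,
                         epoch_id = 1L, t0 = 0) {
  t <- seq(0, duration, by = 1 / fps)
  v <- ifelse(abs(t - center) <= width / 2,
              peak_speed * 0.5 * (1 + cos(2 * pi * (t - center) / width)), 0)
  x <- cumsum(v) / fps
  raw_records(time = t + t0, body_x = x, body_z = 0,
              head_x = x + 2, head_z = 0,
              pitch = rep(pitch, length(t)), epoch_id = rep(epoch_id, length(t)),
              length = rep(4, length(t)))
}

# Small render setup matched to a compact fish so tracker tests stay fast.
desk_render_cfg <- function(image_size = c(160, 160)) {
  render_config(image_size = image_size, mm_per_pixel = 0.1,
                background_level = 10, noise_sd = 2, body_length = 4,
                body_intensity = 40, head_intensity = 120)
}

# Thresholds matched to desk_render_cfg geometry (fish ~ 40 x 8 px).
desk_thresholds <- function() {
  tracker_thresholds(body_low = 30, body_high = 255,
                     head_low = 80, head_high = 255,
                     initial_cut_low = 15, initial_cut_high = 255,
                     size_low = 120, size_high = 600)
}

# Static pose "trace" for renderer/tracker tests.
static_trace <- function(n = 5, pitch = 0, x = 0, z = 0, fps = 166) {
  structure(list(times = (seq_len(n) - 1) / fps,
                 x = rep(x, n), z = rep(z, n),
                 pitch = rep(pitch, n),
                 epoch_id = rep(1L, n), frame_rate = fps,
                 ground_truth = data.frame()),
            class = "pose_trace")
}
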