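# Kinematic profiles: reference parameter sets for the synthetic swimmer.
#
# A profile bundles everything the generator needs to emulate a cohort of
# larval zebrafish at a given age: the bout-timing parabola (rate of movement
# initiation as a function of posture), the steering line, the fin-body
# sigmoid, the righting line, and the marginal distributions of peak speed,
# posture, and inter-bout interval noise.

.profile_tables <- function() {
  # Reference columns by age (days post-fertilization). Sensitivity is stored
  # in Hz/deg^2; it is conventionally reported in mHz/deg^2.
  list(
    "4dpf" = list(
      sensitivity_a = 0.00061, timing_vertex_b = 8.75, baseline_rate_c = 0.51,
      steering_gain = 0.64,
      sigmoid_h = 16.47, fin_body_ratio = 3.41, attack_mid = 4.10,
      righting_gain = 0.15, set_point = 13.00,
      peak_speed_mean = 10.42, peak_speed_sd = 3.85,
      pitch_at_peak_mean = 9.74, pitch_at_peak_sd = 29.16 / 1.349,
      ibi_pitch_mean = 8.75, ibi_pitch_sd = 17.48,
      trajectory_mean = 12.29, trajectory_sd = 27.52,
      srr_mean = 1.72, srr_sd = 6.15,
      steering_rotation_mean = 2.30,
      bout_displacement_mean = 1.12,
      angvel_peak_lead = 50.6
    ),
    "7dpf" = list(
      sensitivity_a = 0.00106, timing_vertex_b = 8.06, baseline_rate_c = 0.51,
      steering_gain = 0.67,
      sigmoid_h = 10.28, fin_body_ratio = 2.27, attack_mid = 0.77,
      righting_gain = 0.18, set_point = 19.47,
      peak_speed_mean = 13.02, peak_speed_sd = 4.99,
      pitch_at_peak_mean = 6.84, pitch_at_peak_sd = 20.35 / 1.349,
      ibi_pitch_mean = 8.06, ibi_pitch_sd = 12.66,
      trajectory_mean = 8.92, trajectory_sd = 20.19,
      srr_mean = 1.74, srr_sd = 5.95,
      steering_rotation_mean = 3.00,
      bout_displacement_mean = 1.36,
      angvel_peak_lead = 39.16
    ),
    "14dpf" = list(
      sensitivity_a = 0.00131, timing_vertex_b = 6.08, baseline_rate_c = 0.47,
      steering_gain = 0.51,
      sigmoid_h = 25.15, fin_body_ratio = 3.55, attack_mid = 0.91,
      righting_gain = 0.18, set_point = 13.60,
      peak_speed_mean = 11.41, peak_speed_sd = 4.20,
      pitch_at_peak_mean = 4.36, pitch_at_peak_sd = 19.73 / 1.349,
      ibi_pitch_mean = 6.08, ibi_pitch_sd = 11.23,
      trajectory_mean = 7.85, trajectory_sd = 22.89,
      srr_mean = 0.99, srr_sd = 5.42,
      steering_rotation_mean = 1.94,
      bout_displacement_mean = 1.35,
      angvel_peak_lead = 50.0
    )
  )
}

#' Build a kinematic profile
#'
#' Returns the full generator parameter set for a named age group, optionally
#' with individual fields overridden. The named presets carry the reference
#' values measured for AB-strain larvae at 4, 7 and 14 days post-fertilization
#' (dpf): the bout-timing parabola \eqn{\lambda(p) = a(p-b)^2 + c}, the
#' steering gain, the fin-body sigmoid (height `sigmoid_h`, steepness
#' `sigmoid_k`, so that the maximal slope is `k h / 4`), the righting gain and
#' set point, and the marginal distributions of peak speed, posture, and
#' inter-bout-interval (IBI) noise.
#'
#' The sigmoid's horizontal placement and lower asymptote are not part of the
#' reference tables; the preset centers the sigmoid at zero steering-related
#' rotation (`sigmoid_b = 0`) and chooses `sigmoid_a` so that the curve's
#' midpoint reproduces the age's central attack angle.
#'
#' Peak speed is modeled as a normal truncated below at the 5 mm/s detection
#' threshold whose parent parameters are solved so the *truncated*
#' distribution has exactly the quoted mean/SD (printed summary statistics
#' describe detected bouts, which are themselves conditioned on exceeding the
#' threshold).
#'
#' @param age one of `"4dpf"`, `"7dpf"`, `"14dpf"`.
#' @param ... named overrides for any profile field (e.g. `sensitivity_a = 0`
#'   for a flat bout-timing relationship, or `peak_speed_mean = 12.90`).
#' @return an object of class `kinematic_profile`: a named list of generator
#'   parameters. `sensitivity_a` is stored in Hz/deg^2 (reported elsewhere in
#'   mHz/deg^2); angles in degrees, speeds in mm/s, rates in Hz, times in the
#'   units stated per field (`angvel_peak_lead` in ms).
#' @examples
#' p <- make_profile("7dpf")
#' p$steering_gain            # 0.67
#' make_profile("7dpf", sensitivity_a = 0)$sensitivity_a
#' @export
make_profile <- function(age = c("7dpf", "4dpf", "14dpf"), ...) {
  age <- match.arg(age)
  tab <- .profile_tables()[[age]]
  prof <- list(
    age = age,
    frame_rate = 166,
    sensitivity_a = tab$sensitivity_a,
    timing_vertex_b = tab$timing_vertex_b,
    baseline_rate_c = tab$baseline_rate_c,
    steering_gain = tab$steering_gain,
    sigmoid_a = tab$attack_mid - tab$sigmoid_h / 2,
    sigmoid_b = 0,
    sigmoid_k = 4 * tab$fin_body_ratio / tab$sigmoid_h,
    sigmoid_h = tab$sigmoid_h,
    righting_gain = tab$righting_gain,
    set_point = tab$set_point,
    peak_speed_mean = tab$peak_speed_mean,
    peak_speed_sd = tab$peak_speed_sd,
    pitch_at_peak_mean = tab$pitch_at_peak_mean,
    pitch_at_peak_sd = tab$pitch_at_peak_sd,
    ibi_pitch_mean = tab$ibi_pitch_mean,
    ibi_pitch_sd = tab$ibi_pitch_sd,
    trajectory_mean = tab$trajectory_mean,
    trajectory_sd = tab$trajectory_sd,
    srr_mean = tab$srr_mean,
    srr_sd = tab$srr_sd,
    steering_rotation_mean = tab$steering_rotation_mean,
    bout_displacement_mean = tab$bout_displacement_mean,
    angvel_peak_lead = tab$angvel_peak_lead,
    ibi_lognoise_sigma = 0.8,
    speed_threshold = 5,
    # residual SDs of the four fitted relationships plus latent-chain jitter
    timing_resid_sd = 0.6,
    steering_resid_sd = 6,
    finbody_resid_sd = 5,
    righting_resid_sd = 3,
    initial_pitch_jitter_sd = 1,
    residual_rotation_sd = 2
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("profile overrides must be named")
    unknown <- setdiff(names(overrides), names(prof))
    if (length(unknown))
      stop("unknown profile field(s): ", paste(unknown, collapse = ", "))
    prof[names(overrides)] <- overrides
  }
  validate_profile(prof)
  structure(prof, class = "kinematic_profile")
}

validate_profile <- function(p) {
  num <- p[setdiff(names(p), "age")]
  if (!all(vapply(num, function(v) is.numeric(v) && all(is.finite(v)), TRUE)))
    stop("profile fields must be finite numerics")
  stopifnot(
    p$frame_rate > 0,
    p$baseline_rate_c > 0,
    p$sigmoid_h >= 0,
    p$peak_speed_mean > 5,
    p$peak_speed_sd >= 0, p$ibi_pitch_sd >= 0, p$pitch_at_peak_sd >= 0,
    p$trajectory_sd >= 0, p$srr_sd >= 0,
    p$timing_resid_sd >= 0, p$steering_resid_sd >= 0,
    p$finbody_resid_sd >= 0, p$righting_resid_sd >= 0,
    p$initial_pitch_jitter_sd >= 0, p$residual_rotation_sd >= 0,
    p$ibi_lognoise_sigma >= 0
  )
  invisible(p)
}

#' @export
print.kinematic_profile <- function(x, ...) {
  cat("Kinematic profile (", x$age, "), frame rate ", x$frame_rate, " Hz\n",
      sep = "")
  cat(sprintf("  bout timing : a = %.3f mHz/deg^2, vertex b = %.2f deg, baseline c = %.2f Hz\n",
              1000 * x$sensitivity_a, x$timing_vertex_b, x$baseline_rate_c))
  cat(sprintf("  steering    : gain = %.2f\n", x$steering_gain))
  cat(sprintf("  fin-body    : k = %.3f /deg, h = %.2f deg (max slope kh/4 = %.2f)\n",
              x$sigmoid_k, x$sigmoid_h, x$sigmoid_k * x$sigmoid_h / 4))
  cat(sprintf("  righting    : gain = %.2f, set point = %.2f deg\n",
              x$righting_gain, x$set_point))
  cat(sprintf("  peak speed  : %.2f (%.2f) mm/s; pitch at peak %.2f (%.2f) deg\n",
              x$peak_speed_mean, x$peak_speed_sd,
              x$pitch_at_peak_mean, x$pitch_at_peak_sd))
  invisible(x)
}
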