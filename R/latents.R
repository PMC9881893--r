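# Ground-truth bout latents and targeted relationship samples.

#' Sample ground-truth bout latents
#'
#' Draws per-bout latent variables from the causal chain the simulator uses:
#' \enumerate{
#'   \item IBI pitch \eqn{p \sim N(\mu_p, \sigma_p)};
#'   \item preceding IBI duration \eqn{= \epsilon / \lambda(p)} with
#'     \eqn{\lambda(p) = a(p-b)^2 + c} and \eqn{\epsilon} lognormal with mean 1
#'     and shape `ibi_lognoise_sigma` (a multiplicative-noise inverse-rate
#'     model, so that bout frequency is proportional to \eqn{\lambda(p)} in
#'     expectation);
#'   \item initial pitch = IBI pitch + a small deterministic nose-down drift
#'     (front-heavy larvae fall nose-down between bouts; the offset is chosen
#'     so that pitch at peak speed has the profile's `pitch_at_peak_mean` in
#'     expectation) + jitter;
#'   \item steering-related rotation (initial pitch to time of peak angular
#'     velocity) drawn normal; attack angle = sigmoid(rotation) + noise;
#'   \item total steering rotation = steering-related rotation + a zero-mean
#'     residual rotation (accrued while angular velocity decays);
#'   \item pitch at peak = initial pitch + steering rotation;
#'     trajectory = pitch at peak + attack angle (exact, by construction);
#'   \item righting rotation = \eqn{-g (p_{initial} - p_{set})} + noise;
#'   \item peak speed from the truncated-normal speed model (always > 5 mm/s).
#' }
#'
#' @param profile a [make_profile()] object.
#' @param n number of bouts (>= 1).
#' @param seed integer seed; the same (profile, seed) yields identical output.
#' @return a data.frame of class `bout_latents`, one row per bout, with
#'   columns `onset_time` (NA until placed on a session timeline by
#'   [simulate_session()]), `preceding_ibi_duration`, `preceding_ibi_pitch`,
#'   `initial_pitch`, `steering_related_rotation`, `steering_rotation`,
#'   `attack_angle`, `pitch_at_peak`, `trajectory`, `righting_rotation`,
#'   `peak_speed`.
#' @export
sample_bout_latents <- function(profile, n, seed = 1L) {
  stopifnot(inherits(profile, "kinematic_profile"), n >= 1)
  validate_profile(profile)
  p <- profile
  set.seed(as.integer(seed))

  ibi_pitch <- stats::rnorm(n, p$ibi_pitch_mean, p$ibi_pitch_sd)
  lambda <- p$sensitivity_a * (ibi_pitch - p$timing_vertex_b)^2 + p$baseline_rate_c
  s <- p$ibi_lognoise_sigma
  eps <- if (s > 0) stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s) else rep(1, n)
  ibi_dur <- eps / lambda

  # front-heavy larvae drift nose-down between bouts: the deterministic
  # offset from the IBI pitch to the initial pitch is chosen so that pitch at
  # peak speed has the profile's pitch_at_peak_mean in expectation
  resid_rot_mean <- p$steering_rotation_mean - p$srr_mean
  drift_offset <- p$pitch_at_peak_mean - p$ibi_pitch_mean - p$srr_mean -
    resid_rot_mean
  initial_pitch <- ibi_pitch + drift_offset +
    stats::rnorm(n, 0, p$initial_pitch_jitter_sd)
  srr <- stats::rnorm(n, p$srr_mean, p$srr_sd)
  attack <- logistic4(srr, p$sigmoid_a, p$sigmoid_b, p$sigmoid_k, p$sigmoid_h) +
    stats::rnorm(n, 0, p$finbody_resid_sd)
  steering_rot <- srr +
    stats::rnorm(n, resid_rot_mean, p$residual_rotation_sd)
  pitch_at_peak <- initial_pitch + steering_rot
  trajectory <- pitch_at_peak + attack
  righting <- -p$righting_gain * (initial_pitch - p$set_point) +
    stats::rnorm(n, 0, p$righting_resid_sd)

  if (p$peak_speed_sd == 0) {
    peak_speed <- rep(p$peak_speed_mean, n)
  } else {
    sp <- match_truncated_normal(p$peak_speed_mean, p$peak_speed_sd,
                                 p$speed_threshold)
    peak_speed <- rtrunc_norm(n, sp["mu"], sp["sigma"], p$speed_threshold)
  }

  out <- data.frame(
    onset_time = NA_real_,
    preceding_ibi_duration = ibi_dur,
    preceding_ibi_pitch = ibi_pitch,
    initial_pitch = initial_pitch,
    steering_related_rotation = srr,
    steering_rotation = steering_rot,
    attack_angle = attack,
    pitch_at_peak = pitch_at_peak,
    trajectory = trajectory,
    righting_rotation = righting,
    peak_speed = peak_speed
  )
  class(out) <- c("bout_latents", "data.frame")
  out
}

#' Default targeted-mode parameters for one relationship
#'
#' Extracts, from a profile, the coefficients, residual SD and predictor
#' distribution that [generate_relationship_samples()] needs for a single
#' relationship. Used so each of the four fitted relationships can be
#' generated (and hence recovered) in isolation.
#'
#' @param profile a [make_profile()] object.
#' @param relationship one of `"timing"`, `"steering"`, `"finbody"`,
#'   `"righting"`.
#' @return a named list of generating parameters.
#' @export
relationship_params <- function(profile,
                                relationship = c("timing", "steering",
                                                 "finbody", "righting")) {
  relationship <- match.arg(relationship)
  p <- profile
  switch(relationship,
    timing = list(a = p$sensitivity_a, b = p$timing_vertex_b,
                  c = p$baseline_rate_c,
                  x_mean = p$ibi_pitch_mean, x_sd = p$ibi_pitch_sd,
                  resid_sd = p$timing_resid_sd),
    steering = list(gain = p$steering_gain,
                    intercept = p$pitch_at_peak_mean -
                      p$steering_gain * p$trajectory_mean,
                    x_mean = p$trajectory_mean, x_sd = p$trajectory_sd,
                    resid_sd = p$steering_resid_sd),
    finbody = list(a = p$sigmoid_a, b = p$sigmoid_b, k = p$sigmoid_k,
                   h = p$sigmoid_h,
                   x_mean = p$srr_mean, x_sd = p$srr_sd,
                   resid_sd = p$finbody_resid_sd),
    righting = list(slope = -p$righting_gain,
                    intercept = p$righting_gain * p$set_point,
                    x_mean = p$ibi_pitch_mean, x_sd = p$ibi_pitch_sd,
                    resid_sd = p$righting_resid_sd)
  )
}

#' Generate targeted-mode (x, y) samples for one relationship
#'
#' Draws paired samples directly from one of the four kinematic
#' relationships, so that the corresponding fit recovers the generating
#' coefficients exactly in expectation (and exactly, when `resid_sd = 0`).
#' This is the mode used for coefficient-recovery tests; [simulate_session()]
#' is the end-to-end mode.
#'
#' @param relationship one of `"timing"` (x = IBI pitch, y = bout frequency,
#'   \eqn{E[y|x] = a(x-b)^2 + c}), `"steering"` (x = trajectory, y = pitch at
#'   peak, \eqn{E[y|x] = gain \cdot x + intercept}), `"finbody"` (x =
#'   steering-related rotation, y = attack angle on the logistic), or
#'   `"righting"` (x = initial pitch, y = righting rotation on the
#'   negative-slope line).
#' @param params named list as returned by [relationship_params()]; individual
#'   entries may be overridden before the call.
#' @param n number of pairs; must exceed the number of model coefficients.
#' @param seed integer seed.
#' @return a data.frame with columns `x`, `y` and attribute `relationship`.
#' @export
generate_relationship_samples <- function(relationship, params, n, seed = 1L) {
  relationship <- match.arg(relationship,
                            c("timing", "steering", "finbody", "righting"))
  ncoef <- switch(relationship, timing = 3, steering = 2, finbody = 4,
                  righting = 2)
  if (n < ncoef)
    stop("n must be at least the number of model coefficients (", ncoef, ")")
  req <- switch(relationship,
    timing = c("a", "b", "c"), steering = c("gain", "intercept"),
    finbody = c("a", "b", "k", "h"), righting = c("slope", "intercept"))
  missing_par <- setdiff(c(req, "x_mean", "x_sd", "resid_sd"), names(params))
  if (length(missing_par))
    stop("missing relationship parameter(s): ",
         paste(missing_par, collapse = ", "))
  set.seed(as.integer(seed))
  x <- stats::rnorm(n, params$x_mean, params$x_sd)
  ey <- switch(relationship,
    timing = params$a * (x - params$b)^2 + params$c,
    steering = params$gain * x + params$intercept,
    finbody = logistic4(x, params$a, params$b, params$k, params$h),
    righting = params$slope * x + params$intercept)
  y <- ey + stats::rnorm(n, 0, params$resid_sd)
  structure(data.frame(x = x, y = y), relationship = relationship,
            params = params)
}
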