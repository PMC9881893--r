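# Continuous session simulation: latents -> pose trace -> raw records.

# Pre-peak pitch ramp over [-pre, 0]: a constant base rotation rate plus a
# symmetric squared-cosine angular-velocity bump centered `lead` seconds
# before the speed peak (half-width = lead, so the bump ends exactly at the
# peak). The base rate and bump area are solved so that the pitch change
# from bout start to the angular-velocity peak equals the steering-related
# rotation latent exactly, and the change from there to the speed peak
# equals the residual rotation. A symmetric bump keeps the measured
# (moving-average-smoothed) angular-velocity peak at -lead, which an
# asymmetric ramp would not. Closed form, exact at any sample time.
.steer_ramp_inc <- function(tau, lead, srr, resid, pre = 0.25) {
  w_b <- (srr - resid) / (pre - 2 * lead)
  s1 <- resid - w_b * lead
  L <- lead
  A <- 2 * s1 / L
  u <- pmin(pmax(tau + lead, -L), L)
  bump_cum <- A * (u / 2 + (L / (2 * pi)) * sin(pi * u / L) + L / 2)
  tau_c <- pmin(pmax(tau, -pre), 0)
  w_b * (tau_c + pre) + bump_cum
}

# Raised-cosine step for the post-peak righting rotation (zero slope at both
# ends, complete at `dur`).
.right_frac <- function(tau, dur = 0.1) {
  f <- 0.5 * (1 - cos(pi * pmin(pmax(tau, 0), dur) / dur))
  f
}

#' Simulate a recording session
#'
#' Generates a continuous pose trace at the acquisition frame rate by
#' concatenating inter-bout intervals (pitch relaxing to the IBI pitch, then
#' moving to the next bout's initial pitch, plus small jitter) and swim bouts
#' (a raised-cosine speed bump reaching the sampled peak speed, whose width is
#' set so the net displacement equals the profile's mean bout displacement;
#' pitch follows a smooth pre-peak steering ramp whose angular velocity peaks
#' `angvel_peak_lead` ms before the speed peak, and a post-peak righting ramp
#' completing by +100 ms). Displacement during a bout points along the bout's
#' trajectory angle. Occasional detection gaps (rate `epoch_break_rate` per
#' IBI) split the trace into epochs. Ground-truth latents are attached.
#'
#' @param profile a [make_profile()] object.
#' @param duration session length in seconds (> 0). Sessions shorter than one
#'   bout cycle simply contain zero bouts.
#' @param seed integer seed.
#' @param epoch_break_rate probability, per inter-bout interval, of inserting
#'   a 1 s detection gap (only in IBIs longer than 2.5 s).
#' @return a list of class `pose_trace` with elements `times`, `x`, `z`
#'   (mm, z up), `pitch` (deg), `epoch_id` (integer), `frame_rate`, and
#'   `ground_truth`, a data.frame of the placed bouts (the latent columns of
#'   [sample_bout_latents()] plus `onset_time`, `peak_time`, and
#'   `extractable`, TRUE when the full -500/+300 ms window lies inside the
#'   bout's epoch).
#' @export
simulate_session <- function(profile, duration, seed = 1L,
                             epoch_break_rate = 0.02) {
  stopifnot(inherits(profile, "kinematic_profile"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  p <- profile
  dt <- 1 / p$frame_rate
  thr <- p$speed_threshold
  pre_ramp <- 0.25
  post_ramp <- 0.10
  lead <- p$angvel_peak_lead / 1000

  # draw more latents than can fit, then place until the session is full
  mean_cycle <- 1 / p$baseline_rate_c + 0.4
  n_est <- max(4L, ceiling(duration / mean_cycle * 1.8) + 8L)
  lat <- sample_bout_latents(p, n_est, seed = seed)
  breaks <- stats::runif(n_est) < epoch_break_rate
  jitter_sd <- min(0.2, p$initial_pitch_jitter_sd)

  w <- 2 * p$bout_displacement_mean / lat$peak_speed        # bump width (s)
  tau_star <- (w / (2 * pi)) * acos(pmin(1, 2 * thr / lat$peak_speed - 1))
  tail <- w / 2 - tau_star                                  # sub-threshold tail

  # place bouts sequentially; peaks are kept at least pre_ramp + post_ramp
  # plus a short drift apart so consecutive maneuvers never overlap (the
  # realized IBI replaces the drawn one in the ground truth)
  peak <- numeric(n_est)
  cur <- 0
  n_placed <- 0L
  # the latent IBI duration is the *buffered* duration (the quantity bout
  # frequency is the reciprocal of), so the sub-threshold gap laid down is
  # latent + 2 x 100 ms detection buffers
  ibi_buf <- 0.2
  for (i in seq_len(n_est)) {
    gap <- lat$preceding_ibi_duration[i] + ibi_buf - tail[i] -
      if (i > 1) tail[i - 1] else 0
    gap <- max(gap, 0.05)
    pk <- cur + gap + w[i] / 2
    min_pk <- if (i > 1) peak[i - 1] + pre_ramp + post_ramp + 0.07 else
      pre_ramp + 0.01
    pk <- max(pk, min_pk)
    if (pk + w[i] / 2 + post_ramp > duration) break
    lat$preceding_ibi_duration[i] <- (pk - w[i] / 2 - cur) + tail[i] - ibi_buf +
      if (i > 1) tail[i - 1] else 0
    peak[i] <- pk
    cur <- pk + w[i] / 2
    n_placed <- i
  }
  N <- floor(duration / dt) + 1L
  times <- (seq_len(N) - 1L) * dt
  speed_v <- numeric(N)
  pitch_v <- numeric(N)
  visible <- rep(TRUE, N)
  epoch_bump <- integer(N)

  if (n_placed == 0L) {
    pitch_v[] <- p$ibi_pitch_mean
    gt <- lat[0, ]
    gt$peak_time <- numeric(0)
    gt$extractable <- logical(0)
  } else {
    lat <- lat[seq_len(n_placed), , drop = FALSE]
    peak <- peak[seq_len(n_placed)]
    w <- w[seq_len(n_placed)]
    tau_star <- tau_star[seq_len(n_placed)]
    breaks <- breaks[seq_len(n_placed)]
    end_pitch <- lat$pitch_at_peak + lat$righting_rotation

    idx_at <- function(t) pmin(pmax(1L, as.integer(round(t / dt)) + 1L), N)

    # inter-bout pitch: hold the previous end pitch briefly, relax to the IBI
    # pitch, hold, then approach the next initial pitch over the last 150 ms
    # before the steering ramp begins
    seg_start_t <- c(0, peak[-n_placed] + post_ramp)
    seg_from <- c(lat$preceding_ibi_pitch[1], end_pitch[-n_placed])
    plateau <- 0.02
    for (i in seq_len(n_placed)) {
      i0 <- idx_at(seg_start_t[i])
      i1 <- idx_at(peak[i] - pre_ramp)
      if (i1 < i0) i1 <- i0
      tt <- times[i0:i1]
      span <- max(tt[length(tt)] - tt[1], dt)
      r <- min(0.15, max(span / 3 - plateau, dt))
      hold <- lat$preceding_ibi_pitch[i]
      # piecewise-linear through (start.. start+plateau, from) ->
      # (start+plateau+r, hold) -> (end-r, hold) -> (end, initial)
      rel <- tt - tt[1]
      pv <- ifelse(rel < plateau, seg_from[i],
             ifelse(rel < plateau + r,
                    seg_from[i] + (hold - seg_from[i]) * (rel - plateau) / r,
             ifelse(rel > span - r,
                    hold + (lat$initial_pitch[i] - hold) * (rel - (span - r)) / r,
                    hold)))
      if (jitter_sd > 0) pv <- pv + stats::rnorm(length(pv), 0, jitter_sd)
      pitch_v[i0:i1] <- pv
      # steering ramp: rise phase carries the steering-related rotation,
      # fall phase the residual rotation
      j0 <- i1
      j1 <- idx_at(peak[i])
      tt2 <- times[j0:j1] - peak[i]
      srr_i <- lat$steering_related_rotation[i]
      resid_rot <- lat$steering_rotation[i] - srr_i
      pitch_v[j0:j1] <- lat$initial_pitch[i] +
        .steer_ramp_inc(tt2, lead, srr_i, resid_rot, pre_ramp)
      # righting ramp
      k1 <- idx_at(peak[i] + post_ramp)
      tt3 <- times[j1:k1] - peak[i]
      pitch_v[j1:k1] <- lat$pitch_at_peak[i] +
        lat$righting_rotation[i] * .right_frac(tt3, post_ramp)
      # speed bump
      b0 <- idx_at(peak[i] - w[i] / 2)
      b1 <- idx_at(peak[i] + w[i] / 2)
      tb <- times[b0:b1] - peak[i]
      bump <- lat$peak_speed[i] * 0.5 * (1 + cos(2 * pi * tb / w[i]))
      bump[abs(tb) > w[i] / 2] <- 0
      speed_v[b0:b1] <- bump
    }
    # tail of the session after the last bout
    i0 <- idx_at(peak[n_placed] + post_ramp)
    if (i0 < N) pitch_v[i0:N] <- end_pitch[n_placed]

    # detection gaps inside long IBIs
    for (i in seq_len(n_placed)) {
      if (!breaks[i]) next
      ibi_lo <- if (i == 1) 0 else peak[i - 1] + w[i - 1] / 2
      ibi_hi <- peak[i] - w[i] / 2
      if (ibi_hi - ibi_lo < 2.5) next
      mid <- (ibi_lo + ibi_hi) / 2
      g0 <- idx_at(mid - 0.5); g1 <- idx_at(mid + 0.5)
      visible[g0:g1] <- FALSE
      if (g1 < N) epoch_bump[g1 + 1L] <- 1L
    }

    gt <- lat
    gt$onset_time <- peak - tau_star
    gt$peak_time <- peak
  }

  epoch_id <- 1L + cumsum(epoch_bump)
  # displacement: integrate speed along each bout's trajectory direction
  if (n_placed > 0L) {
    dirx <- numeric(N); dirz <- numeric(N)
    for (i in seq_len(n_placed)) {
      b0 <- min(max(1L, as.integer(round((peak[i] - w[i] / 2) / dt)) + 1L), N)
      b1 <- min(max(1L, as.integer(round((peak[i] + w[i] / 2) / dt)) + 1L), N)
      ang <- gt$trajectory[i] * pi / 180
      dirx[b0:b1] <- cos(ang)
      dirz[b0:b1] <- sin(ang)
    }
    x <- cumsum(speed_v * dirx) * dt
    z <- cumsum(speed_v * dirz) * dt
  } else {
    x <- numeric(N); z <- numeric(N)
  }

  keep <- visible
  times_k <- times[keep]; epoch_k <- epoch_id[keep]
  # extractability: full -500/+300 ms window inside the bout's epoch
  if (n_placed > 0L) {
    ep_of <- function(t) epoch_id[pmin(pmax(1L, as.integer(round(t / dt)) + 1L), N)]
    ep_lo <- vapply(split(times_k, epoch_k), min, 0)
    ep_hi <- vapply(split(times_k, epoch_k), max, 0)
    pk_ep <- ep_of(gt$peak_time)
    vis_pk <- visible[pmin(pmax(1L, as.integer(round(gt$peak_time / dt)) + 1L), N)]
    gt$extractable <- vis_pk &
      (gt$peak_time - 0.5 >= ep_lo[as.character(pk_ep)]) &
      (gt$peak_time + 0.3 <= ep_hi[as.character(pk_ep)]) &
      ep_of(gt$peak_time - 0.5) == pk_ep &
      ep_of(gt$peak_time + 0.3) == pk_ep
  }

  structure(list(times = times_k, x = x[keep], z = z[keep],
                 pitch = pitch_v[keep], epoch_id = epoch_k,
                 frame_rate = p$frame_rate, speed_true = speed_v[keep],
                 ground_truth = gt),
            class = "pose_trace")
}

#' @export
print.pose_trace <- function(x, ...) {
  cat("Pose trace:", length(x$times), "frames at", x$frame_rate, "Hz,",
      length(unique(x$epoch_id)), "epoch(s),",
      nrow(x$ground_truth), "ground-truth bout(s)\n")
  invisible(x)
}

#' Convert a pose trace to raw records
#'
#' One record per frame; the head is placed half a body length from the body
#' centroid along the pitch direction (heading along +x), and the fish length
#' is constant for the session.
#'
#' @param trace a [simulate_session()] trace.
#' @param metadata a [session_metadata()] object; `fish_length` (mm) is read
#'   from it when present.
#' @param body_length fish length in mm (default 4).
#' @return a [raw_records()] data.frame.
#' @export
trace_to_records <- function(trace, metadata = session_metadata(),
                             body_length = 4) {
  stopifnot(inherits(trace, "pose_trace"))
  if (!is.null(metadata$fish_length)) body_length <- as.numeric(metadata$fish_length)
  n <- length(trace$times)
  if (n == 0) return(raw_records())
  ang <- trace$pitch * pi / 180
  raw_records(time = trace$times,
              body_x = trace$x, body_z = trace$z,
              head_x = trace$x + cos(ang) * body_length / 2,
              head_z = trace$z + sin(ang) * body_length / 2,
              pitch = trace$pitch,
              epoch_id = trace$epoch_id,
              length = rep(body_length, n))
}
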