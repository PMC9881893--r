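# Per-bout kinematic features.

#' Compute per-bout features
#'
#' For each aligned bout, samples pitch at the grid points nearest -250, 0,
#' +100 and +200 ms relative to the peak-speed frame, derives the rotation
#' decomposition, and measures the bout trajectory from the displacement
#' vector between the two frames flanking t = 0 (elevation-signed and
#' invariant to left/right heading, range (-90, 90]). Displacement is the net
#' distance over the contiguous super-threshold span containing t = 0.
#'
#' Feature identities hold exactly by construction:
#' `attack_angle = trajectory - pitch_at_peak` and
#' `steering_rotation = pitch_at_peak - initial_pitch`.
#'
#' @param bouts an [extract_bouts()] object.
#' @param angvel_time_ms time of peak angular velocity, in ms before the
#'   speed peak, at which the steering-related rotation is evaluated
#'   (typically the per-repeat value from [angular_velocity_summary()], or
#'   the fixed 40 ms convention).
#' @return data.frame of class `bout_features`, one row per bout: pitches at
#'   the four landmarks, `trajectory`, `peak_speed`, `displacement`,
#'   `steering_rotation`, `steering_related_rotation`, `righting_rotation`,
#'   `attack_angle`, `trajectory_deviation`, plus `bout_id`, `epoch_id`,
#'   `repeat_id`.
#' @export
bout_features <- function(bouts, angvel_time_ms = 40) {
  stopifnot(inherits(bouts, "aligned_bouts"))
  if (nrow(bouts$bouts) == 0) {
    out <- data.frame(bout_id = integer(), initial_pitch = numeric(),
                      pitch_at_peak = numeric(), post_bout_pitch = numeric(),
                      end_pitch = numeric(), trajectory = numeric(),
                      peak_speed = numeric(), displacement = numeric(),
                      steering_rotation = numeric(),
                      steering_related_rotation = numeric(),
                      righting_rotation = numeric(), attack_angle = numeric(),
                      trajectory_deviation = numeric(), epoch_id = integer(),
                      repeat_id = character())
    class(out) <- c("bout_features", "data.frame")
    return(out)
  }
  thr <- bouts$speed_threshold
  res <- lapply(split(bouts$samples, bouts$samples$bout_id), function(s) {
    near <- function(t) s$pitch[which.min(abs(s$t_ms - t))]
    i0 <- which.min(abs(s$t_ms))
    initial <- near(-250); at_peak <- near(0)
    post <- near(100); endp <- near(200)
    pre_av <- near(-abs(angvel_time_ms))
    dx <- s$x[min(i0 + 1L, nrow(s))] - s$x[max(i0 - 1L, 1L)]
    dz <- s$z[min(i0 + 1L, nrow(s))] - s$z[max(i0 - 1L, 1L)]
    traj <- elevation_angle(dx, dz)
    # contiguous super-threshold span containing t = 0
    sup <- s$speed > thr
    lo <- i0; hi <- i0
    while (lo > 1L && sup[lo - 1L]) lo <- lo - 1L
    while (hi < nrow(s) && sup[hi + 1L]) hi <- hi + 1L
    disp <- sqrt((s$x[hi] - s$x[lo])^2 + (s$z[hi] - s$z[lo])^2)
    data.frame(bout_id = s$bout_id[1],
               initial_pitch = initial, pitch_at_peak = at_peak,
               post_bout_pitch = post, end_pitch = endp,
               trajectory = traj, displacement = disp,
               steering_rotation = at_peak - initial,
               steering_related_rotation = pre_av - initial,
               righting_rotation = post - at_peak,
               attack_angle = traj - at_peak,
               trajectory_deviation = traj - initial)
  })
  out <- do.call(rbind, res)
  out <- merge(out, bouts$bouts[, c("bout_id", "epoch_id", "peak_speed",
                                    "repeat_id")], by = "bout_id")
  rownames(out) <- NULL
  class(out) <- c("bout_features", "data.frame")
  out
}

#' Binned averages for display
#'
#' Sorts x into bins aligned to multiples of `bin_width` and returns per-bin
#' means of x and y. Empty bins are omitted. Intended for plotting only;
#' all model fits in this package use the raw points.
#'
#' @param x,y numeric vectors.
#' @param bin_width bin width in x units (> 0).
#' @return data.frame with `bin_center`, `x_mean`, `y_mean`, `n`.
#' @export
binned_average <- function(x, y, bin_width) {
  stopifnot(bin_width > 0, length(x) == length(y))
  b <- floor(x / bin_width)
  xs <- tapply(x, b, mean); ys <- tapply(y, b, mean)
  ns <- tapply(x, b, length)
  data.frame(bin_center = (as.numeric(names(xs)) + 0.5) * bin_width,
             x_mean = as.numeric(xs), y_mean = as.numeric(ys),
             n = as.integer(ns))
}
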