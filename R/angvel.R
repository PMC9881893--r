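# Adjusted angular-velocity summary: when, before the speed peak, does the
# body rotate fastest?

#' Angular-velocity summary across bouts and repeats
#'
#' Per bout, the pitch trace is smoothed with a centered moving average
#' (default 11 frames) and differentiated to angular velocity (deg/s). The
#' sign of bouts that start with nose-down rotation — operationalized as a
#' negative mean angular velocity over -250 to 0 ms — is flipped so all bouts
#' start with positive rotation. Per experimental repeat, the median adjusted
#' trace across bouts is taken at every time point, and the peak time is the
#' time of that trace's maximum before t = 0, expressed in ms before the
#' speed peak. The summary reports the mean and SD of the peak time across
#' repeats.
#'
#' @param bouts an [extract_bouts()] object (the `repeat_id` column of
#'   `bouts$bouts` defines the repeats).
#' @param smoothing odd window width in frames for pitch smoothing.
#' @return list of class `angvel_summary`: `per_repeat` (repeat_id,
#'   peak_time_ms, n_bouts), `mean_peak_time`, `sd_peak_time`, `times_ms`
#'   (grid of the median traces) and `median_traces` (one column per repeat).
#' @export
angular_velocity_summary <- function(bouts, smoothing = 11) {
  stopifnot(inherits(bouts, "aligned_bouts"))
  if (nrow(bouts$bouts) == 0) stop("no bouts to summarize")
  dt <- 1 / bouts$frame_rate
  ids <- bouts$bouts$bout_id
  n_win <- sum(bouts$samples$bout_id == ids[1])
  if (smoothing >= n_win)
    stop("smoothing window (", smoothing, ") is not shorter than the bout (",
         n_win, " frames)")
  t_ms <- bouts$samples$t_ms[bouts$samples$bout_id == ids[1]]
  t_av <- (t_ms[-1] + t_ms[-length(t_ms)]) / 2   # midpoint grid
  av_mat <- vapply(split(bouts$samples$pitch, bouts$samples$bout_id),
    function(pitch) {
      sm <- moving_average(pitch, smoothing)
      av <- diff(sm) / dt
      pre <- av[t_av >= -250 & t_av < 0]
      if (mean(pre) < 0) av <- -av
      av
    }, numeric(n_win - 1L))
  rep_of <- bouts$bouts$repeat_id[match(as.integer(colnames(av_mat)),
                                        bouts$bouts$bout_id)]
  reps <- unique(rep_of)
  med <- vapply(reps, function(r) {
    m <- av_mat[, rep_of == r, drop = FALSE]
    apply(m, 1, stats::median)
  }, numeric(n_win - 1L))
  pre_ix <- which(t_av < 0)
  peak_ms <- vapply(seq_along(reps), function(j) {
    -t_av[pre_ix[which.max(med[pre_ix, j])]]
  }, numeric(1))
  per_repeat <- data.frame(repeat_id = reps, peak_time_ms = peak_ms,
                           n_bouts = as.integer(table(rep_of)[reps]))
  structure(list(per_repeat = per_repeat,
                 mean_peak_time = mean(peak_ms),
                 sd_peak_time = if (length(peak_ms) > 1) stats::sd(peak_ms) else NA_real_,
                 times_ms = t_av, median_traces = med),
            class = "angvel_summary")
}

#' @export
print.angvel_summary <- function(x, ...) {
  cat("Angular-velocity peak:", sprintf("%.1f", x$mean_peak_time),
      "ms before peak speed (SD",
      sprintf("%.1f", x$sd_peak_time), "across",
      nrow(x$per_repeat), "repeat(s))\n")
  invisible(x)
}
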