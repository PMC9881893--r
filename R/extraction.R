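# Swim-bout and inter-bout-interval extraction from raw pose records.

#' Extraction configuration
#'
#' Parameters governing bout segmentation. Defaults follow the standard
#' zebrafish analysis: bouts are spans where instantaneous speed exceeds
#' 5 mm/s; only epochs longer than 2.5 s containing at least one such span
#' are analyzed; aligned bout windows run from 500 ms before to 300 ms after
#' the peak-speed frame (800 ms total); inter-bout intervals lose a 100 ms
#' buffer at each end.
#'
#' @param speed_threshold mm/s; a bout is a span with speed strictly above
#'   this.
#' @param min_epoch_duration s; epochs must be strictly longer.
#' @param pre_window,post_window ms before/after the peak-speed frame.
#' @param ibi_buffer ms deducted from each end of an inter-bout interval.
#' @param speed_smoothing odd number of frames for a centered moving average
#'   of the speed series (1 = off).
#' @param qc_max_jump mm of frame-to-frame displacement above which an epoch
#'   is discarded as a tracking artifact. `NULL` (default) resolves to a
#'   150 mm/s pace equivalent at the session frame rate — an order of
#'   magnitude above typical swim speed, so genuine fast bouts are kept while
#'   tracking teleports are not.
#' @param qc_length_tolerance fractional deviation of recorded fish length
#'   from the session median beyond which an epoch is discarded.
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(speed_threshold = 5, min_epoch_duration = 2.5,
                              pre_window = 500, post_window = 300,
                              ibi_buffer = 100, speed_smoothing = 3,
                              qc_max_jump = NULL, qc_length_tolerance = 0.4) {
  stopifnot(speed_threshold > 0, min_epoch_duration > 0,
            pre_window > 0, post_window > 0, ibi_buffer > 0,
            speed_smoothing >= 1, qc_length_tolerance > 0)
  structure(list(speed_threshold = speed_threshold,
                 min_epoch_duration = min_epoch_duration,
                 pre_window = pre_window, post_window = post_window,
                 ibi_buffer = ibi_buffer, speed_smoothing = speed_smoothing,
                 qc_max_jump = qc_max_jump,
                 qc_length_tolerance = qc_length_tolerance),
            class = "extraction_config")
}

.infer_dt <- function(series) {
  d <- unlist(tapply(series$time, series$epoch_id, function(t) diff(t),
                     simplify = FALSE), use.names = FALSE)
  if (!length(d)) stop("cannot infer frame interval from a single frame")
  stats::median(d)
}

#' Per-frame instantaneous speed
#'
#' Adds a `speed` column: the Euclidean body-centroid displacement from the
#' previous frame divided by the frame interval, never computed across epoch
#' boundaries. The first frame of each epoch inherits its successor's speed.
#' Single-frame epochs cannot carry a speed and are dropped with a warning.
#' An optional centered moving average (within epochs) smooths the series.
#'
#' @param series a [raw_records()] data.frame.
#' @param cfg an [extraction_config()].
#' @return the series with a `speed` column (mm/s).
#' @export
compute_speed <- function(series, cfg = extraction_config()) {
  stopifnot(inherits(series, "data.frame"), nrow(series) >= 0)
  if (nrow(series) == 0) { series$speed <- numeric(0); return(series) }
  sizes <- table(series$epoch_id)
  singles <- as.integer(names(sizes)[sizes < 2])
  if (length(singles)) {
    warning("dropping ", length(singles), " single-frame epoch(s)")
    series <- series[!series$epoch_id %in% singles, , drop = FALSE]
    if (nrow(series) == 0) { series$speed <- numeric(0); return(series) }
  }
  sp <- unlist(lapply(split(seq_len(nrow(series)), series$epoch_id),
    function(ix) {
      t <- series$time[ix]
      d <- sqrt(diff(series$body_x[ix])^2 + diff(series$body_z[ix])^2)
      v <- d / diff(t)
      v <- c(v[1], v)
      if (cfg$speed_smoothing > 1) v <- moving_average(v, cfg$speed_smoothing)
      v
    }), use.names = FALSE)
  # split() orders groups by epoch id; restore original row order
  ord <- order(series$epoch_id, seq_len(nrow(series)))
  series$speed[ord] <- sp
  series
}

#' Select analyzable epochs
#'
#' Keeps epochs that are strictly longer than `min_epoch_duration`, reach a
#' maximum speed strictly above `speed_threshold`, and pass quality control:
#' no frame-to-frame displacement above `qc_max_jump`, recorded fish length
#' within `qc_length_tolerance` of the session median at every frame, and no
#' missing frames (within-epoch interval within 10% of the frame interval).
#' Exclusions are recorded, with reasons, in the `"excluded"` attribute.
#'
#' @param series output of [compute_speed()].
#' @param cfg an [extraction_config()].
#' @return the filtered series; `attr(, "excluded")` is a data.frame of
#'   (epoch_id, reason).
#' @export
select_epochs <- function(series, cfg = extraction_config()) {
  if (is.null(series$speed)) stop("run compute_speed() first")
  if (nrow(series) == 0) return(series)
  dt <- .infer_dt(series)
  max_jump <- cfg$qc_max_jump %||% (150 * dt)
  med_len <- stats::median(series$length)
  excl <- list()
  keep_ids <- c()
  for (ep in unique(series$epoch_id)) {
    ix <- which(series$epoch_id == ep)
    t <- series$time[ix]
    reason <- NULL
    if (t[length(t)] - t[1] <= cfg$min_epoch_duration) reason <- "too_short"
    else if (max(series$speed[ix]) <= cfg$speed_threshold) reason <- "no_swim"
    else {
      jump <- sqrt(diff(series$body_x[ix])^2 + diff(series$body_z[ix])^2)
      if (any(jump > max_jump)) reason <- "jump"
      else if (any(abs(series$length[ix] - med_len) >
                   cfg$qc_length_tolerance * med_len)) reason <- "length"
      else if (any(diff(t) > 1.1 * dt)) reason <- "missing_frames"
    }
    if (is.null(reason)) keep_ids <- c(keep_ids, ep)
    else excl[[length(excl) + 1L]] <- data.frame(epoch_id = ep, reason = reason)
  }
  out <- series[series$epoch_id %in% keep_ids, , drop = FALSE]
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(epoch_id = integer(), reason = character())
  out
}

# Maximal super-threshold spans within one epoch's speed series; returns a
# data.frame of (start, end) row offsets, or NULL.
.super_spans <- function(speed, thr) {
  r <- rle(speed > thr)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Extract peak-aligned swim bouts
#'
#' Within each epoch, every maximal span with speed strictly above the
#' threshold yields one candidate bout at its speed maximum (the first frame
#' on ties). A bout is kept iff the full window from `pre_window` ms before
#' to `post_window` ms after the peak lies inside the epoch. Windows are
#' sampled on the session frame grid, with the peak frame at t = 0.
#'
#' @param epochs output of [select_epochs()].
#' @param cfg an [extraction_config()].
#' @param repeat_id optional label attached to every bout.
#' @return list of class `aligned_bouts`: `bouts` (one row per bout:
#'   `bout_id`, `epoch_id`, `peak_time`, `peak_speed`, `repeat_id`),
#'   `samples` (one row per window sample: `bout_id`, `t_ms`, `speed`,
#'   `pitch`, `x`, `z`), `frame_rate`, and the window extents.
#' @export
extract_bouts <- function(epochs, cfg = extraction_config(),
                          repeat_id = "r01") {
  if (is.null(epochs$speed)) stop("run compute_speed() first")
  dt <- if (nrow(epochs) > 1) .infer_dt(epochs) else NA_real_
  fps <- 1 / dt
  pre_n <- round(cfg$pre_window / 1000 * fps)
  post_n <- round(cfg$post_window / 1000 * fps)
  bouts <- list(); samples <- list(); bid <- 0L
  for (ep in unique(epochs$epoch_id)) {
    ix <- which(epochs$epoch_id == ep)
    spans <- .super_spans(epochs$speed[ix], cfg$speed_threshold)
    if (is.null(spans)) next
    for (si in seq_len(nrow(spans))) {
      seg <- spans$start[si]:spans$end[si]
      pk_rel <- seg[which.max(epochs$speed[ix][seg])]
      lo <- pk_rel - pre_n; hi <- pk_rel + post_n
      if (lo < 1 || hi > length(ix)) next
      bid <- bid + 1L
      rows <- ix[lo:hi]
      samples[[bid]] <- data.frame(
        bout_id = bid,
        t_ms = (seq(-pre_n, post_n)) * dt * 1000,
        speed = epochs$speed[rows], pitch = epochs$pitch[rows],
        x = epochs$body_x[rows], z = epochs$body_z[rows])
      bouts[[bid]] <- data.frame(
        bout_id = bid, epoch_id = ep,
        peak_time = epochs$time[ix][pk_rel],
        peak_speed = epochs$speed[ix][pk_rel],
        repeat_id = repeat_id)
    }
  }
  structure(list(
    bouts = if (bid) do.call(rbind, bouts) else
      data.frame(bout_id = integer(), epoch_id = integer(),
                 peak_time = numeric(), peak_speed = numeric(),
                 repeat_id = character()),
    samples = if (bid) do.call(rbind, samples) else
      data.frame(bout_id = integer(), t_ms = numeric(), speed = numeric(),
                 pitch = numeric(), x = numeric(), z = numeric()),
    frame_rate = fps, pre_window = cfg$pre_window,
    post_window = cfg$post_window,
    speed_threshold = cfg$speed_threshold),
    class = "aligned_bouts")
}

#' @export
print.aligned_bouts <- function(x, ...) {
  cat("Aligned bouts:", nrow(x$bouts), "bout(s),",
      "window -", x$pre_window, "/ +", x$post_window, "ms at",
      round(x$frame_rate, 1), "Hz\n")
  invisible(x)
}

#' Extract buffered inter-bout intervals
#'
#' For each sub-threshold span between two consecutive super-threshold spans
#' within an epoch, the IBI duration is the time from the last super-threshold
#' frame to the next super-threshold frame minus a buffer at each end
#' (non-positive results are discarded); the IBI pitch is the mean pitch over
#' the buffered interval, and bout frequency is the reciprocal of the
#' duration.
#'
#' @param epochs output of [select_epochs()].
#' @param cfg an [extraction_config()].
#' @param repeat_id optional label.
#' @return data.frame of class `ibi_records`: `duration` (s), `mean_pitch`
#'   (deg), `bout_frequency` (Hz), `time` (session time of the buffered
#'   interval start), `epoch_id`, `repeat_id`.
#' @export
extract_ibis <- function(epochs, cfg = extraction_config(),
                         repeat_id = "r01") {
  if (is.null(epochs$speed)) stop("run compute_speed() first")
  buf <- cfg$ibi_buffer / 1000
  out <- list()
  for (ep in unique(epochs$epoch_id)) {
    ix <- which(epochs$epoch_id == ep)
    spans <- .super_spans(epochs$speed[ix], cfg$speed_threshold)
    if (is.null(spans) || nrow(spans) < 2) next
    for (si in seq_len(nrow(spans) - 1L)) {
      t_end <- epochs$time[ix][spans$end[si]]
      t_next <- epochs$time[ix][spans$start[si + 1L]]
      dur <- (t_next - t_end) - 2 * buf
      if (dur <= 0) next
      sel <- ix[epochs$time[ix] >= t_end + buf & epochs$time[ix] <= t_next - buf]
      out[[length(out) + 1L]] <- data.frame(
        duration = dur, mean_pitch = mean(epochs$pitch[sel]),
        bout_frequency = 1 / dur, time = t_end + buf,
        epoch_id = ep, repeat_id = repeat_id)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(duration = numeric(), mean_pitch = numeric(),
               bout_frequency = numeric(), time = numeric(),
               epoch_id = integer(), repeat_id = character())
  class(res) <- c("ibi_records", "data.frame")
  res
}

#' Restrict data to the light phase (zeitgeber day)
#'
#' Keeps records, bouts or IBIs whose wall-clock times fall inside the light
#' phase of the metadata's light schedule. With no schedule present the input
#' is returned unchanged with a warning.
#'
#' @param x a [raw_records()] series, an `aligned_bouts` object, or an
#'   `ibi_records` data.frame.
#' @param metadata a [session_metadata()] with `light_on`, `light_off`
#'   (`"HH:MM"`) and `session_start`.
#' @return the filtered object.
#' @export
filter_daytime <- function(x, metadata) {
  need <- c("light_on", "light_off", "session_start")
  if (!all(need %in% names(metadata)) ||
      any(!nzchar(unlist(metadata[need])))) {
    warning("light schedule absent; returning data unchanged")
    return(x)
  }
  t0 <- as.POSIXct(metadata$session_start, tz = "UTC")
  hm <- function(s) {
    p <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    p[1] * 3600 + p[2] * 60
  }
  on_s <- hm(metadata$light_on); off_s <- hm(metadata$light_off)
  in_day <- function(t_session) {
    tod <- (as.numeric(t0) %% 86400 + t_session) %% 86400
    if (off_s > on_s) tod >= on_s & tod < off_s
    else tod >= on_s | tod < off_s   # schedule wrapping midnight
  }
  if (inherits(x, "aligned_bouts")) {
    keep <- in_day(x$bouts$peak_time)
    kept_ids <- x$bouts$bout_id[keep]
    x$bouts <- x$bouts[keep, , drop = FALSE]
    x$samples <- x$samples[x$samples$bout_id %in% kept_ids, , drop = FALSE]
    x
  } else if (inherits(x, "ibi_records")) {
    x[in_day(x$time), , drop = FALSE]
  } else {
    x[in_day(x$time), , drop = FALSE]
  }
}
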