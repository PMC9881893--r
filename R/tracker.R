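# Frame-level tracking: background estimation, per-frame detection, and
# conversion of a frame stack into raw pose records. Mirrors the acquisition
# algorithm: background subtraction, noise thresholding, rejection of frames
# without exactly one animal, intensity-band separation of head and body,
# and centroid/orientation extraction.

#' Tracker thresholds
#'
#' Intensity bands (on the raw frame, within the foreground mask) that
#' isolate the whole animal (`body_low`..`body_high`) and the brighter head
#' (`head_low`..`head_high`); the initial cut band applied to the absolute
#' background difference; and the pixel-count bounds an animal-sized blob
#' must satisfy.
#'
#' @param body_low,body_high,head_low,head_high,initial_cut_low,initial_cut_high
#'   intensities in [0, 255], low <= high per pair.
#' @param size_low,size_high blob pixel-count bounds.
#' @return list of class `tracker_thresholds`.
#' @export
tracker_thresholds <- function(body_low, body_high, head_low, head_high,
                               initial_cut_low, initial_cut_high,
                               size_low, size_high) {
  v <- c(body_low, body_high, head_low, head_high,
         initial_cut_low, initial_cut_high)
  stopifnot(all(v >= 0 & v <= 255),
            body_low <= body_high, head_low <= head_high,
            initial_cut_low <= initial_cut_high, size_low <= size_high)
  structure(list(body_low = body_low, body_high = body_high,
                 head_low = head_low, head_high = head_high,
                 initial_cut_low = initial_cut_low,
                 initial_cut_high = initial_cut_high,
                 size_low = size_low, size_high = size_high),
            class = "tracker_thresholds")
}

#' Named recording-threshold presets
#'
#' The published recording parameters for each supported organism, verbatim.
#'
#' @param organism `"zebrafish"` (larvae up to 12 dpf), `"zebrafish_old"`
#'   (> 12 dpf), `"fly"`, or `"worm"`.
#' @return a [tracker_thresholds()] object.
#' @export
tracker_preset <- function(organism = c("zebrafish", "zebrafish_old",
                                        "fly", "worm")) {
  organism <- match.arg(organism)
  switch(organism,
    zebrafish = tracker_thresholds(14, 255, 45, 255, 25, 120, 180, 260),
    zebrafish_old = tracker_thresholds(14, 255, 45, 255, 25, 120, 250, 450),
    fly = tracker_thresholds(100, 255, 30, 255, 45, 145, 80, 180),
    worm = tracker_thresholds(20, 255, 21, 255, 3, 30, 30, 80))
}

#' Estimate the static background
#'
#' @param frames list of matrices, or a `frame_sequence`.
#' @param mode `"median"` (per-pixel median over frames) or `"first_n_mean"`
#'   (mean of the first `n`).
#' @param n frames used by `"first_n_mean"`; `"median"` subsamples to at most
#'   `n` evenly spaced frames for speed.
#' @return a background matrix with attribute `"mode"`.
#' @export
estimate_background <- function(frames, mode = c("median", "first_n_mean"),
                                n = 101) {
  mode <- match.arg(mode)
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  if (!length(frames)) stop("no frames given")
  if (mode == "first_n_mean") {
    use <- frames[seq_len(min(n, length(frames)))]
    bg <- Reduce(`+`, use) / length(use)
  } else {
    use <- frames[unique(round(seq(1, length(frames),
                                   length.out = min(n, length(frames)))))]
    if (length(use) == 1) bg <- use[[1]]
    else {
      arr <- vapply(use, as.numeric, numeric(length(use[[1]])))
      bg <- matrix(apply(arr, 1, stats::median), nrow(use[[1]]), ncol(use[[1]]))
    }
  }
  attr(bg, "mode") <- mode
  bg
}

#' Detect the animal in a single frame
#'
#' Foreground = pixels whose absolute difference from the background falls in
#' the initial-cut band; connected components (8-connectivity) below a small
#' noise floor are ignored. Zero animal-scale components gives `no_animal`;
#' more than one gives `multiple_animals`; a single blob with pixel count
#' outside the size bounds gives `size_out_of_range`. Otherwise the blob is
#' split by raw-frame intensity into head (head band) and body (remainder);
#' an empty part gives `parts_not_separable`. Pitch is the elevation of the
#' head-minus-body centroid vector (nose-up positive, heading-invariant);
#' length is the blob's extent along that axis.
#'
#' @param frame,background matrices of equal shape (row 1 at the top).
#' @param thr a [tracker_thresholds()] object.
#' @param noise_floor components at or below this pixel count are noise.
#' @return list of class `detection`: `status`, and for `status == "ok"` the
#'   `body_centroid` and `head_centroid` (c(col, row) px), `pitch` (deg),
#'   `length` (px), `pixel_count`.
#' @export
detect_frame <- function(frame, background, thr, noise_floor = 5) {
  if (!all(dim(frame) == dim(background)))
    stop("frame and background shapes differ")
  fail <- function(status) structure(
    list(status = status, body_centroid = NULL, head_centroid = NULL,
         pitch = NA_real_, length = NA_real_, pixel_count = NA_integer_),
    class = "detection")
  d <- abs(frame - background)
  fg <- d >= thr$initial_cut_low & d <= thr$initial_cut_high
  if (!any(fg)) return(fail("no_animal"))
  lab <- EBImage::bwlabel(fg)
  counts <- tabulate(lab[lab > 0])
  comp <- which(counts > noise_floor)
  if (!length(comp)) return(fail("no_animal"))
  animal_scale <- comp[counts[comp] >= thr$size_low]
  if (length(animal_scale) > 1) return(fail("multiple_animals"))
  main <- if (length(animal_scale) == 1) animal_scale else
    comp[which.max(counts[comp])]
  npx <- counts[main]
  if (npx < thr$size_low || npx > thr$size_high)
    return(fail("size_out_of_range"))
  px <- which(lab == main, arr.ind = TRUE)  # (row, col)
  raw <- frame[lab == main]
  in_head <- raw >= thr$head_low & raw <= thr$head_high
  in_body <- raw >= thr$body_low & raw <= thr$body_high & !in_head
  if (!any(in_head) || !any(in_body)) return(fail("parts_not_separable"))
  hc <- c(mean(px[in_head, 2]), mean(px[in_head, 1]))
  bc <- c(mean(px[in_body, 2]), mean(px[in_body, 1]))
  dx <- hc[1] - bc[1]
  dz <- -(hc[2] - bc[2])                    # rows grow downward
  pitch <- elevation_angle(dx, dz)
  # blob extent along the body axis
  nv <- c(dx, dz) / sqrt(dx^2 + dz^2)
  proj <- px[, 2] * nv[1] + (-px[, 1]) * nv[2]
  structure(list(status = "ok", body_centroid = bc, head_centroid = hc,
                 pitch = pitch, length = diff(range(proj)) + 1,
                 pixel_count = as.integer(npx)),
            class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("detection ok: body (%.1f, %.1f) px, pitch %.1f deg, %d px\n",
                x$body_centroid[1], x$body_centroid[2], x$pitch,
                x$pixel_count))
  else cat("detection:", x$status, "\n")
  invisible(x)
}

#' Track a frame stack into raw pose records
#'
#' Runs [detect_frame()] over a stack, converts pixel coordinates to mm
#' (z increasing upward), and emits one record per frame with an `ok`
#' detection. The epoch id increments whenever a frame fails detection (no
#' animal, multiple animals, size out of range, parts not separable), so
#' consecutive `ok` frames share an epoch.
#'
#' @param frames list of matrices or a `frame_sequence`.
#' @param thr a [tracker_thresholds()] object.
#' @param mm_per_pixel spatial calibration (> 0).
#' @param frame_rate acquisition rate, Hz.
#' @param background optional precomputed background; estimated with the
#'   median mode otherwise.
#' @param noise_floor see [detect_frame()].
#' @return a [raw_records()] data.frame; `attr(, "status")` is the per-frame
#'   status vector. Empty (with a warning) if no frame is `ok`.
#' @export
track_frames <- function(frames, thr, mm_per_pixel, frame_rate = 166,
                         background = NULL, noise_floor = 5) {
  stopifnot(mm_per_pixel > 0, frame_rate > 0)
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  if (!length(frames)) stop("no frames given")
  if (is.null(background)) background <- estimate_background(frames)
  h <- nrow(frames[[1]])
  status <- character(length(frames))
  rows <- vector("list", length(frames))
  epoch <- 1L
  prev_ok <- TRUE
  for (i in seq_along(frames)) {
    det <- detect_frame(frames[[i]], background, thr, noise_floor)
    status[i] <- det$status
    if (det$status != "ok") {
      if (prev_ok && i > 1) epoch <- epoch + 1L
      prev_ok <- FALSE
      next
    }
    prev_ok <- TRUE
    rows[[i]] <- data.frame(
      time = (i - 1) / frame_rate,
      body_x = det$body_centroid[1] * mm_per_pixel,
      body_z = (h - det$body_centroid[2]) * mm_per_pixel,
      head_x = det$head_centroid[1] * mm_per_pixel,
      head_z = (h - det$head_centroid[2]) * mm_per_pixel,
      pitch = det$pitch, epoch_id = epoch,
      length = det$length * mm_per_pixel)
  }
  got <- !vapply(rows, is.null, TRUE)
  if (!any(got)) {
    warning("no frame produced an ok detection")
    out <- raw_records()
  } else {
    df <- do.call(rbind, rows[got])
    out <- raw_records(df$time, df$body_x, df$body_z, df$head_x, df$head_z,
                       df$pitch, df$epoch_id, df$length)
  }
  attr(out, "status") <- status
  out
}
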