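# Grayscale frame rendering: turns a pose trace into the image stacks the
# tracker consumes, with exact per-frame ground truth.

#' Render configuration
#'
#' Geometry and intensity model for synthetic frames: a static noisy
#' background with, per frame, a body ellipse and a brighter head disc
#' positioned and oriented from the pose trace. The head disc is centered
#' inside the front of the ellipse so the two parts form one connected blob.
#'
#' @param image_size c(height, width) in px; 400x400 suits desk-scale tests,
#'   the full acquisition format (1216x1200) is supported.
#' @param mm_per_pixel spatial calibration.
#' @param background_level 8-bit background intensity.
#' @param noise_sd SD of the static background noise (intensity units).
#' @param body_length fish length in mm.
#' @param body_intensity,head_intensity 8-bit paint levels; the head must be
#'   brighter than the body, and the body must clear the background by more
#'   than 3 noise SDs.
#' @param n_animals number of rendered animals (0 = background only; >= 2
#'   renders offset copies to exercise multi-animal rejection).
#' @return list of class `render_config`.
#' @export
render_config <- function(image_size = c(400, 400), mm_per_pixel = 0.05,
                          background_level = 10, noise_sd = 2,
                          body_length = 4, body_intensity = 40,
                          head_intensity = 120, n_animals = 1) {
  stopifnot(length(image_size) == 2, all(image_size > 0), mm_per_pixel > 0,
            body_length > 0, n_animals >= 0)
  if (!(head_intensity > body_intensity &&
        body_intensity > background_level + 3 * noise_sd))
    stop("need head_intensity > body_intensity > background_level + 3*noise_sd")
  structure(list(image_size = as.integer(image_size),
                 mm_per_pixel = mm_per_pixel,
                 background_level = background_level, noise_sd = noise_sd,
                 body_length = body_length,
                 body_intensity = body_intensity,
                 head_intensity = head_intensity,
                 n_animals = as.integer(n_animals)),
            class = "render_config")
}

# Paint one fish; returns masks. Center (cx, rz) in px (col, row), pitch deg.
.fish_masks <- function(h, w, cx, cz_row, pitch, cfg) {
  Lpx <- cfg$body_length / cfg$mm_per_pixel
  a <- Lpx / 2; b <- max(2, Lpx / 10)       # ellipse semi-axes
  rh <- max(2, Lpx / 8)                     # head disc radius
  ch <- a - rh                              # head center offset along axis
  th <- pitch * pi / 180
  # px right = +x, row down = -z
  lim <- ceiling(a + rh + 2)
  c0 <- max(1L, floor(cx - lim)); c1 <- min(w, ceiling(cx + lim))
  r0 <- max(1L, floor(cz_row - lim)); r1 <- min(h, ceiling(cz_row + lim))
  cols <- c0:c1; rows_ <- r0:r1
  dxm <- outer(rep(1, length(rows_)), cols - cx)
  dzm <- outer(-(rows_ - cz_row), rep(1, length(cols)))
  u <- dxm * cos(th) + dzm * sin(th)        # along axis
  v <- -dxm * sin(th) + dzm * cos(th)       # across axis
  ell <- (u / a)^2 + (v / b)^2 <= 1
  head <- (u - ch)^2 + v^2 <= rh^2
  list(rows = rows_, cols = cols, ellipse = ell, head = head)
}

#' Render frames from a pose trace
#'
#' @param trace a [simulate_session()] trace (or any list with `times`, `x`,
#'   `z`, `pitch`).
#' @param cfg a [render_config()].
#' @param seed integer seed for the static background noise.
#' @param frames indices of trace frames to render (default all).
#' @return list of class `frame_sequence`: `frames` (list of integer
#'   matrices, row 1 at the top, intensities 0-255), `background` (the clean
#'   noiseless background is *not* retained; this is the rendered static
#'   background), `ground_truth` (per frame: painted body-pixel centroid
#'   `body_col`/`body_row`, head centroid `head_col`/`head_row`, `pitch`,
#'   trace `x`/`z`, `n_pixels`), and `cfg`.
#' @export
render_frames <- function(trace, cfg = render_config(), seed = 1L,
                          frames = NULL) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  set.seed(as.integer(seed))
  bg <- matrix(pmax(0, pmin(255, round(
    cfg$background_level + stats::rnorm(h * w, 0, cfg$noise_sd)))), h, w)
  idx <- frames %||% seq_along(trace$times)
  # map trace mm coordinates into the frame, centered
  margin <- cfg$body_length / cfg$mm_per_pixel + 4
  if (length(idx) && cfg$n_animals >= 1) {
    xr <- range(trace$x[idx]); zr <- range(trace$z[idx])
    scale <- 1 / cfg$mm_per_pixel
    col_of <- function(x) (x - mean(xr)) * scale + (w + 1) / 2
    row_of <- function(z) (h + 1) / 2 - (z - mean(zr)) * scale
    if (diff(xr) * scale + 2 * margin > w || diff(zr) * scale + 2 * margin > h)
      stop("animal trajectory does not fit in the frame")
  }
  out_frames <- vector("list", length(idx))
  gt <- data.frame(frame = idx, body_col = NA_real_, body_row = NA_real_,
                   head_col = NA_real_, head_row = NA_real_,
                   pitch = NA_real_, x = NA_real_, z = NA_real_,
                   n_pixels = 0L)
  for (j in seq_along(idx)) {
    i <- idx[j]
    img <- bg
    if (cfg$n_animals >= 1) {
      cx <- col_of(trace$x[i]); cz <- row_of(trace$z[i])
      for (k in seq_len(cfg$n_animals)) {
        # extra animals offset by a third of the frame
        ox <- (k - 1) * w / 3
        m <- .fish_masks(h, w, cx + ox, cz, trace$pitch[i], cfg)
        sub <- img[m$rows, m$cols]
        sub[m$ellipse & !m$head] <- cfg$body_intensity
        sub[m$head] <- cfg$head_intensity
        img[m$rows, m$cols] <- sub
        if (k == 1) {
          body_px <- which(m$ellipse & !m$head, arr.ind = TRUE)
          head_px <- which(m$head, arr.ind = TRUE)
          gt$body_col[j] <- mean(m$cols[body_px[, 2]])
          gt$body_row[j] <- mean(m$rows[body_px[, 1]])
          gt$head_col[j] <- mean(m$cols[head_px[, 2]])
          gt$head_row[j] <- mean(m$rows[head_px[, 1]])
          gt$pitch[j] <- trace$pitch[i]
          gt$x[j] <- trace$x[i]; gt$z[j] <- trace$z[i]
          gt$n_pixels[j] <- sum(m$ellipse | m$head)
        }
      }
    }
    out_frames[[j]] <- img
  }
  structure(list(frames = out_frames, background = bg, ground_truth = gt,
                 cfg = cfg, times = trace$times[idx],
                 frame_rate = trace$frame_rate %||% NA_real_),
            class = "frame_sequence")
}

#' Write a frame sequence to numbered TIFF files with a ground-truth sidecar
#'
#' @param fs a [render_frames()] sequence.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly. Requires the `tiff` package.
#' @export
write_frames <- function(fs, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF frames requires the 'tiff' package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(fs$frames))
    tiff::writeTIFF(fs$frames[[j]] / 255,
                    file.path(dir, sprintf("frame_%05d.tif", j)))
  utils::write.csv(fs$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
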