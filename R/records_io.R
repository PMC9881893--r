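# Raw pose-record files and session metadata.
#
# The record dialect mirrors the tab-delimited files the acquisition software
# writes: one row per frame with time stamp, body coordinates, head
# coordinates, pitch angle, epoch number, and fish length. We fix what the
# acquisition side leaves open: tab separator, no header, 6-decimal floats,
# coordinates in mm. Metadata is a key=value text file.

.record_cols <- c("time", "body_x", "body_z", "head_x", "head_z",
                  "pitch", "epoch_id", "length")

#' Construct a raw record series
#'
#' @param time time stamps in seconds (non-decreasing).
#' @param body_x,body_z body centroid in mm (z increases upward).
#' @param head_x,head_z head centroid in mm.
#' @param pitch pitch angle in degrees, nose-up positive.
#' @param epoch_id integer id of the contiguous detection span.
#' @param length fish length in mm.
#' @return data.frame of class `raw_records`.
#' @export
raw_records <- function(time = numeric(), body_x = numeric(),
                        body_z = numeric(), head_x = numeric(),
                        head_z = numeric(), pitch = numeric(),
                        epoch_id = integer(), length = numeric()) {
  out <- data.frame(time = as.numeric(time), body_x = as.numeric(body_x),
                    body_z = as.numeric(body_z), head_x = as.numeric(head_x),
                    head_z = as.numeric(head_z), pitch = as.numeric(pitch),
                    epoch_id = as.integer(epoch_id),
                    length = as.numeric(length))
  if (nrow(out) > 1 && any(diff(out$time) < 0))
    stop("record time stamps must be non-decreasing")
  class(out) <- c("raw_records", "data.frame")
  out
}

#' Write / read raw pose records
#'
#' `write_records()` writes the tab-delimited dialect (no header, one row per
#' frame, 6-decimal floats, column order time, body x/z, head x/z, pitch,
#' epoch, length). `read_records()` is its exact inverse; a row with the
#' wrong number of fields is reported with its line number.
#'
#' @param series a [raw_records()] data.frame.
#' @param path file path.
#' @return `read_records()` returns a `raw_records` data.frame.
#' @export
write_records <- function(series, path) {
  stopifnot(inherits(series, "data.frame"),
            all(.record_cols %in% names(series)))
  if (nrow(series) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  lines <- sprintf("%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%d\t%.6f",
                   series$time, series$body_x, series$body_z,
                   series$head_x, series$head_z, series$pitch,
                   as.integer(series$epoch_id), series$length)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such records file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(raw_records())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 8L)
  if (length(bad))
    stop("malformed record row at line ", bad[1], ": expected 8 fields, got ",
         nf[bad[1]])
  m <- matrix(as.numeric(unlist(fields)), ncol = 8, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in records file ", path)
  raw_records(time = m[, 1], body_x = m[, 2], body_z = m[, 3],
              head_x = m[, 4], head_z = m[, 5], pitch = m[, 6],
              epoch_id = as.integer(m[, 7]), length = m[, 8])
}

#' Session metadata
#'
#' Builds the metadata object that accompanies a record file: acquisition
#' frame rate, spatial calibration, light schedule (zeitgeber times), session
#' start, chamber type and repeat id. Extra named fields are preserved.
#'
#' @param frame_rate acquisition rate in Hz (required, > 0).
#' @param mm_per_pixel spatial calibration.
#' @param light_on,light_off clock times `"HH:MM"` delimiting the light phase.
#' @param session_start `"YYYY-MM-DD HH:MM:SS"` wall-clock start.
#' @param chamber_type `"standard"` or `"narrow"`.
#' @param repeat_id identifier of the experimental repeat.
#' @param ... further fields, kept verbatim.
#' @return list of class `session_metadata`.
#' @export
session_metadata <- function(frame_rate = 166, mm_per_pixel = 0.05,
                             light_on = "09:00", light_off = "23:00",
                             session_start = "2026-01-01 09:00:00",
                             chamber_type = c("standard", "narrow"),
                             repeat_id = "r01", ...) {
  chamber_type <- match.arg(chamber_type)
  stopifnot(is.numeric(frame_rate), frame_rate > 0)
  structure(c(list(frame_rate = frame_rate, mm_per_pixel = mm_per_pixel,
                   light_on = light_on, light_off = light_off,
                   session_start = session_start,
                   chamber_type = chamber_type, repeat_id = repeat_id),
              list(...)),
            class = "session_metadata")
}

#' Write / read session metadata
#'
#' Plain `key=value` text, one pair per line. Unknown keys survive a
#' round trip. `read_metadata()` fails if the required `frame_rate` key is
#' absent.
#'
#' @param meta a [session_metadata()] object (or plain named list).
#' @param path file path.
#' @export
write_metadata <- function(meta, path) {
  vals <- vapply(meta, function(v) as.character(v)[1], character(1))
  writeLines(paste0(names(meta), "=", vals), path)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such metadata file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  if (any(lengths(kv) != 2))
    stop("malformed metadata line: ", lines[which(lengths(kv) != 2)[1]])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  if (!"frame_rate" %in% keys)
    stop("metadata is missing required key 'frame_rate'")
  out <- as.list(vals)
  names(out) <- keys
  for (k in c("frame_rate", "mm_per_pixel"))
    if (k %in% keys) out[[k]] <- as.numeric(out[[k]])
  structure(out, class = "session_metadata")
}
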