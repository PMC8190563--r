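#' Write and read frame streams as PNG directories
#'
#' One 8-bit grey PNG per frame, named `frame_000000.png` by frame index
#' (no TIFF library is available in this toolchain, so the stack-on-disk
#' container is a single-frame PNG directory, which the readers of this
#' package and common imaging tools both accept).
#'
#' @param frames List of `pccr_frame`s.
#' @param dir Output directory (created if needed).
#' @return `write_frames()` the directory, invisibly; `read_frames()` a
#'   list of `pccr_frame`s.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in frames) {
    png::writePNG(f$pixels / 255,
                  file.path(dir, sprintf("frame_%06d.png", f$frame_index)))
  }
  invisible(dir)
}

#' @param camera_id Camera label attached to the frames read.
#' @param frame_rate Sampling rate used to reconstruct `time_s`.
#' @rdname write_frames
#' @export
read_frames <- function(dir, camera_id = "left", frame_rate = 395) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG frames found in ", dir)
  lapply(seq_along(files), function(i) {
    a <- png::readPNG(files[i])
    if (length(dim(a)) == 3L) a <- a[, , 1] # grey stored in channel 1
    pix <- round(a * 255)
    storage.mode(pix) <- "integer"
    structure(list(pixels = pix, camera_id = camera_id,
                   frame_index = i - 1L, time_s = (i - 1L) / frame_rate,
                   out_of_bounds = FALSE),
              class = "pccr_frame")
  })
}

#' Write and read the simulator truth log
#'
#' Long-format CSV with one row per frame and eye: `frame_index`, `time_s`,
#' `eye`, `gaze_h_deg`, `gaze_v_deg`, `pupil_mm`, `vergence_deg`, `blink`
#' (header row, UTF-8, '.' decimal).
#'
#' @param truth Truth table from [protocol_truth()].
#' @param path CSV path.
#' @return `write_truth()` the path invisibly; `read_truth()` a data.frame.
#' @export
write_truth <- function(truth, path) {
  long <- rbind(
    data.frame(frame_index = truth$frame_index, time_s = truth$time_s,
               eye = "left", gaze_h_deg = truth$gaze_h_left,
               gaze_v_deg = truth$gaze_v_left, pupil_mm = truth$pupil_mm,
               vergence_deg = truth$vergence_deg, blink = as.integer(truth$blink)),
    data.frame(frame_index = truth$frame_index, time_s = truth$time_s,
               eye = "right", gaze_h_deg = truth$gaze_h_right,
               gaze_v_deg = truth$gaze_v_right, pupil_mm = truth$pupil_mm,
               vergence_deg = truth$vergence_deg, blink = as.integer(truth$blink))
  )
  long <- long[order(long$frame_index, long$eye), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) utils::read.csv(path)

#' Write a detection table
#'
#' Column order: `frame_index`, `time_s`, `camera_id`, `pupil_x`,
#' `pupil_y`, `pupil_area`, `pupil_mm`, `cr_x`, `cr_y`, `cr_area`,
#' `valid` (plus the PC-CR components `dx`, `dy`).
#'
#' @param det Detection table (see [detect_stream()]).
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_detections <- function(det, path) {
  cols <- c("frame_index", "time_s", "camera_id", "pupil_x", "pupil_y",
            "pupil_area", "pupil_mm", "cr_x", "cr_y", "cr_area",
            "dx", "dy", "valid")
  utils::write.csv(det[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) utils::read.csv(path)

recording_data_cols <- c("pupil_left_mm", "pupil_right_mm", "x_left_px",
                         "x_right_px", "vergence_raw_arcmin",
                         "vergence_corrected_arcmin")
recording_cols <- c("computer_time", "frame_number", recording_data_cols,
                    "target_x", "target_y", "ttl", "blink")

#' Write a gaze recording file
#'
#' The per-frame recording: computer time (s since session start), frame
#' number, pupil sizes for left and right eye (mm), horizontal eye
#' positions in screen coordinates (pixels from the screen center),
#' vergence in arcmin without and with pupil-decentration correction,
#' target x/y, and a TTL column that is 1 only on frames where a new target
#' appeared. On blink rows all data columns are written as zeros; a `blink`
#' flag column keeps those rows distinguishable from true zeros. Comma
#' separated, '.' decimal, UTF-8.
#'
#' @param samples data.frame with the columns listed above (`blink`
#'   logical/0-1; data columns are zeroed by the writer on blink rows).
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_recording <- function(samples, path) {
  missing_cols <- setdiff(recording_cols, names(samples))
  if (length(missing_cols)) {
    stop("recording lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  fn <- samples$frame_number
  if (any(diff(fn) <= 0)) stop("frame_number must be strictly increasing")
  if (!all(samples$ttl %in% c(0, 1))) stop("ttl must be 0 or 1")
  out <- samples[, recording_cols]
  out$blink <- as.integer(as.logical(out$blink))
  for (cl in recording_data_cols) {
    cl_v <- out[[cl]]
    cl_v[out$blink == 1L | is.na(cl_v)] <- 0
    out[[cl]] <- signif(cl_v, 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gaze recording file
#'
#' Validates the documented header and row invariants (strictly increasing
#' frame numbers, TTL in {0, 1}), reporting the offending line number.
#' Zeroed blink rows come back flagged via the `blink` column.
#'
#' @param path CSV path written by [write_recording()].
#' @return data.frame with the recording columns (`blink` logical).
#' @export
read_recording <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(hdr, recording_cols)) {
    stop("malformed recording header (line 1): expected ",
         paste(recording_cols, collapse = ","))
  }
  rec <- utils::read.csv(path)
  if (nrow(rec) == 0L) { rec$blink <- logical(0); return(rec) }
  bad <- which(!rec$ttl %in% c(0, 1))
  if (length(bad)) stop(sprintf("invalid ttl value at line %d", bad[1] + 1L))
  bad <- which(diff(rec$frame_number) <= 0)
  if (length(bad)) stop(sprintf("frame_number not strictly increasing at line %d", bad[1] + 2L))
  rec$blink <- as.logical(rec$blink)
  rec
}

#' Write and read a calibration report
#'
#' JSON document with, per eye, the target positions, the stored mean
#' PC-CR vectors, the affine model coefficients, and the corner residuals.
#'
#' @param calib A `pccr_calibration_binocular` (see [calibrate_eyes()]).
#' @param path JSON path.
#' @return `write_calibration()` the path invisibly; `read_calibration()` a
#'   `pccr_calibration_binocular`.
#' @export
write_calibration <- function(calib, path) {
  enc <- function(m) list(gain = unclass(m$gain), offset = unname(m$offset),
                          residuals_deg = unclass(m$residuals_deg),
                          points = m$points)
  jsonlite::write_json(list(left = enc(calib$left), right = enc(calib$right)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::fromJSON(path)
  dec <- function(m) structure(list(gain = matrix(unlist(m$gain), 2, 2),
                                    offset = as.numeric(m$offset),
                                    residuals_deg = matrix(unlist(m$residuals_deg), ncol = 2,
                                                           dimnames = list(NULL, c("h", "v"))),
                                    points = as.data.frame(m$points)),
                               class = "pccr_calibration")
  structure(list(left = dec(j$left), right = dec(j$right), targets = NULL),
            class = "pccr_calibration_binocular")
}
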