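#' Stimulus protocols
#'
#' A protocol is an ordered list of segments. Each segment presents exactly
#' one fixation target for a fixed number of frames: either a point on the
#' screen (`target_x_px`/`target_y_px`, pixel offsets from the screen center,
#' x rightward and y downward) or a midline target at a physical distance
#' (`target_distance_mm`), which drives symmetric convergence of the two
#' eyes. `screen_grey` sets the background luminance that drives the pupil
#' light response; `blink_at` lists frame offsets (0-based, within the
#' segment) at which a blink (eyelid sweep) starts.
#'
#' @param duration_frames Positive integer, segment length in frames.
#' @param target_x_px,target_y_px Screen target, pixels from screen center.
#' @param target_distance_mm Midline depth target, mm from the eyes
#'   (mutually exclusive with a screen target).
#' @param screen_grey Screen background grey level 0-255 (default 0, black).
#' @param blink_at Integer vector of blink onsets within the segment.
#' @param label Optional segment label.
#' @return `protocol_segment()` returns a segment; `protocol()` an object of
#'   class `pccr_protocol`.
#' @examples
#' p <- protocol(
#'   protocol_segment(200, target_x_px = 0, target_y_px = 0),
#'   protocol_segment(200, target_distance_mm = 290)
#' )
#' @export
protocol_segment <- function(duration_frames,
                             target_x_px = 0, target_y_px = 0,
                             target_distance_mm = NULL,
                             screen_grey = 0,
                             blink_at = integer(0),
                             label = NULL) {
  duration_frames <- as.integer(duration_frames)
  if (length(duration_frames) != 1L || is.na(duration_frames) || duration_frames <= 0L) {
    stop("duration_frames must be a positive integer")
  }
  if (!is.null(target_distance_mm)) {
    if (target_distance_mm <= 0) stop("target_distance_mm must be positive")
    if (!missing(target_x_px) || !missing(target_y_px)) {
      stop("a segment has exactly one active target: screen or depth, not both")
    }
  }
  stopifnot(screen_grey >= 0, screen_grey <= 255)
  structure(list(duration_frames = duration_frames,
                 target_x_px = target_x_px, target_y_px = target_y_px,
                 target_distance_mm = target_distance_mm,
                 screen_grey = screen_grey,
                 blink_at = as.integer(blink_at),
                 label = label),
            class = "pccr_segment")
}

#' @param ... Segments created by [protocol_segment()] (or a single list of
#'   them).
#' @rdname protocol_segment
#' @export
protocol <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && !inherits(segs[[1]], "pccr_segment")) segs <- segs[[1]]
  if (length(segs) == 0L) stop("protocol must contain at least one segment")
  ok <- vapply(segs, inherits, logical(1), "pccr_segment")
  if (!all(ok)) stop("all protocol elements must be protocol_segment()s")
  structure(segs, class = "pccr_protocol")
}

#' @export
print.pccr_protocol <- function(x, ...) {
  cat(sprintf("<pccr_protocol> %d segments, %d frames total\n",
              length(x), sum(vapply(x, `[[`, integer(1), "duration_frames"))))
  invisible(x)
}

#' Convert between screen pixels and visual degrees
#'
#' Screen-referenced ("cyclopean") angles: `atan(offset / screen_distance)`
#' with the offset measured from the screen center in mm
#' (`pixels * screen_pitch`). Vertical angles are positive upward while
#' screen y pixels run downward, hence the sign flip in the vertical
#' direction handled by the callers.
#'
#' @param px Pixel offset from the screen center (vectorised).
#' @param deg Angle in degrees (vectorised).
#' @param cfg An [optical_config()].
#' @return Degrees, or pixels.
#' @export
screen_px_to_deg <- function(px, cfg) rad2deg(atan(px * cfg$screen_pitch / cfg$screen_distance))

#' @rdname screen_px_to_deg
#' @export
screen_deg_to_px <- function(deg, cfg) tan(deg2rad(deg)) * cfg$screen_distance / cfg$screen_pitch

#' Four-point calibration protocol
#'
#' Four fixation points at the corners of a rectangle centred on the screen,
#' presented one after the other, as used by the automated calibration.
#'
#' @param cfg An [optical_config()].
#' @param half_width_deg,half_height_deg Half extent of the calibration
#'   rectangle in degrees (default 4).
#' @param frames_per_point Frames per corner (default 200; must comfortably
#'   exceed trigger window + 100 averaged samples).
#' @param screen_grey Background grey during calibration (default 0).
#' @return A `pccr_protocol` of four segments (order: top-left, top-right,
#'   bottom-right, bottom-left).
#' @export
calibration_protocol <- function(cfg, half_width_deg = 4, half_height_deg = 4,
                                 frames_per_point = 200L, screen_grey = 0) {
  x <- screen_deg_to_px(half_width_deg, cfg)
  y <- screen_deg_to_px(half_height_deg, cfg) # +v deg is up = -y px
  corners <- list(c(-x, -y), c(x, -y), c(x, y), c(-x, y))
  protocol(lapply(corners, function(co) {
    protocol_segment(frames_per_point, target_x_px = co[1], target_y_px = co[2],
                     screen_grey = screen_grey, label = "calibration")
  }))
}

#' Light-step protocol for pupil-artifact assessment
#'
#' A central fixation point on a black background (the pupil dilates),
#' followed by a brief bright screen (grey level 150 for 30 frames, about
#' 75 ms at 395 Hz) that elicits a pupil constriction, followed by darkness
#' again. The artifact regression uses samples from the step onset until
#' 600 ms after its offset (see [assess_pupil_artifact()]).
#'
#' @param cfg An [optical_config()].
#' @param dark_frames Frames of dark fixation before the step (default
#'   4 s worth).
#' @param step_frames Duration of the bright step (default 30 frames).
#' @param step_grey Grey level of the bright step (default 150).
#' @param post_frames Frames after the step (default 2 s worth, covering the
#'   600 ms regression window plus re-dilation).
#' @return A `pccr_protocol` of three central-fixation segments.
#' @export
light_step_protocol <- function(cfg,
                                dark_frames = round(4 * cfg$frame_rate),
                                step_frames = 30L,
                                step_grey = 150,
                                post_frames = round(2 * cfg$frame_rate)) {
  protocol(
    protocol_segment(dark_frames, 0, 0, screen_grey = 0, label = "dark"),
    protocol_segment(step_frames, 0, 0, screen_grey = step_grey, label = "light_step"),
    protocol_segment(post_frames, 0, 0, screen_grey = 0, label = "post")
  )
}

# --- protocol (de)serialisation -------------------------------------------

#' Read and write protocols as JSON
#'
#' The on-disk form is a JSON array of segment objects with keys
#' `duration_frames`, `target_x_px`/`target_y_px` or `target_distance_mm`,
#' `screen_grey`, `blink_at`, `label`.
#'
#' @param path File path.
#' @param protocol A `pccr_protocol`.
#' @return `read_protocol()` returns a `pccr_protocol`; `write_protocol()`
#'   the path, invisibly.
#' @export
read_protocol <- function(path) {
  segs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  protocol(lapply(segs, function(s) {
    blink <- s$blink_at %||% s$blink %||% integer(0) # "blink" accepted as alias
    if (!is.null(s$target_distance_mm)) {
      protocol_segment(s$duration_frames,
                       target_distance_mm = s$target_distance_mm,
                       screen_grey = s$screen_grey %||% 0,
                       blink_at = blink,
                       label = s$label)
    } else {
      protocol_segment(s$duration_frames,
                       target_x_px = s$target_x_px %||% 0,
                       target_y_px = s$target_y_px %||% 0,
                       screen_grey = s$screen_grey %||% 0,
                       blink_at = blink,
                       label = s$label)
    }
  }))
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  segs <- lapply(protocol, function(s) s[!vapply(s, is.null, logical(1))])
  jsonlite::write_json(segs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
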