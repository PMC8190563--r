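#' Fixation-stability trigger
#'
#' The calibration routine stores samples only once fixation is stable:
#' the running standard deviation of the last `window` PC-CR samples,
#' converted to degrees through the nominal per-pixel angle
#' ([arcmin_per_pixel()], about 18.1 arcmin/px at default optics — no
#' calibration exists yet at this point), must fall below `threshold_deg`
#' in both components. A window containing invalid samples never triggers.
#'
#' @param dx,dy The last `window` PC-CR samples, pixels.
#' @param cfg An [optical_config()].
#' @param threshold_deg Stability threshold, degrees (default 0.5).
#' @param window Required window length (default 25).
#' @return TRUE when fixation is stable.
#' @export
fixation_trigger <- function(dx, dy, cfg = optical_config(),
                             threshold_deg = 0.5, window = 25L) {
  if (length(dx) < window || length(dy) < window) {
    stop(sprintf("trigger window needs at least %d samples", window))
  }
  dx <- utils::tail(dx, window); dy <- utils::tail(dy, window)
  if (anyNA(dx) || anyNA(dy)) return(FALSE)
  deg_per_px <- arcmin_per_pixel(cfg) / 60
  stats::sd(dx) * deg_per_px < threshold_deg &&
    stats::sd(dy) * deg_per_px < threshold_deg
}

#' Acquire one calibration point from a sample stream
#'
#' Scans the per-frame PC-CR samples of one eye for the first
#' [fixation_trigger()] window, then averages the next `n_avg` (default
#' 100) consecutive valid samples. Errors (naming the point) if no stable,
#' fully valid stretch exists before `timeout` samples.
#'
#' @param samples data.frame with columns `dx`, `dy`, `valid` (one fixation
#'   segment of the calibration protocol).
#' @param target Named numeric `c(h=, v=)`, the target's screen-referenced
#'   position in degrees.
#' @param cfg An [optical_config()].
#' @param n_avg Samples averaged after the trigger (default 100).
#' @param window Trigger window (default 25).
#' @param timeout Maximum samples scanned (default all supplied).
#' @param label Point name used in error messages.
#' @return A `CalibrationPoint`: list `target`, `mean_dx`, `mean_dy`,
#'   `n_samples`, `trigger_index`.
#' @export
acquire_point <- function(samples, target, cfg = optical_config(),
                          n_avg = 100L, window = 25L,
                          timeout = nrow(samples), label = "point") {
  dx <- samples$dx; dy <- samples$dy
  dx[!samples$valid] <- NA_real_; dy[!samples$valid] <- NA_real_
  n <- min(length(dx), timeout)
  i <- window
  while (i + n_avg <= n) {
    w <- (i - window + 1L):i
    if (!anyNA(dx[w]) && fixation_trigger(dx[w], dy[w], cfg, window = window)) {
      avg <- (i + 1L):(i + n_avg)
      if (!anyNA(dx[avg])) {
        return(list(target = c(h = unname(target["h"]), v = unname(target["v"])),
                    mean_dx = mean(dx[avg]), mean_dy = mean(dy[avg]),
                    n_samples = n_avg, trigger_index = i))
      }
    }
    i <- i + 1L
  }
  stop(sprintf("calibration %s: fixation never stabilised within %d samples", label, n))
}

#' Fit the per-eye linear calibration
#'
#' Least-squares affine map (6 parameters: 2x2 gain matrix plus offset)
#' from the stored mean PC-CR vectors to the target gaze positions in
#' degrees. Four points over-determine the map (8 observations); the fit is
#' exact when the PC-CR-to-gaze relation is truly affine. The model is
#' defined on the whole plane, so any eye position within (or beyond) the
#' calibration rectangle is inferred by linear extrapolation.
#'
#' @param points List of 4 `CalibrationPoint`s for one eye (see
#'   [acquire_point()]).
#' @return A `pccr_calibration`: `gain` (2x2), `offset` (length 2),
#'   `residuals_deg` (4x2), `points`.
#' @export
fit_calibration <- function(points) {
  if (length(points) < 4L) stop("calibration needs 4 points")
  dx <- vapply(points, `[[`, numeric(1), "mean_dx")
  dy <- vapply(points, `[[`, numeric(1), "mean_dy")
  th <- vapply(points, function(p) p$target[["h"]], numeric(1))
  tv <- vapply(points, function(p) p$target[["v"]], numeric(1))
  X <- cbind(1, dx, dy)
  if (qr(X)$rank < 3L) stop("calibration targets/PC-CR vectors are collinear or duplicated")
  beta <- qr.solve(X, cbind(th, tv)) # 3 x 2
  fitted <- X %*% beta
  gain <- t(beta[2:3, , drop = FALSE]) # rows: (h, v), cols: (dx, dy)
  dimnames(gain) <- list(c("h", "v"), c("dx", "dy"))
  structure(list(
    gain = gain,
    offset = c(h = unname(beta[1, 1]), v = unname(beta[1, 2])),
    residuals_deg = cbind(h = th - fitted[, 1], v = tv - fitted[, 2]),
    points = data.frame(target_h = th, target_v = tv, mean_dx = dx, mean_dy = dy)
  ), class = "pccr_calibration")
}

#' @export
print.pccr_calibration <- function(x, ...) {
  cat("<pccr_calibration>\n  gain (deg/px):\n")
  print(round(x$gain, 4))
  cat(sprintf("  offset: (%.3f, %.3f) deg; max |residual| %.4f deg\n",
              x$offset[1], x$offset[2], max(abs(x$residuals_deg))))
  invisible(x)
}

#' Map PC-CR vectors to gaze positions
#'
#' Applies the fitted affine model; linear, continuous, and defined outside
#' the calibration rectangle (extrapolation). Invalid samples (NA) stay NA.
#'
#' @param model A `pccr_calibration`.
#' @param dx,dy PC-CR vector components, pixels (vectorised).
#' @return data.frame with `gaze_h`, `gaze_v` in degrees.
#' @export
map_gaze <- function(model, dx, dy) {
  stopifnot(inherits(model, "pccr_calibration"))
  data.frame(
    gaze_h = as.numeric(model$offset[1] + model$gain[1, 1] * dx + model$gain[1, 2] * dy),
    gaze_v = as.numeric(model$offset[2] + model$gain[2, 1] * dx + model$gain[2, 2] * dy)
  )
}

#' Binocular vergence from calibrated gaze
#'
#' Both eyes are calibrated against the same screen-referenced target
#' angles, so when both fixate a screen point their calibrated horizontal
#' positions agree and the difference `left - right` is zero. The absolute
#' vergence is anchored by adding the geometric vergence of the calibration
#' screen ([vergence_from_distance()] at `screen_distance`): fixation on
#' the screen then reads the true binocular angle (6.360 deg at 540 mm with
#' 60 mm IPD), and nearer fixation reads larger (convergence positive).
#'
#' @param left_gaze_h,right_gaze_h Calibrated horizontal gaze, degrees
#'   (vectorised). NA (blink/invalid) propagates.
#' @param cfg An [optical_config()] (screen distance and IPD).
#' @param units `"arcmin"` (default) or `"deg"`.
#' @return Vergence angle(s).
#' @export
compute_vergence <- function(left_gaze_h, right_gaze_h, cfg = optical_config(),
                             units = c("arcmin", "deg")) {
  units <- match.arg(units)
  v <- (left_gaze_h - right_gaze_h) + vergence_from_distance(cfg$screen_distance, cfg)
  if (units == "arcmin") v * 60 else v
}

#' Run the automated 4-point calibration on detection streams
#'
#' Both eyes are calibrated simultaneously but independently: the target
#' timeline is shared, the models are per eye.
#'
#' @param det_left,det_right Detection tables (see [detect_stream()])
#'   covering the calibration protocol.
#' @param targets data.frame with one row per calibration segment:
#'   `frame_start`, `frame_end` (0-based, inclusive), `target_h`,
#'   `target_v` (degrees). See [calibration_targets()].
#' @param cfg An [optical_config()].
#' @inheritParams acquire_point
#' @return A `pccr_calibration_binocular`: list `left`, `right` (each a
#'   `pccr_calibration`), `targets`.
#' @export
calibrate_eyes <- function(det_left, det_right, targets, cfg = optical_config(),
                           n_avg = 100L, window = 25L) {
  one_eye <- function(det, eye) {
    pts <- lapply(seq_len(nrow(targets)), function(i) {
      seg <- det[det$frame_index >= targets$frame_start[i] &
                   det$frame_index <= targets$frame_end[i], ]
      acquire_point(seg, c(h = targets$target_h[i], v = targets$target_v[i]),
                    cfg, n_avg = n_avg, window = window,
                    label = sprintf("%s point %d", eye, i))
    })
    fit_calibration(pts)
  }
  structure(list(left = one_eye(det_left, "left"),
                 right = one_eye(det_right, "right"),
                 targets = targets),
            class = "pccr_calibration_binocular")
}

#' Calibration target schedule of a protocol
#'
#' Extracts, for each segment of a protocol (by default those labelled
#' "calibration"), the frame range and the screen-referenced target angles,
#' in the form [calibrate_eyes()] consumes.
#'
#' @param protocol A `pccr_protocol`.
#' @param cfg An [optical_config()].
#' @param labels Segment labels to keep (NULL = all segments).
#' @return data.frame `segment`, `frame_start`, `frame_end`, `target_h`,
#'   `target_v`.
#' @export
calibration_targets <- function(protocol, cfg, labels = "calibration") {
  durs <- vapply(protocol, `[[`, integer(1), "duration_frames")
  start <- c(0L, cumsum(durs))[seq_along(protocol)]
  keep <- if (is.null(labels)) seq_along(protocol) else {
    which(vapply(protocol, function(s) identical(s$label, labels), logical(1)))
  }
  tgt <- t(vapply(protocol[keep], segment_target_deg, numeric(2), cfg = cfg))
  data.frame(segment = keep,
             frame_start = start[keep], frame_end = start[keep] + durs[keep] - 1L,
             target_h = tgt[, "h"], target_v = tgt[, "v"])
}
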