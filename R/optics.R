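#' Optical configuration of the tracker and model eye
#'
#' Bundles the optical geometry shared by the simulator and the analysis
#' stages: video magnification, the Hirschberg ratio relating eye rotation to
#' the displacement of the first Purkinje image relative to the pupil center,
#' frame geometry, grey levels of the rendered eye regions, sensor noise, and
#' the binocular viewing geometry (interpupillary distance, screen distance).
#'
#' Coordinate conventions used throughout the package: pixel coordinates are
#' 0-based with x rightward and y downward; gaze angles are in degrees with
#' positive horizontal = rightward and positive vertical = upward; vergence is
#' positive for convergence.
#'
#' @param magnification Video magnification, pixels per mm (default 39.7,
#'   i.e. 25.2 microns per pixel).
#' @param hirschberg_ratio Degrees of eye rotation per mm of displacement of
#'   the first Purkinje image relative to the pupil center (default 12).
#' @param frame_width,frame_height Frame size in pixels (default 640 x 480).
#' @param frame_rate Sampling rate in Hz (default 395).
#' @param pupil_grey Grey level of the rendered pupil disc (default 20).
#' @param background_grey Grey level of iris/sclera/eyelid (default 120).
#' @param cr_grey Grey level of the corneal-reflection blob; must exceed the
#'   fixed detection threshold of 250 (default 255, i.e. saturated).
#' @param cr_diameter Diameter of the rendered corneal reflection, mm
#'   (default 0.59 mm, about 400 above-threshold pixels at 39.7 px/mm).
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise in
#'   grey levels (default 20; calibrated so that the per-frame standard
#'   deviation of the detected PC-CR vector falls in 0.2-0.5 px).
#' @param ipd Interpupillary distance, mm (default 60).
#' @param screen_distance Eye-to-screen distance, mm (default 540).
#' @param screen_pitch Screen pixel pitch, mm per pixel (default 0.282).
#' @param pupil_travel Image-plane travel of the pupil center per degree of
#'   eye rotation, mm/deg (default 0.175; the Purkinje image travels
#'   `pupil_travel - 1/hirschberg_ratio` so that the PC-CR vector grows by
#'   1/hirschberg_ratio mm per degree).
#' @param pupil_baseline,pupil_constricted Pupil diameters (mm) in darkness
#'   and under the bright light step (defaults 6 and 4).
#' @param pupil_latency,pupil_tau Latency (s) and time constant (s) of the
#'   first-order pupil light response (defaults 0.25 and 0.4).
#' @param artifact_coefficient Pupil-decentration artifact strength, mm of
#'   pupil-center shift per mm of pupil-diameter change (default 0.02),
#'   applied with opposite sign in the two eyes (see
#'   [simulate_protocol()]).
#' @param artifact_reference Pupil diameter (mm) at which the decentration is
#'   zero (default 4).
#' @param artifact_eyes Which eyes carry the decentration artifact:
#'   `"both"` (mirrored), `"left"`, `"right"`, or `"none"`.
#' @param saccade_frames Duration of the minimum-jerk gaze transition between
#'   fixation targets, frames (default 12, about 30 ms at 395 Hz).
#' @param blink_frames Frames for the descending and the ascending eyelid
#'   sweep of a simulated blink (default 40 each).
#'
#' @return An object of class `pccr_config` (a validated list).
#' @examples
#' cfg <- optical_config()
#' microns_per_pixel(cfg)   # 25.2 um at 39.7 px/mm
#' arcmin_per_pixel(cfg)    # about 18.1 arcmin
#' @export
optical_config <- function(magnification = 39.7,
                           hirschberg_ratio = 12,
                           frame_width = 640L,
                           frame_height = 480L,
                           frame_rate = 395,
                           pupil_grey = 20,
                           background_grey = 120,
                           cr_grey = 255,
                           cr_diameter = 0.59,
                           noise_sd = 20,
                           ipd = 60,
                           screen_distance = 540,
                           screen_pitch = 0.282,
                           pupil_travel = 0.175,
                           pupil_baseline = 6,
                           pupil_constricted = 4,
                           pupil_latency = 0.25,
                           pupil_tau = 0.4,
                           artifact_coefficient = 0.02,
                           artifact_reference = 4,
                           artifact_eyes = c("both", "left", "right", "none"),
                           saccade_frames = 12L,
                           blink_frames = 40L) {
  artifact_eyes <- match.arg(artifact_eyes)
  cfg <- list(
    magnification = magnification, hirschberg_ratio = hirschberg_ratio,
    frame_width = as.integer(frame_width), frame_height = as.integer(frame_height),
    frame_rate = frame_rate,
    pupil_grey = pupil_grey, background_grey = background_grey,
    cr_grey = cr_grey, cr_diameter = cr_diameter, noise_sd = noise_sd,
    ipd = ipd, screen_distance = screen_distance, screen_pitch = screen_pitch,
    pupil_travel = pupil_travel,
    pupil_baseline = pupil_baseline, pupil_constricted = pupil_constricted,
    pupil_latency = pupil_latency, pupil_tau = pupil_tau,
    artifact_coefficient = artifact_coefficient,
    artifact_reference = artifact_reference, artifact_eyes = artifact_eyes,
    saccade_frames = as.integer(saccade_frames),
    blink_frames = as.integer(blink_frames)
  )
  validate_config(cfg)
  structure(cfg, class = "pccr_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$magnification > 0, cfg$frame_rate > 0, cfg$ipd > 0,
    cfg$hirschberg_ratio > 0, cfg$screen_distance > 0,
    cfg$frame_width > 0, cfg$frame_height > 0,
    cfg$cr_diameter > 0, cfg$noise_sd >= 0,
    cfg$pupil_baseline > cfg$pupil_constricted,
    cfg$pupil_constricted > 0, cfg$pupil_tau > 0, cfg$pupil_latency >= 0
  )
  # the three grey regions must be separable by the detector thresholds
  if (!(cfg$cr_grey > 250 && 250 > cfg$background_grey &&
        cfg$background_grey > cfg$pupil_grey && cfg$pupil_grey >= 0)) {
    stop("grey levels must satisfy cr_grey > 250 > background_grey > pupil_grey >= 0")
  }
  invisible(cfg)
}

#' @export
print.pccr_config <- function(x, ...) {
  cat("<pccr_config>\n")
  cat(sprintf("  %g px/mm (%.1f um/px), Hirschberg %g deg/mm, %d x %d @ %g Hz\n",
              x$magnification, microns_per_pixel(x), x$hirschberg_ratio,
              x$frame_width, x$frame_height, x$frame_rate))
  cat(sprintf("  1 px = %.2f arcmin; ipd %g mm, screen %g mm; noise sd %g\n",
              arcmin_per_pixel(x), x$ipd, x$screen_distance, x$noise_sd))
  invisible(x)
}

#' Unit conversions of the optical geometry
#'
#' `microns_per_pixel()` is the inverse magnification (1000/magnification).
#' `arcmin_per_pixel()` is the nominal angular value of one pixel of PC-CR
#' displacement, obtained through the Hirschberg ratio
#' (`hirschberg_ratio / magnification * 60`); about 18.1 arcmin at the
#' default optics, so a detection resolution of 0.2 px corresponds to about
#' 3.6 arcmin.
#'
#' @param cfg An [optical_config()].
#' @return A scalar, microns or arcminutes per pixel.
#' @export
microns_per_pixel <- function(cfg) 1000 / cfg$magnification

#' @rdname microns_per_pixel
#' @export
arcmin_per_pixel <- function(cfg) cfg$hirschberg_ratio / cfg$magnification * 60

#' Binocular vergence angle of a target at a given distance
#'
#' The full angle between the two lines of sight when both eyes fixate a
#' point on the midline at `distance`: `2 * atan((ipd/2) / distance)`,
#' in degrees. Strictly decreasing in distance and approaching zero
#' (parallel gaze) at infinity. At the default 60 mm interpupillary distance
#' this gives 6.360 deg at 540 mm and 11.812 deg at 290 mm.
#'
#' @param distance Target distance from the eyes, mm. Vectorised.
#' @param cfg An [optical_config()] supplying `ipd`.
#' @return Vergence angle(s) in degrees.
#' @examples
#' cfg <- optical_config()
#' vergence_from_distance(c(540, 490, 440, 290), cfg)
#' @export
vergence_from_distance <- function(distance, cfg = optical_config()) {
  if (any(!is.finite(distance) & !is.infinite(distance)) || any(distance <= 0)) {
    stop("distance must be positive")
  }
  2 * atan((cfg$ipd / 2) / distance) * 180 / pi
}

#' Displacement of the first Purkinje image per eye rotation
#'
#' The corneal reflection moves relative to the pupil center by
#' `gaze_angle / hirschberg_ratio` millimetres: 1 mm per ~12 deg, i.e.
#' 83 um for one degree and 1.39 um for one arcminute. Linear and
#' odd-symmetric.
#'
#' @param gaze_angle Eye rotation in degrees. Vectorised.
#' @param cfg An [optical_config()].
#' @return Displacement in mm of the CR relative to the pupil center.
#' @export
cr_displacement <- function(gaze_angle, cfg = optical_config()) {
  gaze_angle / cfg$hirschberg_ratio
}

#' Nominal conversion between PC-CR vectors and gaze angles
#'
#' Converts a PC-CR vector (pupil center minus CR center, pixels) to gaze
#' angles in degrees using only the nominal optics (magnification and
#' Hirschberg ratio), i.e. without any calibration. Used by the
#' fixation-stability trigger and available as a quick uncalibrated gaze
#' readout. The vertical sign is flipped because image y runs downward while
#' positive vertical gaze is upward.
#'
#' @param dx,dy PC-CR vector components in pixels (vectorised).
#' @param cfg An [optical_config()].
#' @return A data.frame with columns `gaze_h`, `gaze_v` in degrees.
#' @export
pcr_to_gaze_nominal <- function(dx, dy, cfg = optical_config()) {
  k <- cfg$hirschberg_ratio / cfg$magnification
  data.frame(gaze_h = dx * k, gaze_v = -dy * k)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# signed x positions of the two eyes (subject frame, x rightward)
eye_positions <- function(cfg) c(left = -cfg$ipd / 2, right = cfg$ipd / 2)
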