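#' Pupil light response
#'
#' First-order exponential kinetics of the pupil diameter under a light
#' step: the diameter stays at `baseline` until `latency` seconds after the
#' step onset, then approaches `constricted` with time constant `tau`, and
#' relaxes back toward `baseline` (same kinetics) starting `latency` after
#' the step offset. Continuous in `t`.
#'
#' @param t Time in seconds (vectorised).
#' @param baseline,constricted Diameters in mm, `baseline > constricted > 0`.
#' @param latency Response latency, s.
#' @param tau Time constant, s (> 0).
#' @param onset,offset Light-step onset/offset times, s (default sustained
#'   light from t = 0).
#' @return Pupil diameter in mm at each `t`.
#' @examples
#' pupil_response(0.65, 6, 4, 0.25, 0.4)  # == 6 - (1 - exp(-1)) * 2
#' @export
pupil_response <- function(t, baseline, constricted, latency, tau,
                           onset = 0, offset = Inf) {
  if (!(baseline > constricted && constricted > 0)) {
    stop("require baseline > constricted > 0")
  }
  if (tau <= 0) stop("tau must be positive")
  t_on <- onset + latency
  t_off <- offset + latency
  d <- rep(baseline, length(t))
  down <- t >= t_on & t < t_off
  d[down] <- constricted + (baseline - constricted) * exp(-(t[down] - t_on) / tau)
  if (is.finite(t_off)) {
    d_off <- constricted + (baseline - constricted) * exp(-(t_off - t_on) / tau)
    up <- t >= t_off
    d[up] <- baseline + (d_off - baseline) * exp(-(t[up] - t_off) / tau)
  }
  d
}

# minimum-jerk position profile, s(0)=0, s(1)=1, zero velocity/acceleration
# at both ends
minimum_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# pixel position (0-based) of the pupil center implied by gaze and
# decentration; the anatomical center (without decentration) anchors the CR
pupil_center_px <- function(gaze_h, gaze_v, offset_x_mm, offset_y_mm, cfg) {
  cx <- (cfg$frame_width - 1) / 2
  cy <- (cfg$frame_height - 1) / 2
  m <- cfg$magnification
  list(
    x = cx + (gaze_h * cfg$pupil_travel + offset_x_mm) * m,
    y = cy - gaze_v * cfg$pupil_travel * m + offset_y_mm * m,
    anat_x = cx + gaze_h * cfg$pupil_travel * m,
    anat_y = cy - gaze_v * cfg$pupil_travel * m
  )
}

cr_center_px <- function(gaze_h, gaze_v, offset_x_mm, offset_y_mm, cfg) {
  p <- pupil_center_px(gaze_h, gaze_v, offset_x_mm, offset_y_mm, cfg)
  m <- cfg$magnification
  # CR lags the pupil by cr_displacement(gaze): PC-CR vector = gaze/HR * M
  list(x = p$anat_x - cr_displacement(gaze_h, cfg) * m,
       y = p$anat_y + cr_displacement(gaze_v, cfg) * m)
}

# draw an anti-aliased filled disc into matrix pix (rows = y, 0-based coords)
draw_disc <- function(pix, cx, cy, r, value) {
  h <- nrow(pix); w <- ncol(pix)
  x0 <- max(0L, floor(cx - r - 1)); x1 <- min(w - 1L, ceiling(cx + r + 1))
  y0 <- max(0L, floor(cy - r - 1)); y1 <- min(h - 1L, ceiling(cy + r + 1))
  if (x0 > x1 || y0 > y1) return(pix)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  block <- pix[ys + 1L, xs + 1L, drop = FALSE]
  pix[ys + 1L, xs + 1L] <- block * (1 - cov) + value * cov
  pix
}

#' Render one model-eye camera frame
#'
#' Draws, on a uniform iris/sclera background: a dark pupil disc of diameter
#' `pupil_mm * magnification` pixels centred at the position implied by gaze
#' (and shifted by the pupil decentration), a bright corneal-reflection disc
#' displaced from the (anatomical) pupil center by
#' `cr_displacement(gaze) * magnification`, and an eyelid occluder covering
#' the top fraction `1 - eyelid_aperture` of the frame. Disc edges are
#' anti-aliased (1-px coverage ramp). Additive Gaussian pixel noise of SD
#' `noise_sd` is applied, then values are rounded and clipped to [0, 255].
#'
#' A 4 mm pupil at the default 39.7 px/mm renders close to 20,000
#' below-threshold pixels and the CR about 400 above-threshold pixels.
#'
#' @param truth A list/row with fields `gaze_h`, `gaze_v` (degrees),
#'   `pupil_mm`, and optionally `offset_x_mm`, `offset_y_mm` (pupil
#'   decentration), `eyelid_aperture` (default 1), `frame_index`, `time_s`.
#' @param cfg An [optical_config()].
#' @param seed Optional integer; if given, the frame is rendered under a
#'   local RNG seed (identical inputs then give bit-identical frames). If
#'   `NULL` the current RNG stream is used (as during
#'   [simulate_protocol()]).
#' @param camera_id `"left"` or `"right"`.
#' @param draw_cr Draw the corneal reflection (default TRUE). The glint is
#'   rendered on top of the pupil, so in combined frames it occludes its
#'   ~400 pixels of pupil area; disc-only fixtures (`draw_cr = FALSE`)
#'   reproduce the analytic pupil area exactly.
#' @return A `pccr_frame`: list with `pixels` (integer matrix, rows = y),
#'   `camera_id`, `frame_index`, `time_s` and `out_of_bounds` (TRUE when the
#'   pupil or CR disc extends beyond the frame; the frame is still
#'   produced).
#' @export
render_eye_frame <- function(truth, cfg, seed = NULL, camera_id = "left",
                             draw_cr = TRUE) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  ap <- truth$eyelid_aperture %||% 1
  ox <- truth$offset_x_mm %||% 0
  oy <- truth$offset_y_mm %||% 0
  stopifnot(truth$pupil_mm > 0, truth$pupil_mm < 10, ap >= 0, ap <= 1)
  h <- cfg$frame_height; w <- cfg$frame_width; m <- cfg$magnification
  p <- pupil_center_px(truth$gaze_h, truth$gaze_v, ox, oy, cfg)
  cr <- cr_center_px(truth$gaze_h, truth$gaze_v, ox, oy, cfg)
  rp <- truth$pupil_mm * m / 2
  rc <- cfg$cr_diameter * m / 2
  oob <- p$x - rp < 0 || p$x + rp > w - 1 || p$y - rp < 0 || p$y + rp > h - 1 ||
    cr$x - rc < 0 || cr$x + rc > w - 1 || cr$y - rc < 0 || cr$y + rc > h - 1
  pix <- matrix(cfg$background_grey, nrow = h, ncol = w)
  pix <- draw_disc(pix, p$x, p$y, rp, cfg$pupil_grey)
  if (draw_cr) pix <- draw_disc(pix, cr$x, cr$y, rc, cfg$cr_grey)
  if (ap < 1) {
    lid <- (1 - ap) * h # eyelid edge in 0-based y, covering rows above it
    full <- floor(lid)
    if (full > 0) pix[seq_len(min(full, h)), ] <- cfg$background_grey
    frac <- lid - full
    if (frac > 0 && full < h) {
      pix[full + 1L, ] <- pix[full + 1L, ] * (1 - frac) + cfg$background_grey * frac
    }
  }
  if (cfg$noise_sd > 0) {
    pix <- pix + matrix(stats::rnorm(h * w, 0, cfg$noise_sd), nrow = h)
  }
  pix <- round(pmin(pmax(pix, 0), 255))
  storage.mode(pix) <- "integer"
  structure(list(pixels = pix, camera_id = camera_id,
                 frame_index = truth$frame_index %||% 0L,
                 time_s = truth$time_s %||% 0,
                 out_of_bounds = oob),
            class = "pccr_frame")
}

#' @export
print.pccr_frame <- function(x, ...) {
  cat(sprintf("<pccr_frame> %s #%d t=%.4fs %dx%d%s\n", x$camera_id,
              x$frame_index, x$time_s, ncol(x$pixels), nrow(x$pixels),
              if (isTRUE(x$out_of_bounds)) " [out of bounds]" else ""))
  invisible(x)
}

# per-eye fixation gaze (degrees) for a segment target
segment_gaze <- function(seg, cfg) {
  ex <- eye_positions(cfg)
  if (!is.null(seg$target_distance_mm)) {
    d <- seg$target_distance_mm
    gh <- rad2deg(atan((0 - ex) / d))
    gv <- c(left = 0, right = 0)
  } else {
    xmm <- seg$target_x_px * cfg$screen_pitch
    ymm <- seg$target_y_px * cfg$screen_pitch
    gh <- rad2deg(atan((xmm - ex) / cfg$screen_distance))
    gv0 <- rad2deg(atan(-ymm / cfg$screen_distance))
    gv <- c(left = gv0, right = gv0)
  }
  list(h = gh, v = gv)
}

# screen-referenced (cyclopean) target angles used as calibration truth
segment_target_deg <- function(seg, cfg) {
  if (!is.null(seg$target_distance_mm)) {
    c(h = 0, v = 0)
  } else {
    c(h = screen_px_to_deg(seg$target_x_px, cfg),
      v = -screen_px_to_deg(seg$target_y_px, cfg))
  }
}

#' Per-frame ground truth for a protocol
#'
#' Expands a [protocol()] into a per-frame truth table: per-eye gaze angles
#' (with minimum-jerk saccadic transitions between targets), the pupil
#' diameter trace driven by the screen grey level through the first-order
#' light response (input delayed by `pupil_latency`), pupil decentration
#' offsets (`artifact_coefficient * (pupil_mm - artifact_reference)`,
#' mirrored between the eyes), eyelid aperture and blink flags, truth
#' vergence, target bookkeeping and TTL markers (1 on the first frame of
#' each segment). Deterministic: contains no random component.
#'
#' @param protocol A `pccr_protocol`.
#' @param cfg An [optical_config()].
#' @return A data.frame with one row per frame.
#' @export
protocol_truth <- function(protocol, cfg) {
  stopifnot(inherits(protocol, "pccr_protocol"))
  durs <- vapply(protocol, `[[`, integer(1), "duration_frames")
  n <- sum(durs)
  seg_of <- rep(seq_along(protocol), durs)
  seg_start <- c(0L, cumsum(durs))[seq_along(protocol)] # 0-based first frame
  dt <- 1 / cfg$frame_rate

  # fixation gaze per segment and addressable-field check
  fix <- lapply(protocol, segment_gaze, cfg = cfg)
  for (i in seq_along(protocol)) {
    for (eye in c("left", "right")) {
      pc <- pupil_center_px(fix[[i]]$h[[eye]], fix[[i]]$v[[eye]], 0, 0, cfg)
      rmax <- cfg$pupil_baseline * cfg$magnification / 2
      if (pc$x - rmax < 0 || pc$x + rmax > cfg$frame_width - 1 ||
          pc$y - rmax < 0 || pc$y + rmax > cfg$frame_height - 1) {
        stop(sprintf("segment %d: target outside the addressable field (%s eye)", i, eye))
      }
    }
  }

  # gaze traces with minimum-jerk transitions at segment starts
  gh_l <- gh_r <- gv_l <- gv_r <- numeric(n)
  sf <- cfg$saccade_frames
  for (i in seq_along(protocol)) {
    idx <- which(seg_of == i)
    g <- fix[[i]]
    gh_l[idx] <- g$h[["left"]]; gh_r[idx] <- g$h[["right"]]
    gv_l[idx] <- g$v[["left"]]; gv_r[idx] <- g$v[["right"]]
    if (i > 1L && sf > 0L) {
      prev <- fix[[i - 1L]]
      k <- seq_len(min(sf, length(idx)))
      s <- minimum_jerk(k / sf)
      gh_l[idx[k]] <- prev$h[["left"]] + (g$h[["left"]] - prev$h[["left"]]) * s
      gh_r[idx[k]] <- prev$h[["right"]] + (g$h[["right"]] - prev$h[["right"]]) * s
      gv_l[idx[k]] <- prev$v[["left"]] + (g$v[["left"]] - prev$v[["left"]]) * s
      gv_r[idx[k]] <- prev$v[["right"]] + (g$v[["right"]] - prev$v[["right"]]) * s
    }
  }

  # pupil trace: first-order filter on the latency-delayed screen grey
  grey <- vapply(protocol, `[[`, numeric(1), "screen_grey")[seg_of]
  lat_f <- round(cfg$pupil_latency * cfg$frame_rate)
  grey_del <- c(rep(grey[1], lat_f), grey)[seq_len(n)]
  target_d <- cfg$pupil_baseline -
    (cfg$pupil_baseline - cfg$pupil_constricted) * pmin(grey_del, 150) / 150
  a <- exp(-dt / cfg$pupil_tau)
  pupil <- numeric(n)
  pupil[1] <- target_d[1]
  for (i in seq_len(n)[-1]) pupil[i] <- target_d[i] + (pupil[i - 1] - target_d[i]) * a

  # eyelid aperture from blink events (40 frames down + 40 up by default)
  aperture <- rep(1, n)
  bf <- cfg$blink_frames
  for (i in seq_along(protocol)) {
    for (b in protocol[[i]]$blink_at) {
      start <- seg_start[i] + b # 0-based global frame
      prof <- c(1 - seq_len(bf) / bf, seq_len(bf) / bf)
      at <- start + seq_along(prof) # 1-based indices
      keep <- at >= 1 & at <= n
      aperture[at[keep]] <- pmin(aperture[at[keep]], prof[keep])
    }
  }

  # decentration offsets (mm), mirrored between the eyes
  co <- cfg$artifact_coefficient * (pupil - cfg$artifact_reference)
  off_l <- if (cfg$artifact_eyes %in% c("both", "left")) co else 0 * co
  off_r <- if (cfg$artifact_eyes == "both") -co else if (cfg$artifact_eyes == "right") co else 0 * co

  # blink truth: the eyelid edge occludes part of the pupil
  lid_y <- (1 - aperture) * cfg$frame_height
  p_l <- pupil_center_px(gh_l, gv_l, off_l, 0, cfg)
  blink <- lid_y > (p_l$y - pupil * cfg$magnification / 2)

  tgt <- t(vapply(protocol, segment_target_deg, numeric(2), cfg = cfg))
  ttl <- as.integer(seq_len(n) %in% (seg_start + 1L))

  data.frame(
    frame_index = 0:(n - 1L), time_s = (0:(n - 1L)) * dt,
    segment = seg_of,
    gaze_h_left = gh_l, gaze_v_left = gv_l,
    gaze_h_right = gh_r, gaze_v_right = gv_r,
    pupil_mm = pupil,
    offset_x_left_mm = off_l, offset_x_right_mm = off_r,
    eyelid_aperture = aperture, blink = blink,
    vergence_deg = gh_l - gh_r,
    target_h_deg = tgt[seg_of, "h"], target_v_deg = tgt[seg_of, "v"],
    screen_grey = grey, ttl = ttl
  )
}

#' Simulate a binocular recording session
#'
#' Renders both cameras' frame streams for a protocol, aligned 1:1 with the
#' per-frame ground-truth log of [protocol_truth()]. Identical
#' (protocol, cfg, seed) triples produce bit-identical output.
#'
#' @param protocol A `pccr_protocol`.
#' @param cfg An [optical_config()].
#' @param seed Integer RNG seed for the pixel noise.
#' @param frames `"memory"` (default) keeps both frame lists in the returned
#'   session; `"none"` discards frames after the optional `sink` call —
#'   use this (with a sink) for long protocols to bound memory.
#' @param sink Optional `function(frame_left, frame_right, truth_row)`
#'   called once per frame in order.
#' @param cameras `"both"` (default) or a single camera (`"left"`/`"right"`)
#'   for monocular runs; the other stream is then NULL.
#' @return A `pccr_session`: list with `truth` (data.frame), `frames_left`,
#'   `frames_right` (lists of `pccr_frame`, or NULL), `cfg`, `protocol`.
#' @export
simulate_protocol <- function(protocol, cfg, seed = 1L,
                              frames = c("memory", "none"), sink = NULL,
                              cameras = c("both", "left", "right")) {
  frames <- match.arg(frames)
  cameras <- match.arg(cameras)
  truth <- protocol_truth(protocol, cfg)
  n <- nrow(truth)
  keep <- frames == "memory"
  fl <- if (keep) vector("list", n) else NULL
  fr <- if (keep) vector("list", n) else NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  for (i in seq_len(n)) {
    row <- truth[i, ]
    tl <- list(gaze_h = row$gaze_h_left, gaze_v = row$gaze_v_left,
               pupil_mm = row$pupil_mm, offset_x_mm = row$offset_x_left_mm,
               eyelid_aperture = row$eyelid_aperture,
               frame_index = row$frame_index, time_s = row$time_s)
    tr <- list(gaze_h = row$gaze_h_right, gaze_v = row$gaze_v_right,
               pupil_mm = row$pupil_mm, offset_x_mm = row$offset_x_right_mm,
               eyelid_aperture = row$eyelid_aperture,
               frame_index = row$frame_index, time_s = row$time_s)
    f_l <- if (cameras != "right") render_eye_frame(tl, cfg, camera_id = "left") else NULL
    f_r <- if (cameras != "left") render_eye_frame(tr, cfg, camera_id = "right") else NULL
    if (!is.null(sink)) sink(f_l, f_r, row)
    if (keep) { fl[[i]] <- f_l; fr[[i]] <- f_r }
  }
  structure(list(truth = truth, frames_left = fl, frames_right = fr,
                 cfg = cfg, protocol = protocol),
            class = "pccr_session")
}

#' @export
print.pccr_session <- function(x, ...) {
  cat(sprintf("<pccr_session> %d frames x 2 cameras (%s)\n", nrow(x$truth),
              if (is.null(x$frames_left)) "frames not retained" else "frames in memory"))
  invisible(x)
}
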