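#' Run the full tracking pipeline on a simulated session
#'
#' Orchestrates simulate -> detect -> calibrate -> track -> QC -> metrics
#' from a single structured config, fully reproducible from (config, seed).
#'
#' The config (a list, or a path to a JSON file) has fields:
#' \describe{
#'   \item{optics}{optional list of [optical_config()] overrides}
#'   \item{calibration}{required: `half_width_deg`, `half_height_deg`,
#'     `frames_per_point` of the 4-point calibration}
#'   \item{light_step}{optional: `dark_s`, `step_frames`, `step_grey`,
#'     `post_s` — inserts the pupil-artifact assessment block}
#'   \item{targets}{optional list of test fixations: `x_deg`, `y_deg`,
#'     `frames` each (and optionally `blink_at`)}
#'   \item{epoch_s}{epoch length for the precision report (default 1)}
#' }
#'
#' @param config List or JSON path.
#' @param seed Integer seed for the simulation noise.
#' @param out_dir Optional output directory; when given, writes
#'   `recording.csv`, `calibration.json`, `truth.csv`, `qc_left.csv`,
#'   `qc_right.csv`, `metrics.json` and `manifest.json`.
#' @return A list: `recording`, `calibration`, `artifact` (or NULL),
#'   `metrics`, `truth`, `detections`, `cfg`, `manifest`.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  cfg <- do.call(optical_config, config$optics %||% list())
  if (is.null(config$calibration)) {
    stop("config field 'calibration' is missing (half_width_deg, half_height_deg, frames_per_point)")
  }
  cal_spec <- config$calibration
  segs <- unclass(calibration_protocol(
    cfg,
    half_width_deg = cal_spec$half_width_deg %||% 4,
    half_height_deg = cal_spec$half_height_deg %||% 4,
    frames_per_point = cal_spec$frames_per_point %||% 200L
  ))
  if (!is.null(config$light_step)) {
    ls <- config$light_step
    if (isTRUE(ls)) ls <- list()
    segs <- c(segs, unclass(light_step_protocol(
      cfg,
      dark_frames = round((ls$dark_s %||% 1.5) * cfg$frame_rate),
      step_frames = ls$step_frames %||% 30L,
      step_grey = ls$step_grey %||% 150,
      post_frames = round((ls$post_s %||% 1) * cfg$frame_rate)
    )))
  }
  for (tg in config$targets %||% list()) {
    segs <- c(segs, list(protocol_segment(
      tg$frames %||% round(1.5 * cfg$frame_rate),
      target_x_px = screen_deg_to_px(tg$x_deg %||% 0, cfg),
      target_y_px = -screen_deg_to_px(tg$y_deg %||% 0, cfg),
      blink_at = as.integer(tg$blink_at %||% integer(0)),
      label = "target"
    )))
  }
  proto <- protocol(segs)

  # simulate with streaming detection (frames are never retained)
  ds <- detect_sink(cfg)
  sess <- tryCatch(
    simulate_protocol(proto, cfg, seed = seed, frames = "none", sink = ds$sink),
    error = function(e) stop("stage simulate: ", conditionMessage(e), call. = FALSE)
  )
  truth <- sess$truth
  det <- ds$results()

  cal_targets <- calibration_targets(proto, cfg, labels = "calibration")
  calib <- tryCatch(
    calibrate_eyes(det$left, det$right, cal_targets, cfg),
    error = function(e) stop("stage calibrate: ", conditionMessage(e), call. = FALSE)
  )

  gl <- map_gaze(calib$left, det$left$dx, det$left$dy)
  gr <- map_gaze(calib$right, det$right$dx, det$right$dy)
  verg_raw <- compute_vergence(gl$gaze_h, gr$gaze_h, cfg)

  blink <- detect_blink(det$left$pupil_mm) | detect_blink(det$right$pupil_mm) |
    !det$left$valid | !det$right$valid

  artifact <- NULL
  verg_cor <- verg_raw
  if (!is.null(config$light_step)) {
    win <- artifact_window(truth, cfg) & !blink
    artifact <- tryCatch(
      assess_pupil_artifact(det$left$pupil_mm[win], verg_raw[win]),
      error = function(e) stop("stage pupil-artifact: ", conditionMessage(e), call. = FALSE)
    )
    verg_cor <- correct_vergence(verg_raw, det$left$pupil_mm, artifact)
  }

  recording <- data.frame(
    computer_time = truth$time_s,
    frame_number = truth$frame_index,
    pupil_left_mm = det$left$pupil_mm,
    pupil_right_mm = det$right$pupil_mm,
    x_left_px = screen_deg_to_px(gl$gaze_h, cfg),
    x_right_px = screen_deg_to_px(gr$gaze_h, cfg),
    vergence_raw_arcmin = verg_raw,
    vergence_corrected_arcmin = verg_cor,
    target_x = screen_deg_to_px(truth$target_h_deg, cfg),
    target_y = -screen_deg_to_px(truth$target_v_deg, cfg),
    ttl = truth$ttl,
    blink = blink
  )

  metrics <- pipeline_metrics(proto, truth, gl, gr, blink, cfg,
                              epoch_s = config$epoch_s %||% 1)

  manifest <- list(
    package = "pccr",
    version = as.character(utils::packageVersion("pccr")),
    r_version = R.version.string,
    seed = seed,
    config_md5 = config_hash(config),
    n_frames = nrow(truth),
    created = "run_pipeline"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_recording(recording, file.path(out_dir, "recording.csv"))
    write_calibration(calib, file.path(out_dir, "calibration.json"))
    write_truth(truth, file.path(out_dir, "truth.csv"))
    utils::write.csv(qc_report(det$left, cfg), file.path(out_dir, "qc_left.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(qc_report(det$right, cfg), file.path(out_dir, "qc_right.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(recording = recording, calibration = calib, artifact = artifact,
       metrics = metrics, truth = truth, detections = det, cfg = cfg,
       manifest = manifest)
}

# md5 of the canonical JSON form of the config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

# accuracy and precision over the test-target segments (left eye, as in the
# evaluation convention), skipping the saccadic transition at segment start
pipeline_metrics <- function(proto, truth, gl, gr, blink, cfg, epoch_s = 1,
                             settle_frames = 30L) {
  durs <- vapply(proto, `[[`, integer(1), "duration_frames")
  start <- c(0L, cumsum(durs))[seq_along(proto)]
  test <- which(vapply(proto, function(s) identical(s$label, "target"), logical(1)))
  per_target <- lapply(test, function(i) {
    idx <- which(truth$frame_index >= start[i] + settle_frames &
                   truth$frame_index <= start[i] + durs[i] - 1L & !blink)
    tgt <- c(h = truth$target_h_deg[match(start[i], truth$frame_index) + settle_frames],
             v = truth$target_v_deg[match(start[i], truth$frame_index) + settle_frames])
    acc <- accuracy(gl$gaze_h[idx], gl$gaze_v[idx], tgt)
    prec <- precision_report(gl$gaze_h[idx], gl$gaze_v[idx], cfg$frame_rate, epoch_s)
    list(segment = i, target_h = unname(tgt["h"]), target_v = unname(tgt["v"]),
         accuracy_deg = acc$euclidean, accuracy_h = acc$h, accuracy_v = acc$v,
         precision_rms_h = prec$rms_h, precision_rms_v = prec$rms_v,
         precision_sd_h = prec$sd_h, precision_sd_v = prec$sd_v,
         n_samples = length(idx))
  })
  list(per_target = per_target,
       mean_accuracy_deg = if (length(per_target)) {
         mean(vapply(per_target, `[[`, numeric(1), "accuracy_deg"), na.rm = TRUE)
       } else NA_real_)
}
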