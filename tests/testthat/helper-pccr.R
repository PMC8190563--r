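# shared fixtures, built in code

# reduced optics for fast unit tests: same geometry rules, 4x smaller
# magnification and frame; blob-size minima scale with magnification^2
# the CR is drawn larger than scale so its centroid quantisation error stays
# negligible at the coarse magnification
cfg_small <- function(noise_sd = 0, ...) {
  optical_config(magnification = 10, frame_width = 160L, frame_height = 120L,
                 cr_diameter = 1.2, noise_sd = noise_sd, ...)
}

cfg_default <- function(...) optical_config(...)

# static truth row
truth_at <- function(gaze_h = 0, gaze_v = 0, pupil_mm = 4, ...) {
  c(list(gaze_h = gaze_h, gaze_v = gaze_v, pupil_mm = pupil_mm), list(...))
}

# n repeated renders of the same truth, detected (single camera)
repeat_detect <- function(truth, cfg, n, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    detect_frame(render_eye_frame(truth, cfg), cfg = cfg)
  }))
}

# heavier simulated sessions are computed once and shared across test files
.pccr_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .pccr_cache)) assign(key, force(expr), .pccr_cache)
  get(key, .pccr_cache)
}

# the bundled demo pipeline (default optics): calibration + light step +
# 5 fixation targets; feeds the pipeline smoke test and several acceptance
# criteria
demo_pipeline_run <- function() {
  cached("demo", {
    cfg_path <- system.file("extdata", "demo_config.json", package = "pccr")
    run_pipeline(cfg_path, seed = 7)
  })
}

# calibration (+-4 deg, 160 frames/point) followed by a 3x3 grid of test
# fixations at +-3/0 deg, 48 frames each; returns detections + calibration
grid_session <- function(noise = TRUE) {
  cached(paste0("grid_", noise), {
    cfg <- optical_config(noise_sd = if (noise) 20 else 0)
    grid <- expand.grid(h = c(-3, 0, 3), v = c(-3, 0, 3))
    segs <- c(unclass(calibration_protocol(cfg, 4, 4, 160L)),
              lapply(seq_len(nrow(grid)), function(i) {
                protocol_segment(48L,
                                 target_x_px = screen_deg_to_px(grid$h[i], cfg),
                                 target_y_px = -screen_deg_to_px(grid$v[i], cfg),
                                 label = "target")
              }))
    proto <- protocol(segs)
    ds <- detect_sink(cfg)
    sess <- simulate_protocol(proto, cfg, seed = 17, frames = "none", sink = ds$sink)
    det <- ds$results()
    cal <- calibrate_eyes(det$left, det$right, calibration_targets(proto, cfg), cfg)
    list(cfg = cfg, proto = proto, truth = sess$truth, det = det, cal = cal,
         grid = grid)
  })
}

# brute-force Eq. 2 oracle: RMS of inter-sample distances, plain loop
rms_oracle <- function(x, y = NULL) {
  acc <- c()
  for (i in seq_len(length(x) - 1)) {
    d2 <- (x[i + 1] - x[i])^2
    if (!is.null(y)) d2 <- d2 + (y[i + 1] - y[i])^2
    acc <- c(acc, d2)
  }
  sqrt(mean(acc))
}
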