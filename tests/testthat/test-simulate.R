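test_that("pupil_response follows the first-order closed form", {
  b <- 6; cst <- 4; lat <- 0.25; tau <- 0.4
  expect_equal(pupil_response(0.1, b, cst, lat, tau), b) # before latency
  expect_equal(pupil_response(lat + tau, b, cst, lat, tau),
               b - (1 - exp(-1)) * (b - cst))
  expect_equal(pupil_response(100, b, cst, lat, tau), cst, tolerance = 1e-9)
  # continuity across phase boundaries (sustained and finite step)
  t <- seq(0, 3, by = 1e-3)
  y <- pupil_response(t, b, cst, lat, tau, onset = 0.5, offset = 1)
  expect_lt(max(abs(diff(y))), (b - cst) / tau * 2e-3)
  # relaxation back to baseline after offset
  expect_equal(pupil_response(30, b, cst, lat, tau, onset = 0, offset = 1), b,
               tolerance = 1e-9)
  expect_error(pupil_response(1, 4, 6, lat, tau), "baseline")
  expect_error(pupil_response(1, 6, 4, lat, 0), "tau")
})

test_that("rendered pupil pixel count matches the analytic disc area", {
  cfg <- cfg_default(noise_sd = 0)
  for (d_mm in c(2, 4, 6, 8)) {
    f <- render_eye_frame(truth_at(pupil_mm = d_mm), cfg, draw_cr = FALSE)
    det <- detect_pupil(f, cfg = cfg)
    expect_equal(det$area, pi * (d_mm * cfg$magnification / 2)^2,
                 tolerance = 0.01) # within 1%
  }
  # a 4 mm pupil yields about 20,000 dark pixels; the CR punches a ~400 px
  # hole that raw mode keeps and component mode re-fills
  f4 <- render_eye_frame(truth_at(pupil_mm = 4), cfg)
  a4 <- detect_pupil(f4, cfg = cfg)$area
  expect_equal(a4, pi * (2 * cfg$magnification)^2, tolerance = 0.01)
  a4_raw <- detect_pupil(f4, cfg = cfg, component = FALSE)$area
  expect_lt(a4_raw, a4 - 300)
  expect_gt(a4_raw, a4 - 500)
})

test_that("CR moves by the Hirschberg displacement in the image", {
  cfg <- cfg_default(noise_sd = 0)
  d0 <- detect_frame(render_eye_frame(truth_at(0), cfg), cfg = cfg)
  d1 <- detect_frame(render_eye_frame(truth_at(1), cfg), cfg = cfg)
  # 83 um/deg at 39.7 px/mm = 3.31 px of PC-CR change per degree
  expect_equal(d1$dx - d0$dx, 0.0833 * 39.7, tolerance = 0.02)
})

test_that("eyelid occlusion removes the pupil and drives the blink flag", {
  cfg <- cfg_small()
  f <- render_eye_frame(truth_at(eyelid_aperture = 0), cfg)
  expect_false(detect_pupil(f, cfg = cfg)$valid) # full occlusion: no dark pixels
  f_half <- render_eye_frame(truth_at(eyelid_aperture = 0.5), cfg)
  a_half <- detect_pupil(f_half, cfg = cfg)$area
  a_full <- detect_pupil(render_eye_frame(truth_at(), cfg), cfg = cfg)$area
  expect_lt(a_half, a_full)
})

test_that("geometry round-trip: nominal conversion recovers truth gaze", {
  cfg <- cfg_default(noise_sd = 0)
  for (gh in c(-10, -5, -1, 0, 2.5, 10)) {
    det <- detect_frame(render_eye_frame(truth_at(gaze_h = gh, gaze_v = gh / 2), cfg),
                        cfg = cfg)
    g <- pcr_to_gaze_nominal(det$dx, det$dy, cfg)
    expect_lt(abs(g$gaze_h - gh), 0.05)
    expect_lt(abs(g$gaze_v - gh / 2), 0.05)
  }
})

test_that("|PC-CR| grows monotonically with |gaze|", {
  cfg <- cfg_default(noise_sd = 0)
  mags <- vapply(c(0, 3, 6, 9, 12, 15), function(gh) {
    det <- detect_frame(render_eye_frame(truth_at(gaze_h = gh), cfg), cfg = cfg)
    sqrt(det$dx^2 + det$dy^2)
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("rendering is deterministic under a fixed seed", {
  cfg <- cfg_small(noise_sd = 8)
  f1 <- render_eye_frame(truth_at(), cfg, seed = 99)
  f2 <- render_eye_frame(truth_at(), cfg, seed = 99)
  expect_identical(f1$pixels, f2$pixels)
  p <- protocol(protocol_segment(10, 0, 0))
  s1 <- simulate_protocol(p, cfg, seed = 5)
  s2 <- simulate_protocol(p, cfg, seed = 5)
  expect_identical(lapply(s1$frames_left, `[[`, "pixels"),
                   lapply(s2$frames_left, `[[`, "pixels"))
  expect_identical(s1$truth, s2$truth)
})

test_that("out-of-frame features are flagged but the frame is produced", {
  cfg <- cfg_small()
  f <- render_eye_frame(truth_at(gaze_h = 40), cfg)
  expect_true(f$out_of_bounds)
  expect_true(is.matrix(f$pixels))
})

test_that("protocol truth: depth alternation reproduces the vergence staircase", {
  cfg <- cfg_small()
  p <- protocol(
    protocol_segment(30, target_distance_mm = 540),
    protocol_segment(30, target_distance_mm = 290),
    protocol_segment(30, target_distance_mm = 540)
  )
  tr <- protocol_truth(p, cfg)
  # plateaus (after the saccadic transition) sit at the geometric angles
  expect_equal(tr$vergence_deg[25], 6.360, tolerance = 1e-3)
  expect_equal(tr$vergence_deg[55], 11.812, tolerance = 1e-3)
  expect_equal(tr$vergence_deg[85], 6.360, tolerance = 1e-3)
  # convergence is symmetric between the eyes
  expect_equal(tr$gaze_h_left, -tr$gaze_h_right)
})

test_that("protocol truth: light step constricts the pupil after the latency", {
  cfg <- cfg_small()
  p <- protocol(
    protocol_segment(50, 0, 0, screen_grey = 0),
    protocol_segment(30, 0, 0, screen_grey = 150), # ~75 ms bright step
    protocol_segment(300, 0, 0, screen_grey = 0)
  )
  tr <- protocol_truth(p, cfg)
  lat_f <- round(cfg$pupil_latency * cfg$frame_rate)
  expect_equal(tr$pupil_mm[1:(50 + lat_f)], rep(cfg$pupil_baseline, 50 + lat_f))
  expect_lt(min(tr$pupil_mm), cfg$pupil_baseline - 0.2) # clear constriction
  # no discrete pupil jumps: bounded by the ODE rate limit
  expect_lt(max(abs(diff(tr$pupil_mm))),
            (cfg$pupil_baseline - cfg$pupil_constricted) / cfg$pupil_tau / cfg$frame_rate * 1.01)
})

test_that("protocol truth: TTL marks new targets; saccades use minimum jerk", {
  cfg <- cfg_small()
  p <- protocol(protocol_segment(40, 0, 0),
                protocol_segment(40, 30, 0),
                protocol_segment(40, 0, 0))
  tr <- protocol_truth(p, cfg)
  expect_equal(which(tr$ttl == 1), c(1, 41, 81))
  # transition is smooth and completes within saccade_frames
  seg2 <- tr$gaze_h_left[41:80]
  expect_equal(seg2[cfg$saccade_frames:40],
               rep(seg2[40], 40 - cfg$saccade_frames + 1), tolerance = 1e-9)
  expect_true(all(diff(seg2[1:cfg$saccade_frames]) > 0))
})

test_that("targets outside the addressable field raise a named error", {
  cfg <- cfg_small()
  p <- protocol(protocol_segment(10, 5000, 0))
  expect_error(protocol_truth(p, cfg), "segment 1")
})

test_that("simulated blink covers the truth-flag span", {
  cfg <- cfg_small()
  p <- protocol(protocol_segment(150, 0, 0, blink_at = 30L))
  tr <- protocol_truth(p, cfg)
  expect_gt(sum(tr$blink), 0)
  # aperture reaches full closure and returns to open
  expect_equal(min(tr$eyelid_aperture), 0)
  expect_equal(tr$eyelid_aperture[150], 1)
})
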