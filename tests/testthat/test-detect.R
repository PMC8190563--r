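test_that("Eq. 1 self-consistency: area to radius and back", {
  cfg <- cfg_default(noise_sd = 0)
  areas <- c(1, 113, 20000, 5e5)
  for (a in areas) expect_equal(pi * sqrt(a / pi)^2, a)
  # the quoted worked example: 20,000 px -> r = 79.79 px -> 4.02 mm
  r <- sqrt(20000 / pi)
  expect_equal(r, 79.79, tolerance = 1e-4)
  expect_equal(2 * r / cfg$magnification, 4.02, tolerance = 1e-3)
})

test_that("noiseless centroids are sub-pixel accurate (< 0.05 px)", {
  cfg <- cfg_default(noise_sd = 0)
  for (sub in c(0, 0.25, 0.5, 0.7)) {
    gh <- sub / (cfg$pupil_travel * cfg$magnification) # sub-pixel pupil shifts
    tr <- truth_at(gaze_h = gh)
    p <- pccr:::pupil_center_px(tr$gaze_h, 0, 0, 0, cfg)
    det <- detect_pupil(render_eye_frame(tr, cfg, draw_cr = FALSE), cfg = cfg)
    expect_lt(abs(det$x - p$x), 0.05)
    expect_lt(abs(det$y - p$y), 0.05)
  }
})

test_that("the CR detector finds a ~400 px blob at the rendered position", {
  cfg <- cfg_default(noise_sd = 0)
  f <- render_eye_frame(truth_at(), cfg)
  cr <- detect_purkinje(f, cfg = cfg)
  expect_true(cr$valid)
  expect_equal(cr$x, (cfg$frame_width - 1) / 2, tolerance = 0.05)
  expect_equal(cr$y, (cfg$frame_height - 1) / 2, tolerance = 0.05)
  expect_gt(cr$area, 300); expect_lt(cr$area, 500)
})

test_that("CR area is a focus score: defocus enlarges the footprint", {
  sharp <- cfg_default(noise_sd = 0)
  blurred <- cfg_default(noise_sd = 0, cr_diameter = 0.9) # defocused fixture
  a1 <- detect_purkinje(render_eye_frame(truth_at(), sharp), cfg = sharp)$area
  a2 <- detect_purkinje(render_eye_frame(truth_at(), blurred), cfg = blurred)$area
  expect_gt(a2, a1)
})

test_that("degenerate inputs give valid = FALSE, bad ROIs error", {
  cfg <- cfg_small()
  flat <- matrix(120L, 120, 160)
  expect_false(detect_pupil(flat, cfg = cfg)$valid) # nothing below threshold
  m249 <- matrix(249L, 120, 160)
  expect_false(detect_purkinje(m249, cfg = cfg)$valid) # below the fixed 250
  expect_error(detect_pupil(flat, roi = c(-1, 0, 10, 10), cfg = cfg), "roi")
  expect_error(detect_pupil(flat, roi = c(0, 0, 200, 10), cfg = cfg), "roi")
  expect_error(detect_pupil(flat, threshold_factor = 1.2, cfg = cfg), "threshold_factor")
})

test_that("tiny blobs fall below the minimum-area validity gates", {
  cfg <- cfg_default(noise_sd = 0)
  m <- matrix(120, 480, 640)
  m[240:242, 320:322] <- 10 # 9 dark px << 500 minimum
  expect_false(detect_pupil(m, cfg = cfg)$valid)
  m2 <- matrix(120, 480, 640)
  m2[240:241, 320:321] <- 255 # 4 bright px << 20 minimum
  expect_false(detect_purkinje(m2, cfg = cfg)$valid)
})

test_that("component mode ignores stray dark pixels; raw mode keeps them", {
  cfg <- cfg_default(noise_sd = 0)
  f <- render_eye_frame(truth_at(), cfg, draw_cr = FALSE)
  m <- f$pixels
  m[1:10, 1:10] <- 0L # a 100-px dark corner artifact
  with_comp <- detect_pupil(m, cfg = cfg, component = TRUE)
  raw <- detect_pupil(m, cfg = cfg, component = FALSE)
  expect_equal(raw$area, with_comp$area + 100)
  expect_equal(with_comp$x, (cfg$frame_width - 1) / 2, tolerance = 0.05)
  expect_lt(raw$x, with_comp$x) # corner pixels drag the raw centroid
})

test_that("largest_component picks the bigger of two blobs (4-connectivity)", {
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE # 16 px
  m[10:16, 10:16] <- TRUE # 49 px
  m[1, 20] <- TRUE # isolated pixel
  lc <- pccr:::largest_component(m)
  expect_equal(sum(lc), 49)
  expect_true(all(lc[10:16, 10:16]))
  # diagonal touch is NOT connected under 4-connectivity
  m2 <- matrix(FALSE, 5, 5)
  m2[1:2, 1:2] <- TRUE
  m2[3, 3] <- TRUE
  expect_equal(sum(pccr:::largest_component(m2)), 4)
})

test_that("pcr_vector: difference, invalid propagation, translation invariance", {
  p <- list(valid = TRUE, x = 10, y = 20)
  cr <- list(valid = TRUE, x = 10, y = 20)
  expect_equal(pcr_vector(p, cr)[c("dx", "dy")], list(dx = 0, dy = 0))
  expect_false(pcr_vector(list(valid = FALSE), cr)$valid)

  cfg <- cfg_default(noise_sd = 0)
  f <- render_eye_frame(truth_at(gaze_h = 2), cfg)
  d0 <- detect_frame(f, cfg = cfg)
  sh <- 7L # whole-frame circular shift (background is uniform)
  m <- f$pixels[c((sh + 1):480, 1:sh), c((sh + 1):640, 1:sh)]
  d1 <- detect_frame(m, cfg = cfg)
  expect_equal(d1$dx, d0$dx, tolerance = 1e-9)
  expect_equal(d1$dy, d0$dy, tolerance = 1e-9)
})

test_that("per-frame PC-CR noise at default settings sits in the 0.2-0.5 px band", {
  # the 25-sample SD estimator itself scatters ~15%, so average it over a
  # longer run of repeated frames rather than trusting a single window
  cfg <- cfg_default()
  det <- repeat_detect(truth_at(), cfg, 100, seed = 21)
  sdx <- mean(pccr:::rolling_sd(det$dx, 25), na.rm = TRUE)
  sdy <- mean(pccr:::rolling_sd(det$dy, 25), na.rm = TRUE)
  expect_gt(sdx, 0.2); expect_lt(sdx, 0.5)
  expect_gt(sdy, 0.2); expect_lt(sdy, 0.5)
})

test_that("detect_stream tracks the ROI and recovers after loss", {
  cfg <- cfg_small()
  p <- protocol(protocol_segment(8, 0, 0),
                protocol_segment(8, 0, 0, blink_at = 0L), # lid sweep kills detection
                protocol_segment(8, 0, 0))
  cfg2 <- cfg_small(blink_frames = 4L)
  s <- simulate_protocol(p, cfg2, seed = 2, cameras = "left")
  det <- detect_stream(s$frames_left, cfg2)
  expect_true(any(!det$valid)) # lost during lid closure
  expect_true(all(det$valid[21:24])) # re-acquired from full frame
  expect_equal(nrow(det), 24)
})
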