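#' Running noise statistics
#'
#' Real-time-style stability measures over the latest `window` samples
#' (25 samples span 63 ms at 395 Hz): the sample standard deviation, and as
#' a more conservative measure the mean absolute difference between
#' subsequent samples (`mad1`). Reported in the series' native units
#' (pixels for PC-CR components) and, when a config is given, in arcmin via
#' the nominal conversion.
#'
#' @param series Numeric vector, most recent sample last.
#' @param window Window length (default 25).
#' @param cfg Optional [optical_config()] for the arcmin conversion.
#' @return List `sd`, `mad1` (and `sd_arcmin`, `mad1_arcmin` with a cfg);
#'   `NA`s when the series is shorter than the window.
#' @export
running_stats <- function(series, window = 25L, cfg = NULL) {
  if (length(series) < window) {
    out <- list(sd = NA_real_, mad1 = NA_real_)
  } else {
    x <- utils::tail(series, window)
    out <- list(sd = stats::sd(x), mad1 = mean(abs(diff(x))))
  }
  if (!is.null(cfg)) {
    out$sd_arcmin <- out$sd * arcmin_per_pixel(cfg)
    out$mad1_arcmin <- out$mad1 * arcmin_per_pixel(cfg)
  }
  out
}

# rolling (trailing-window) standard deviation; NA for the first window-1
# samples. Two-pass moment formula is adequate for these magnitudes.
rolling_sd <- function(x, window) {
  n <- length(x)
  if (n < window) return(rep(NA_real_, n))
  c1 <- cumsum(x); c2 <- cumsum(x^2)
  s1 <- c1[window:n] - c(0, c1)[1:(n - window + 1)]
  s2 <- c2[window:n] - c(0, c2)[1:(n - window + 1)]
  v <- (s2 - s1^2 / window) / (window - 1)
  c(rep(NA_real_, window - 1L), sqrt(pmax(v, 0)))
}

#' Per-frame QC table
#'
#' Rolling [running_stats()] over a detection stream's PC-CR components,
#' plus the blink flag from the pupil-size channel.
#'
#' @param det Detection table (see [detect_stream()]).
#' @param cfg An [optical_config()].
#' @param window Rolling window (default 25).
#' @return data.frame per frame: `sd_x`, `sd_y`, `mad1` (px),
#'   `sd_x_arcmin`, `sd_y_arcmin`, `mad1_arcmin`, `blink`.
#' @export
qc_report <- function(det, cfg = optical_config(), window = 25L) {
  dx <- det$dx; dy <- det$dy
  dx[!det$valid] <- NA; dy[!det$valid] <- NA
  sd_x <- rolling_sd(dx, window)
  sd_y <- rolling_sd(dy, window)
  adx <- abs(diff(dx))
  mad1 <- c(rep(NA_real_, window - 1L),
            vapply(window:length(dx), function(i) {
              mean(adx[(i - window + 1L):(i - 1L)])
            }, numeric(1)))
  k <- arcmin_per_pixel(cfg)
  data.frame(frame_index = det$frame_index,
             sd_x = sd_x, sd_y = sd_y, mad1 = mad1,
             sd_x_arcmin = sd_x * k, sd_y_arcmin = sd_y * k,
             mad1_arcmin = mad1 * k,
             blink = detect_blink(det$pupil_mm, window = window))
}

#' Blink detection from the pupil-size channel
#'
#' During a blink the eyelid sweeps over the pupil and the dark-pixel count
#' collapses far faster than any physiological pupil response, so a running
#' standard deviation of pupil sizes exceeding `threshold_mm` (default
#' 0.2 mm over 25 samples) denotes a blink. Samples where detection failed
#' entirely (NA pupil size — e.g. the lid covered the pupil) are treated as
#' 0 mm. Flagged spans are extended by `extend` samples on each side as a
#' recovery margin.
#'
#' @param pupil_mm Per-frame pupil diameters, mm (NA = detection lost).
#' @param window Rolling window (default 25).
#' @param threshold_mm SD threshold (default 0.2 mm).
#' @param extend Samples added on each side of a flagged span (default 5).
#' @return Logical vector, TRUE on blink samples.
#' @export
detect_blink <- function(pupil_mm, window = 25L, threshold_mm = 0.2, extend = 5L) {
  p <- ifelse(is.na(pupil_mm), 0, pupil_mm)
  s <- rolling_sd(p, window)
  flag <- !is.na(s) & s > threshold_mm
  if (extend > 0L && any(flag)) {
    idx <- which(flag)
    ext <- unique(unlist(lapply(idx, function(i) (i - extend):(i + extend))))
    ext <- ext[ext >= 1L & ext <= length(flag)]
    flag[ext] <- TRUE
  }
  flag
}

#' Assess the pupil-decentration artifact
#'
#' A changing pupil diameter can drag the detected pupil center with it and
#' masquerade as a vergence change. During the light-step protocol the
#' software regresses the vergence measure on pupil size (ordinary least
#' squares); a slope significantly different from zero (two-sided t-test,
#' default alpha 0.05) indicates that a correction is necessary.
#'
#' @param pupil_mm,vergence_arcmin Paired per-frame series from the
#'   light-step window, blinks excluded (NA pairs are dropped).
#' @param alpha Significance level (default 0.05).
#' @param min_pairs Minimum complete pairs (default 30).
#' @return A `pccr_artifact`: `slope` (arcmin/mm), `intercept`, `slope_se`,
#'   `p_value`, `significant`, `reference_pupil` (mm, the series mean),
#'   `n`.
#' @export
assess_pupil_artifact <- function(pupil_mm, vergence_arcmin, alpha = 0.05,
                                  min_pairs = 30L) {
  ok <- stats::complete.cases(pupil_mm, vergence_arcmin)
  p <- pupil_mm[ok]; v <- vergence_arcmin[ok]
  if (length(p) < min_pairs) {
    stop(sprintf("need at least %d complete pairs, got %d", min_pairs, length(p)))
  }
  if (stats::sd(p) == 0) {
    stop("pupil size has zero variance: the protocol failed to elicit a response")
  }
  fit <- stats::lm(v ~ p)
  # exactly linear (noiseless) input is legitimate here; silence lm's
  # "essentially perfect fit" advisory
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = unname(sm["p", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 slope_se = unname(sm["p", "Std. Error"]),
                 p_value = unname(sm["p", "Pr(>|t|)"]),
                 significant = unname(sm["p", "Pr(>|t|)"]) < alpha,
                 reference_pupil = mean(p), n = length(p)),
            class = "pccr_artifact")
}

#' @export
print.pccr_artifact <- function(x, ...) {
  cat(sprintf("<pccr_artifact> slope %.2f arcmin/mm (se %.2f, p %.3g)%s; ref pupil %.2f mm, n=%d\n",
              x$slope, x$slope_se, x$p_value,
              if (x$significant) " SIGNIFICANT" else "", x$reference_pupil, x$n))
  invisible(x)
}

#' Correct vergence for the pupil-decentration artifact
#'
#' Re-calculates vergence for each known pupil size using the fitted
#' regression: `corrected = vergence - slope * (pupil - reference_pupil)`.
#' Centring on the reference (mean) pupil size of the fitting window makes
#' the correction preserve mean vergence. When the slope is not
#' significant, the input is returned unchanged.
#'
#' @param vergence_arcmin,pupil_mm Vectors (vectorised, NA passes through).
#' @param reg A `pccr_artifact` from [assess_pupil_artifact()].
#' @return Corrected vergence, arcmin.
#' @export
correct_vergence <- function(vergence_arcmin, pupil_mm, reg) {
  stopifnot(inherits(reg, "pccr_artifact"))
  if (!isTRUE(reg$significant)) return(vergence_arcmin)
  vergence_arcmin - reg$slope * (pupil_mm - reg$reference_pupil)
}

#' Samples belonging to the artifact-regression window
#'
#' The regression data span runs from the light-step onset to 600 ms after
#' its offset.
#'
#' @param truth Truth table of a session built on [light_step_protocol()]
#'   (uses `screen_grey`).
#' @param cfg An [optical_config()].
#' @param post_s Seconds after step offset (default 0.6).
#' @return Logical vector over frames.
#' @export
artifact_window <- function(truth, cfg, post_s = 0.6) {
  bright <- truth$screen_grey > 0
  if (!any(bright)) stop("protocol contains no light step")
  onset <- which(bright)[1]
  offset <- max(which(bright))
  idx <- seq_len(nrow(truth))
  idx >= onset & idx <= offset + round(post_s * cfg$frame_rate)
}
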