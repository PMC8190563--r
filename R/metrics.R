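#' Precision: RMS of inter-sample distances
#'
#' Sample-to-sample noise during steady fixation:
#' `sqrt(mean(theta_i^2))` where `theta_i` is the angular distance between
#' successive samples — per axis when only `x` is given, Euclidean when
#' both axes are given. Distances are formed only between consecutive valid
#' (non-NA) samples. For white noise of standard deviation sigma the RMS
#' approaches `sigma * sqrt(2)`.
#'
#' @param x Gaze samples (degrees) for one axis.
#' @param y Optional second axis; if given, `theta_i` is the 2-D
#'   inter-sample distance.
#' @return RMS in degrees, or NA with fewer than 2 valid samples.
#' @export
precision_rms <- function(x, y = NULL) {
  if (is.null(y)) {
    d2 <- diff(x)^2
  } else {
    d2 <- diff(x)^2 + diff(y)^2
  }
  d2 <- d2[!is.na(d2)]
  if (length(d2) < 1L) return(NA_real_)
  sqrt(mean(d2))
}

#' Precision: standard deviation of samples
#'
#' Dispersion of the gaze samples per axis during steady fixation. Less
#' dependent on sampling rate than [precision_rms()].
#'
#' @param x Gaze samples (degrees) for one axis; NAs dropped.
#' @return SD in degrees, NA with fewer than 2 valid samples.
#' @export
precision_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

#' Accuracy: mean offset from the true target position
#'
#' Mean Euclidean distance between the measured gaze samples and the true
#' stimulus position, plus per-axis mean offsets. The caller supplies a
#' fixation interval free of saccades and blinks.
#'
#' @param x,y Gaze samples, degrees (NA pairs dropped).
#' @param target Named `c(h=, v=)` true target position, degrees.
#' @return List `euclidean`, `h`, `v` (degrees); NAs for an empty interval.
#' @export
accuracy <- function(x, y, target) {
  ok <- stats::complete.cases(x, y)
  if (!any(ok)) return(list(euclidean = NA_real_, h = NA_real_, v = NA_real_))
  ex <- x[ok] - target[["h"]]; ey <- y[ok] - target[["v"]]
  list(euclidean = mean(sqrt(ex^2 + ey^2)), h = mean(ex), v = mean(ey))
}

#' Split a trace into fixed-length epochs
#'
#' Consecutive non-overlapping spans of `round(epoch_s * frame_rate)`
#' samples; the trailing partial epoch is dropped. 15 s at 395 Hz gives 15
#' epochs of 395 samples.
#'
#' @param n Number of samples in the trace.
#' @param frame_rate Sampling rate, Hz.
#' @param epoch_s Epoch length, s (default 1).
#' @return List of index vectors (possibly empty).
#' @export
epoch_split <- function(n, frame_rate, epoch_s = 1) {
  len <- round(epoch_s * frame_rate)
  k <- n %/% len
  lapply(seq_len(k), function(i) ((i - 1L) * len + 1L):(i * len))
}

#' Epoch-averaged precision of a fixation trace
#'
#' Divides the trace into epochs ([epoch_split()]), computes
#' [precision_rms()] and [precision_sd()] per axis within each epoch, and
#' averages across epochs. Samples flagged as blinks are excluded together
#' with one sample on each side.
#'
#' @param x,y Gaze samples, degrees.
#' @param frame_rate Sampling rate, Hz.
#' @param epoch_s Epoch length, s (default 1).
#' @param blink Optional logical vector of blink flags.
#' @return List `rms_h`, `rms_v`, `sd_h`, `sd_v` (degrees), `n_epochs`.
#' @export
precision_report <- function(x, y, frame_rate, epoch_s = 1, blink = NULL) {
  if (!is.null(blink)) {
    bad <- blink | c(FALSE, blink[-length(blink)]) | c(blink[-1], FALSE)
    x[bad] <- NA; y[bad] <- NA
  }
  eps <- epoch_split(length(x), frame_rate, epoch_s)
  if (length(eps) == 0L) {
    return(list(rms_h = NA_real_, rms_v = NA_real_,
                sd_h = NA_real_, sd_v = NA_real_, n_epochs = 0L))
  }
  per <- vapply(eps, function(idx) {
    c(precision_rms(x[idx]), precision_rms(y[idx]),
      precision_sd(x[idx]), precision_sd(y[idx]))
  }, numeric(4))
  m <- rowMeans(per, na.rm = TRUE)
  list(rms_h = m[1], rms_v = m[2], sd_h = m[3], sd_v = m[4],
       n_epochs = length(eps))
}

# radial velocity by central differences, deg/s; no smoothing is applied
# anywhere (filters can alter the spectral content of fixation signals)
radial_velocity <- function(x, y, frame_rate) {
  n <- length(x)
  vx <- c(NA, (x[3:n] - x[1:(n - 2)]) * frame_rate / 2, NA)
  vy <- c(NA, (y[3:n] - y[1:(n - 2)]) * frame_rate / 2, NA)
  sqrt(vx^2 + vy^2)
}

#' Velocity-threshold event detection
#'
#' Simple saccade/microsaccade detector used as analysis plumbing: samples
#' whose unfiltered central-difference radial velocity exceeds
#' `velocity_threshold` for at least `min_duration_s` form an event;
#' events separated by less than 2 samples are merged. With unfiltered
#' data at the default noise level, velocity noise limits reliable
#' detection to amplitudes of roughly half a degree and above; smaller
#' events need an external detector.
#'
#' @param x,y Gaze trace, degrees (blinks excluded by the caller).
#' @param frame_rate Sampling rate, Hz.
#' @param velocity_threshold deg/s (default 30).
#' @param min_duration_s Minimum event duration, s (default 0.006).
#' @param merge_gap Merge events whose gap is below this many samples
#'   (default 2).
#' @return data.frame `onset`, `offset` (sample indices, 1-based,
#'   inclusive); zero rows when nothing is detected.
#' @export
detect_events_velocity <- function(x, y, frame_rate, velocity_threshold = 30,
                                   min_duration_s = 0.006, merge_gap = 2L) {
  v <- radial_velocity(x, y, frame_rate)
  above <- !is.na(v) & v > velocity_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  on <- starts[r$values]; off <- ends[r$values]
  if (length(on) > 1L) { # merge near-adjacent runs first
    keep_on <- on[1]; keep_off <- off[1]
    res_on <- integer(0); res_off <- integer(0)
    for (i in 2:length(on)) {
      if (on[i] - keep_off < merge_gap + 1L) {
        keep_off <- off[i]
      } else {
        res_on <- c(res_on, keep_on); res_off <- c(res_off, keep_off)
        keep_on <- on[i]; keep_off <- off[i]
      }
    }
    on <- c(res_on, keep_on); off <- c(res_off, keep_off)
  }
  n_min <- ceiling(min_duration_s * frame_rate)
  keep <- (off - on + 1L) >= n_min
  data.frame(onset = on[keep], offset = off[keep])
}

#' Metrics of one saccadic event
#'
#' Latency (event onset time minus stimulus onset), duration
#' (`(offset - onset) / frame_rate`), amplitude (Euclidean distance between
#' the start and end points) and peak velocity (maximum of the unfiltered
#' radial velocity inside the interval). With `endpoint_window > 1` the
#' start/end points are means of that many samples ending at the onset and
#' starting at the offset — an averaging refinement that removes the
#' noise-induced positive bias of single-sample amplitudes on small events.
#' Events touching the trace boundary are computed but flagged.
#'
#' @param x,y Gaze trace, degrees.
#' @param onset,offset Event interval, sample indices (1-based, inclusive).
#' @param frame_rate Sampling rate, Hz.
#' @param stimulus_onset_s Stimulus onset time (s) for the latency; the
#'   trace is taken to start at t = 0.
#' @param endpoint_window Samples averaged per endpoint (default 1, i.e.
#'   raw start/end samples).
#' @return List `onset`, `offset`, `latency_ms`, `duration_ms`,
#'   `amplitude_deg`, `peak_velocity`, `boundary`.
#' @export
event_metrics <- function(x, y, onset, offset, frame_rate,
                          stimulus_onset_s = NA_real_, endpoint_window = 1L) {
  n <- length(x)
  stopifnot(offset > onset, onset >= 1L, offset <= n)
  w <- as.integer(endpoint_window)
  pre <- max(1L, onset - w + 1L):onset
  post <- offset:min(n, offset + w - 1L)
  x0 <- mean(x[pre], na.rm = TRUE); y0 <- mean(y[pre], na.rm = TRUE)
  x1 <- mean(x[post], na.rm = TRUE); y1 <- mean(y[post], na.rm = TRUE)
  v <- radial_velocity(x, y, frame_rate)
  pv <- suppressWarnings(max(v[onset:offset], na.rm = TRUE))
  list(onset = onset, offset = offset,
       latency_ms = if (is.na(stimulus_onset_s)) NA_real_ else
         ((onset - 1L) / frame_rate - stimulus_onset_s) * 1000,
       duration_ms = (offset - onset) / frame_rate * 1000,
       amplitude_deg = sqrt((x1 - x0)^2 + (y1 - y0)^2),
       peak_velocity = if (is.finite(pv)) pv else NA_real_,
       boundary = onset <= 1L || offset >= n)
}
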