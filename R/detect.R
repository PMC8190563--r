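#' @title Pupil and Purkinje-image detection
#' @name detect
#' @description Per-frame feature detection by thresholding and center of
#'   mass. The dark pupil is every pixel below an adjustable fraction
#'   (default 0.6) of the mean region brightness; the first Purkinje image
#'   (corneal reflection) is every pixel at or above a fixed threshold of
#'   250, independent of mean brightness. Centers are intensity-agnostic
#'   centroids with full sub-pixel resolution; pupil radius follows
#'   `r = sqrt(area / pi)`.
NULL

# minimum blob areas at the reference optics, scaled by (magnification/39.7)^2
min_pupil_area <- function(cfg) 500 * (cfg$magnification / 39.7)^2
min_cr_area <- function(cfg) 20 * (cfg$magnification / 39.7)^2

as_roi <- function(roi, w, h) {
  if (is.null(roi)) return(c(0L, 0L, w - 1L, h - 1L))
  roi <- as.numeric(roi)
  if (length(roi) != 4L) stop("roi must be c(x0, y0, x1, y1), 0-based inclusive")
  if (roi[1] < 0 || roi[2] < 0 || roi[3] > w - 1 || roi[4] > h - 1 ||
      roi[1] > roi[3] || roi[2] > roi[4]) {
    stop("roi outside frame bounds")
  }
  round(roi)
}

invalid_detection <- function(threshold = NA_real_) {
  list(valid = FALSE, x = NA_real_, y = NA_real_, area = 0L,
       radius_px = NA_real_, bbox = NULL, threshold_used = threshold)
}

# 4-connected component labelling of a logical matrix via run-length
# encoding of columns (vectorised run finding) and union-find across
# adjacent columns. Returns NULL when all-FALSE, otherwise per-run
# col/row_s/row_e (1-based) and the component root of each run.
label_runs <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # pad a FALSE row on top of each column so runs never span column breaks
  v <- as.vector(rbind(FALSE, mask))
  d <- diff(c(FALSE, v, FALSE))
  starts <- which(d == 1L) # 1-based positions in v
  if (length(starts) == 0L) return(NULL)
  ends <- which(d == -1L) - 1L
  col <- (starts - 1L) %/% (nr + 1L) + 1L
  row_s <- (starts - 1L) %% (nr + 1L) # padded row offset = true row (1-based)
  row_e <- row_s + (ends - starts)
  nrun <- length(starts)
  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  first_of_col <- match(seq_len(nc), col)
  runs_in_col <- tabulate(col, nbins = nc)
  for (j in which(runs_in_col > 0 & c(0L, runs_in_col[-nc]) > 0)) {
    ia <- first_of_col[j - 1L] + 0:(runs_in_col[j - 1L] - 1L)
    ib <- first_of_col[j] + 0:(runs_in_col[j] - 1L)
    a <- 1L; b <- 1L
    while (a <= length(ia) && b <= length(ib)) {
      if (row_s[ia[a]] <= row_e[ib[b]] && row_s[ib[b]] <= row_e[ia[a]]) {
        ra <- find(ia[a]); rb <- find(ib[b]) # overlapping rows => 4-connected
        if (ra != rb) parent[rb] <- ra
      }
      if (row_e[ia[a]] < row_e[ib[b]]) a <- a + 1L else b <- b + 1L
    }
  }
  root <- vapply(seq_len(nrun), find, integer(1))
  list(col = col, row_s = row_s, row_e = row_e, root = root,
       nr = nr, nc = nc)
}

runs_to_mask <- function(runs, keep) {
  out <- matrix(FALSE, runs$nr, runs$nc)
  idx <- unlist(lapply(keep, function(k) {
    (runs$col[k] - 1L) * runs$nr + runs$row_s[k]:runs$row_e[k]
  }))
  out[idx] <- TRUE
  out
}

# largest 4-connected component
largest_component <- function(mask) {
  runs <- label_runs(mask)
  if (is.null(runs)) return(NULL)
  len <- runs$row_e - runs$row_s + 1L
  sizes <- vapply(split(len, runs$root), sum, integer(1))
  big <- as.integer(names(sizes)[which.max(sizes)])
  runs_to_mask(runs, which(runs$root == big))
}

# fill enclosed holes: complement components that do not touch the matrix
# border become part of the mask (used to re-fill the bright glint hole
# inside the pupil component so the centroid is not dragged off-center)
fill_holes <- function(mask) {
  runs <- label_runs(!mask)
  if (is.null(runs)) return(mask)
  touches <- runs$col == 1L | runs$col == runs$nc |
    runs$row_s == 1L | runs$row_e == runs$nr
  border_roots <- unique(runs$root[touches])
  holes <- which(!(runs$root %in% border_roots))
  if (length(holes) == 0L) return(mask)
  mask | runs_to_mask(runs, holes)
}

centroid_of_mask <- function(mask, x_off, y_off) {
  idx <- which(mask, arr.ind = TRUE)
  list(x = mean(idx[, 2] - 1L) + x_off, y = mean(idx[, 1] - 1L) + y_off,
       area = nrow(idx),
       bbox = c(min(idx[, 2]) - 1L + x_off, min(idx[, 1]) - 1L + y_off,
                max(idx[, 2]) - 1L + x_off, max(idx[, 1]) - 1L + y_off))
}

#' Detect the dark pupil in one frame
#'
#' Pixels inside the ROI strictly darker than
#' `threshold_factor * mean(ROI)` form the candidate pupil. By default the
#' largest 4-connected component is kept (`component = TRUE`), which makes
#' stray dark pixels elsewhere in the ROI harmless, and enclosed holes are
#' re-filled before the centroid is taken — the bright corneal reflection
#' punches a ~400 px hole into the pupil mask, and because the glint sits
#' off-center whenever the eye is rotated, an unfilled hole drags the
#' centroid by up to ~2% of the PC-CR vector (a gain error that calibration
#' would silently absorb). `component = FALSE` ("raw" mode) uses all
#' sub-threshold pixels verbatim, with no filling. The center is the
#' unweighted centroid; the radius follows from the pixel count as
#' `sqrt(area/pi)`.
#'
#' @param frame A `pccr_frame` (or plain integer matrix).
#' @param roi `c(x0, y0, x1, y1)` 0-based inclusive, or NULL for the full
#'   frame.
#' @param threshold_factor Fraction of the mean ROI brightness (default 0.6).
#' @param cfg An [optical_config()] (supplies magnification and minimum
#'   area).
#' @param component Keep only the largest connected component (default TRUE).
#' @return A list: `valid`, `x`, `y` (sub-pixel, 0-based), `area`,
#'   `radius_px`, `diameter_mm`, `bbox`, `threshold_used`.
#' @export
detect_pupil <- function(frame, roi = NULL, threshold_factor = 0.6,
                         cfg = optical_config(), component = TRUE) {
  pix <- if (inherits(frame, "pccr_frame")) frame$pixels else frame
  if (!(threshold_factor > 0 && threshold_factor < 1)) {
    stop("threshold_factor must be in (0, 1)")
  }
  r <- as_roi(roi, ncol(pix), nrow(pix))
  sub <- pix[(r[2]:r[4]) + 1L, (r[1]:r[3]) + 1L, drop = FALSE]
  thr <- threshold_factor * mean(sub)
  mask <- sub < thr
  if (!any(mask)) return(c(invalid_detection(thr), diameter_mm = NA_real_))
  if (component) {
    mask <- largest_component(mask)
    # fill the glint hole working only on the component's bounding box
    # (plus a 1-px FALSE margin so outside stays border-connected)
    rb <- range(which(rowSums(mask) > 0)); cb <- range(which(colSums(mask) > 0))
    r0 <- max(1L, rb[1] - 1L); r1 <- min(nrow(mask), rb[2] + 1L)
    c0 <- max(1L, cb[1] - 1L); c1 <- min(ncol(mask), cb[2] + 1L)
    mask[r0:r1, c0:c1] <- fill_holes(mask[r0:r1, c0:c1, drop = FALSE])
  }
  cen <- centroid_of_mask(mask, r[1], r[2])
  radius <- sqrt(cen$area / pi)
  list(valid = cen$area >= min_pupil_area(cfg),
       x = cen$x, y = cen$y, area = cen$area,
       radius_px = radius, diameter_mm = 2 * radius / cfg$magnification,
       bbox = cen$bbox, threshold_used = thr)
}

#' Detect the first Purkinje image (corneal reflection)
#'
#' Pixels at or above a fixed intensity threshold (default 250, independent
#' of mean brightness) inside the ROI. The pixel count doubles as a focus
#' score: a defocused CR spreads over more pixels.
#'
#' @param frame A `pccr_frame` or matrix.
#' @param roi Search window, `c(x0, y0, x1, y1)`; in the stream detector
#'   this is the pupil bounding box dilated by 50%.
#' @param threshold Fixed intensity threshold (default 250).
#' @param cfg An [optical_config()].
#' @return A list like [detect_pupil()]'s (without `diameter_mm`).
#' @export
detect_purkinje <- function(frame, roi = NULL, threshold = 250,
                            cfg = optical_config()) {
  pix <- if (inherits(frame, "pccr_frame")) frame$pixels else frame
  r <- as_roi(roi, ncol(pix), nrow(pix))
  sub <- pix[(r[2]:r[4]) + 1L, (r[1]:r[3]) + 1L, drop = FALSE]
  mask <- sub >= threshold
  if (!any(mask)) return(invalid_detection(threshold))
  cen <- centroid_of_mask(mask, r[1], r[2])
  list(valid = cen$area >= min_cr_area(cfg),
       x = cen$x, y = cen$y, area = cen$area,
       radius_px = sqrt(cen$area / pi), bbox = cen$bbox,
       threshold_used = threshold)
}

#' PC-CR vector
#'
#' Componentwise difference pupil center minus CR center, in pixels.
#' Translation-invariant: shifting the whole frame moves both features
#' equally and leaves the vector unchanged. Invalid input detections
#' propagate to an invalid result.
#'
#' @param pupil,cr Detections from [detect_pupil()] / [detect_purkinje()].
#' @return A list `dx`, `dy`, `valid`.
#' @export
pcr_vector <- function(pupil, cr) {
  if (!isTRUE(pupil$valid) || !isTRUE(cr$valid)) {
    return(list(dx = NA_real_, dy = NA_real_, valid = FALSE))
  }
  list(dx = pupil$x - cr$x, dy = pupil$y - cr$y, valid = TRUE)
}

# dilate a bbox (x0,y0,x1,y1) by 50% of its size, clipped to the frame
dilate_bbox <- function(bbox, w, h, factor = 0.5) {
  bw <- bbox[3] - bbox[1]; bh <- bbox[4] - bbox[2]
  c(max(0, floor(bbox[1] - factor * bw / 2)), max(0, floor(bbox[2] - factor * bh / 2)),
    min(w - 1, ceiling(bbox[3] + factor * bw / 2)), min(h - 1, ceiling(bbox[4] + factor * bh / 2)))
}

#' Detect pupil and CR in one frame
#'
#' Runs [detect_pupil()] on the ROI, then [detect_purkinje()] inside the
#' pupil's bounding box dilated by 50% (keeping specular artifacts elsewhere
#' from capturing the CR centroid), and forms the PC-CR vector.
#'
#' @inheritParams detect_pupil
#' @return A one-row data.frame: `frame_index`, `time_s`, `camera_id`,
#'   `pupil_x`, `pupil_y`, `pupil_area`, `pupil_mm`, `cr_x`, `cr_y`,
#'   `cr_area`, `dx`, `dy`, `valid`, `threshold_used`.
#' @export
detect_frame <- function(frame, roi = NULL, threshold_factor = 0.6,
                         cfg = optical_config(), component = TRUE) {
  pix <- if (inherits(frame, "pccr_frame")) frame$pixels else frame
  pup <- detect_pupil(frame, roi, threshold_factor, cfg, component)
  cr <- if (isTRUE(pup$valid)) {
    detect_purkinje(frame, dilate_bbox(pup$bbox, ncol(pix), nrow(pix)), cfg = cfg)
  } else {
    invalid_detection(250)
  }
  v <- pcr_vector(pup, cr)
  data.frame(
    frame_index = if (inherits(frame, "pccr_frame")) frame$frame_index else NA_integer_,
    time_s = if (inherits(frame, "pccr_frame")) frame$time_s else NA_real_,
    camera_id = if (inherits(frame, "pccr_frame")) frame$camera_id else NA_character_,
    pupil_x = pup$x, pupil_y = pup$y, pupil_area = pup$area,
    pupil_mm = if (isTRUE(pup$valid)) pup$diameter_mm else NA_real_,
    cr_x = cr$x, cr_y = cr$y, cr_area = cr$area,
    dx = v$dx, dy = v$dy, valid = v$valid,
    threshold_used = pup$threshold_used
  )
}

# ROI tracking state machine: full frame on the first frame (and after any
# invalid frame), otherwise a box centred on the last pupil center with side
# 3x the last pupil diameter.
next_roi <- function(det, cfg) {
  if (!isTRUE(det$valid)) return(NULL)
  side <- 3 * det$pupil_mm * cfg$magnification
  c(max(0, floor(det$pupil_x - side / 2)), max(0, floor(det$pupil_y - side / 2)),
    min(cfg$frame_width - 1, ceiling(det$pupil_x + side / 2)),
    min(cfg$frame_height - 1, ceiling(det$pupil_y + side / 2)))
}

#' Detect features across a frame stream
#'
#' Applies [detect_frame()] to a list of frames with ROI tracking: the
#' first frame is searched in full; afterwards the ROI is a box centred on
#' the last pupil center (side = 3 pupil diameters), re-seeded from the
#' full frame after any invalid frame.
#'
#' @param frames List of `pccr_frame`s (one camera).
#' @inheritParams detect_pupil
#' @return A data.frame with one row per frame (see [detect_frame()]).
#' @export
detect_stream <- function(frames, cfg = optical_config(),
                          threshold_factor = 0.6, component = TRUE) {
  roi <- NULL
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    det <- detect_frame(frames[[i]], roi, threshold_factor, cfg, component)
    out[[i]] <- det
    roi <- next_roi(det, cfg)
  }
  do.call(rbind, out)
}

#' Streaming detector for use as a simulation sink
#'
#' Returns a closure suitable as the `sink` of [simulate_protocol()]: it
#' detects both eyes frame-by-frame (so frames never need to be retained)
#' and accumulates the per-frame results, retrievable with `$results()` as
#' a list with `left` and `right` detection tables.
#'
#' @inheritParams detect_pupil
#' @return A list: `sink` (the callback) and `results` (accessor).
#' @export
detect_sink <- function(cfg = optical_config(), threshold_factor = 0.6,
                        component = TRUE) {
  rows_l <- list(); rows_r <- list()
  roi_l <- NULL; roi_r <- NULL
  sink <- function(frame_left, frame_right, truth_row) {
    if (!is.null(frame_left)) {
      dl <- detect_frame(frame_left, roi_l, threshold_factor, cfg, component)
      roi_l <<- next_roi(dl, cfg)
      rows_l[[length(rows_l) + 1L]] <<- dl
    }
    if (!is.null(frame_right)) {
      dr <- detect_frame(frame_right, roi_r, threshold_factor, cfg, component)
      roi_r <<- next_roi(dr, cfg)
      rows_r[[length(rows_r) + 1L]] <<- dr
    }
  }
  results <- function() list(left = if (length(rows_l)) do.call(rbind, rows_l) else NULL,
                             right = if (length(rows_r)) do.call(rbind, rows_r) else NULL)
  list(sink = sink, results = results)
}
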