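# ROI handling: an ROI is NULL (whole frame), a logical mask, or a 0-based
# half-open pixel rectangle c(x0, y0, x1, y1).
roi_to_mask <- function(roi, dims) {
  if (is.null(roi)) return(matrix(TRUE, dims[1], dims[2]))
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == dims)) stop_cofi("ROI mask does not match the frame")
    return(roi)
  }
  if (is.numeric(roi) && length(roi) == 4L) {
    x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
    if (x1 <= x0 || y1 <= y0) stop_cofi("empty ROI rectangle")
    m <- matrix(FALSE, dims[1], dims[2])
    rows <- seq.int(max(y0, 0) + 1L, min(y1, dims[1]))
    cols <- seq.int(max(x0, 0) + 1L, min(x1, dims[2]))
    m[rows, cols] <- TRUE
    return(m)
  }
  stop_cofi("ROI must be NULL, a logical mask, or c(x0, y0, x1, y1)")
}

resolve_background <- function(frame, mask, background) {
  if (identical(background, "min")) min(frame[mask])
  else if (identical(background, "none")) 0
  else if (is_scalar_num(background)) background
  else stop_cofi("`background` must be \"min\", \"none\", or a number")
}

#' Intensity-weighted centroid of a frame region
#'
#' Position (um, pixel-centre convention) of the intensity-weighted mean of
#' `max(frame - background, 0)` over the ROI. The default background is the
#' ROI minimum, robust for high-contrast targets.
#'
#' @param frame numeric matrix.
#' @param roi `NULL`, logical mask, or rectangle `c(x0, y0, x1, y1)`
#'   (0-based pixels, half-open).
#' @param pixel_pitch um per pixel.
#' @param background `"min"`, `"none"`, or a number (counts).
#' @return named vector `c(x_um, y_um)` with attribute `"mass"` (total
#'   background-subtracted intensity).
#' @export
centroid <- function(frame, roi = NULL, pixel_pitch = 1,
                     background = "min") {
  mask <- roi_to_mask(roi, dim(frame))
  if (!any(mask)) stop_cofi("ROI is empty")
  bg <- resolve_background(frame, mask, background)
  w <- pmax(frame - bg, 0) * mask
  mass <- sum(w)
  if (mass <= 0) stop_cofi("undefined centroid: no positive mass after background subtraction")
  xs <- px_coords(ncol(frame), pixel_pitch)
  ys <- px_coords(nrow(frame), pixel_pitch)
  out <- c(x_um = sum(w %*% xs) / mass,
           y_um = sum(ys %*% w) / mass)
  attr(out, "mass") <- mass
  out
}

circle_roi <- function(dims, center_um, radius_um, pitch) {
  xs <- px_coords(dims[2], pitch); ys <- px_coords(dims[1], pitch)
  outer((ys - center_um[2])^2, (xs - center_um[1])^2, `+`) <= radius_um^2
}

#' Greedy nearest-neighbour centroid tracking
#'
#' Tracks each object by computing, frame after frame, the intensity-weighted
#' centroid inside a circular window centred on the object's previous
#' position. Suitable for few, well-separated objects (window radius smaller
#' than the inter-object distance). A lost object (no positive mass in the
#' window) truncates its track with a warning.
#'
#' @param cube a [video_cube()].
#' @param initial_positions data.frame `(object_id, x_um, y_um)` at the first
#'   frame.
#' @param window_radius_um linking window radius, um.
#' @param background passed to [centroid()].
#' @return data.frame `(frame_index, time_ms, object_id, x_um, y_um,
#'   intensity)`; class `cofi_tracks`.
#' @export
track_nearest_neighbor <- function(cube, initial_positions,
                                   window_radius_um = 60,
                                   background = "min") {
  stopifnot(is.data.frame(initial_positions),
            all(c("object_id", "x_um", "y_um") %in% names(initial_positions)))
  ts <- cube_timestamps(cube)
  pitch <- attr(cube, "pixel_pitch")
  d <- dim(cube)
  rows <- list()
  for (o in seq_len(nrow(initial_positions))) {
    prev <- c(initial_positions$x_um[o], initial_positions$y_um[o])
    for (k in seq_len(d[3])) {
      roi <- circle_roi(d[1:2], prev, window_radius_um, pitch)
      pos <- tryCatch(centroid(cube[, , k], roi, pitch, background),
                      error = function(e) NULL)
      if (is.null(pos)) {
        warning(sprintf("object '%s' lost at frame %d; track truncated",
                        initial_positions$object_id[o], k - 1L))
        break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        frame_index = k - 1L, time_ms = ts[k],
        object_id = initial_positions$object_id[o],
        x_um = pos[["x_um"]], y_um = pos[["y_um"]],
        intensity = attr(pos, "mass"))
      prev <- c(pos[["x_um"]], pos[["y_um"]])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame_index = integer(0), time_ms = numeric(0),
               object_id = character(0), x_um = numeric(0),
               y_um = numeric(0), intensity = numeric(0))
  class(out) <- c("cofi_tracks", "data.frame")
  out
}

#' Constant-velocity fit of a track
#'
#' Ordinary least squares of each position axis against time; the speed is
#' the norm of the slope vector.
#'
#' @param track data.frame with `time_ms`, `x_um`, `y_um` (>= 3 points).
#' @return list: `speed_um_per_ms`, `direction` (unit vector), `slopes`,
#'   `stderr` (per-axis), `r_squared` (pooled over both axes; `NA` for a
#'   stationary track).
#' @export
fit_velocity <- function(track) {
  if (nrow(track) < 3L) stop_cofi("need at least 3 track points to fit a velocity")
  fx <- stats::lm(x_um ~ time_ms, data = track)
  fy <- stats::lm(y_um ~ time_ms, data = track)
  sx <- unname(stats::coef(fx)[2]); sy <- unname(stats::coef(fy)[2])
  speed <- sqrt(sx^2 + sy^2)
  sst <- sum((track$x_um - mean(track$x_um))^2) +
    sum((track$y_um - mean(track$y_um))^2)
  ssr <- sum(stats::resid(fx)^2) + sum(stats::resid(fy)^2)
  list(speed_um_per_ms = speed,
       direction = if (speed > 0) c(sx, sy) / speed else c(NA_real_, NA_real_),
       slopes = c(x = sx, y = sy),
       stderr = suppressWarnings(  # summary.lm warns on exact linear input
         c(x = summary(fx)$coefficients[2, 2],
           y = summary(fy)$coefficients[2, 2])),
       r_squared = if (sst > 0) 1 - ssr / sst else NA_real_)
}

#' Positional error of measured centroids against preset ground truth
#'
#' For every frame and axis, the mean over objects (line pairs) of
#' measured minus preset position; the summary is the maximum over frames
#' and axes of the absolute mean error.
#'
#' @param measured data.frame `(frame_index, object_id, x_um, y_um)`.
#' @param preset ground-truth table with the same columns and indexing.
#' @return list: `table` (`frame_index, axis, mean_error_um`) and
#'   `max_abs_um`.
#' @export
positional_error <- function(measured, preset) {
  j <- merge(measured, preset, by = c("frame_index", "object_id"),
             suffixes = c("", "_ref"))
  missing_ids <- setdiff(paste(measured$frame_index, measured$object_id),
                         paste(j$frame_index, j$object_id))
  if (length(missing_ids)) {
    stop_cofi("unmatched (frame, object) pairs: ",
              paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  ex <- stats::aggregate(cbind(err = x_um - x_um_ref) ~ frame_index, j, mean)
  ey <- stats::aggregate(cbind(err = y_um - y_um_ref) ~ frame_index, j, mean)
  tab <- rbind(data.frame(frame_index = ex$frame_index, axis = "x",
                          mean_error_um = ex$err),
               data.frame(frame_index = ey$frame_index, axis = "y",
                          mean_error_um = ey$err))
  list(table = tab[order(tab$frame_index, tab$axis), ],
       max_abs_um = max(abs(tab$mean_error_um)))
}

#' Signal-to-background ratio
#'
#' The ratio of the mean intensity in the signal region to that in the
#' background region, with no background subtraction.
#'
#' @param image numeric matrix.
#' @param signal_roi,background_roi disjoint, non-empty ROIs (mask or
#'   rectangle, see [centroid()]).
#' @return list: `snr`, `signal_mean`, `background_mean`.
#' @export
snr <- function(image, signal_roi, background_roi) {
  ms <- roi_to_mask(signal_roi, dim(image))
  mb <- roi_to_mask(background_roi, dim(image))
  if (!any(ms) || !any(mb)) stop_cofi("ROIs must be non-empty")
  if (any(ms & mb)) stop_cofi("signal and background ROIs must be disjoint")
  smean <- mean(image[ms]); bmean <- mean(image[mb])
  if (bmean <= 0) stop_cofi("undefined SNR: background mean is not positive")
  list(snr = smean / bmean, signal_mean = smean, background_mean = bmean)
}

# Bilinear interpolation of a frame at physical positions (um).
interp_bilinear <- function(frame, x_um, y_um, pitch) {
  j <- x_um / pitch; i <- y_um / pitch   # 0-based fractional indices
  j <- pmin(pmax(j, 0), ncol(frame) - 1)
  i <- pmin(pmax(i, 0), nrow(frame) - 1)
  j0 <- pmin(floor(j), ncol(frame) - 2); i0 <- pmin(floor(i), nrow(frame) - 2)
  fj <- j - j0; fi <- i - i0
  f00 <- frame[cbind(i0 + 1, j0 + 1)]
  f01 <- frame[cbind(i0 + 1, j0 + 2)]
  f10 <- frame[cbind(i0 + 2, j0 + 1)]
  f11 <- frame[cbind(i0 + 2, j0 + 2)]
  (1 - fi) * ((1 - fj) * f00 + fj * f01) + fi * ((1 - fj) * f10 + fj * f11)
}

#' Line-pair spacing to spatial frequency
#' @param spacing_um centre-to-centre line spacing, um.
#' @return line pairs per millimetre, `1000 / spacing_um`.
#' @export
spacing_to_lp_mm <- function(spacing_um) 1000 / spacing_um

#' Line-pair resolvability from modulation contrast
#'
#' Extracts the mean intensity profile across a bar group (perpendicular to
#' the bar orientation, averaged along the bars), measures the modulation
#' contrast `(mean peak - mean trough) / (mean peak + mean trough)` between
#' the preset line centres and the midpoints between lines, and counts local
#' maxima. The group is deemed resolvable if the contrast reaches the
#' threshold and the expected number of peaks is found. The spacing is also
#' converted to spatial frequency (lp/mm).
#'
#' @param frame numeric matrix.
#' @param center_um group centre `c(x, y)`, um.
#' @param orientation_deg bar long-axis angle, degrees from horizontal.
#' @param spacing_um centre-to-centre line spacing, um.
#' @param n_lines number of lines in the group.
#' @param pixel_pitch um per pixel.
#' @param avg_length_um length along the bars to average over.
#' @param threshold contrast threshold for the resolvable flag.
#' @return list: `spacing_um`, `contrast`, `n_peaks_expected`,
#'   `n_peaks_found`, `resolvable`, `lp_per_mm`, `profile` (data.frame
#'   `s_um`, `intensity`).
#' @export
resolvability <- function(frame, center_um, orientation_deg, spacing_um,
                          n_lines = 3L, pixel_pitch = 1,
                          avg_length_um = NULL, threshold = 0.1) {
  th <- orientation_deg * pi / 180
  along <- c(cos(th), sin(th)); perp <- c(-sin(th), cos(th))
  half_span <- (n_lines / 2 + 0.5) * spacing_um
  if (is.null(avg_length_um)) avg_length_um <- 2 * spacing_um
  s <- seq(-half_span, half_span, by = spacing_um / 40)
  if (length(s) < 41L) stop_cofi("profile shorter than one line period")
  a <- seq(-avg_length_um / 2, avg_length_um / 2, length.out = 9L)
  prof <- vapply(s, function(si) {
    xs <- center_um[1] + si * perp[1] + a * along[1]
    ys <- center_um[2] + si * perp[2] + a * along[2]
    mean(interp_bilinear(frame, xs, ys, pixel_pitch))
  }, numeric(1))
  prof0 <- prof - min(prof)
  line_offs <- (seq_len(n_lines) - (n_lines + 1) / 2) * spacing_um
  trough_offs <- (line_offs[-1] + line_offs[-n_lines]) / 2
  at <- function(offs) vapply(offs, function(o) prof0[which.min(abs(s - o))],
                              numeric(1))
  pk <- mean(at(line_offs)); tr <- mean(at(trough_offs))
  contrast <- if (pk + tr > 0) (pk - tr) / (pk + tr) else 0
  # local maxima within the group span, on a lightly smoothed profile
  sm <- stats::filter(prof0, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- prof0[is.na(sm)]
  interior <- which(s >= min(line_offs) - spacing_um / 2 &
                      s <= max(line_offs) + spacing_um / 2)
  n_peaks <- 0L
  if (length(interior) > 2L) {
    ii <- interior[-c(1L, length(interior))]
    n_peaks <- sum(sm[ii] > sm[ii - 1L] & sm[ii] >= sm[ii + 1L] &
                     sm[ii] > 0.05 * max(prof0))
  }
  list(spacing_um = spacing_um, contrast = contrast,
       n_peaks_expected = as.integer(n_lines), n_peaks_found = n_peaks,
       resolvable = contrast >= threshold && n_peaks == n_lines,
       lp_per_mm = spacing_to_lp_mm(spacing_um),
       profile = data.frame(s_um = s, intensity = prof))
}

#' Space-bandwidth-time product
#'
#' Effective number of resolved pixels multiplied by the frame rate
#' (pixels/s), the throughput figure of merit of a high-speed imager.
#'
#' @param effective_pixels effective resolved pixel count, > 0.
#' @param frames_per_second frame rate, > 0.
#' @return SBTP in pixels/s.
#' @export
sbtp <- function(effective_pixels, frames_per_second) {
  if (!is_scalar_num(effective_pixels) || effective_pixels <= 0 ||
      !is_scalar_num(frames_per_second) || frames_per_second <= 0) {
    stop_cofi("both arguments must be positive")
  }
  effective_pixels * frames_per_second
}

#' Measure line-pair centroids in rotated band windows
#'
#' For each preset bar centre, computes the intensity-weighted centroid
#' within a band aligned with the bar: pixels within half a spacing of the
#' bar's centre line (perpendicular) and within half the bar length (along).
#' The band is symmetric about the preset line, so a perfectly reconstructed
#' bar yields zero positional error while reconstruction artefacts shift the
#' measured centroid.
#'
#' @param frame numeric matrix.
#' @param bars data.frame `(object_id, spacing_um, x_um, y_um)` of preset
#'   bar centres in this frame.
#' @param orientation_deg bar long-axis angle, degrees.
#' @param bar_length_um bar length, um.
#' @param pixel_pitch um per pixel.
#' @param background passed to [centroid()].
#' @return data.frame `(object_id, x_um, y_um)`.
#' @export
measure_bar_centroids <- function(frame, bars, orientation_deg, bar_length_um,
                                  pixel_pitch, background = "min") {
  th <- orientation_deg * pi / 180
  along <- c(cos(th), sin(th)); perp <- c(-sin(th), cos(th))
  xs <- px_coords(ncol(frame), pixel_pitch)
  ys <- px_coords(nrow(frame), pixel_pitch)
  X <- matrix(xs, nrow(frame), ncol(frame), byrow = TRUE)
  Y <- matrix(ys, nrow(frame), ncol(frame))
  out <- bars[, "object_id", drop = FALSE]
  out$x_um <- out$y_um <- NA_real_
  for (b in seq_len(nrow(bars))) {
    dx <- X - bars$x_um[b]; dy <- Y - bars$y_um[b]
    p <- dx * perp[1] + dy * perp[2]
    a <- dx * along[1] + dy * along[2]
    mask <- abs(p) < bars$spacing_um[b] / 2 & abs(a) <= bar_length_um / 2
    pos <- centroid(frame, mask, pixel_pitch, background)
    out$x_um[b] <- pos[["x_um"]]; out$y_um[b] <- pos[["y_um"]]
  }
  out[, c("object_id", "x_um", "y_um")]
}
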