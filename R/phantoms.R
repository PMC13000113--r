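#' Scene specification for synthetic phantoms
#'
#' Defines the physical coordinate grid all phantoms are rendered on. The
#' field of view is derived as `grid * pixel_pitch` on each axis, so the
#' invariant pitch x pixels = extent holds by construction. The default grid
#' (128 x 160 pixels at 15 um pitch) spans a 1.92 mm x 2.4 mm field of view,
#' the scale of a mesoscopic fluorescence macroscope.
#'
#' Coordinate convention (used by every module): pixel indices are 0-based;
#' physical positions are in micrometres measured from the centre of the
#' top-left pixel, x along columns (rightward), y along rows (downward);
#' time is in milliseconds from the start of the snapshot exposure.
#'
#' Intensities are expected photoelectron counts, so the Poisson sensor
#' model in [add_sensor_noise()] applies directly.
#'
#' @param grid integer vector `c(height, width)` in pixels.
#' @param pixel_pitch pixel pitch in micrometres.
#' @param supersampling integer >= 1; shapes are rasterized on a grid finer
#'   by this factor and mean-binned to the target grid (antialiasing).
#' @param duration scene duration in milliseconds.
#' @param background constant background level, counts.
#' @param seed integer seed attached to the scene (phantom rendering itself
#'   is deterministic; the seed is carried for provenance).
#' @return An object of class `cofi_scene_spec`.
#' @export
scene_spec <- function(grid = c(128L, 160L), pixel_pitch = 15,
                       supersampling = 4L, duration = 6,
                       background = 5, seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L)) {
    stop_cofi("`grid` must be two positive integers c(height, width)")
  }
  if (!is_scalar_num(pixel_pitch) || pixel_pitch <= 0) {
    stop_cofi("`pixel_pitch` must be a positive number (um)")
  }
  supersampling <- as.integer(supersampling)
  if (supersampling < 1L) stop_cofi("`supersampling` must be >= 1")
  if (!is_scalar_num(duration) || duration <= 0) {
    stop_cofi("`duration` must be positive (ms)")
  }
  if (!is_scalar_num(background) || background < 0) {
    stop_cofi("`background` must be >= 0")
  }
  structure(list(
    grid = grid,
    pixel_pitch = pixel_pitch,
    field_of_view = grid * pixel_pitch,  # (height_um, width_um)
    supersampling = supersampling,
    duration = duration,
    background = background,
    seed = as.integer(seed)
  ), class = "cofi_scene_spec")
}

#' @export
print.cofi_scene_spec <- function(x, ...) {
  cat(sprintf(
    "<cofi_scene_spec> %d x %d px @ %g um (FOV %.3g x %.3g mm), ss %d, %g ms, bg %g\n",
    x$grid[1], x$grid[2], x$pixel_pitch,
    x$field_of_view[1] / 1000, x$field_of_view[2] / 1000,
    x$supersampling, x$duration, x$background))
  invisible(x)
}

#' Time-ordered intensity video cube
#'
#' A 3-D array of nonnegative frames, dimension `c(height, width, n_frames)`,
#' with per-frame timestamps (ms) and the pixel pitch (um) attached.
#'
#' @param data numeric 3-D array (or a matrix, treated as one frame).
#' @param timestamps numeric vector of frame times in ms, strictly increasing.
#' @param pixel_pitch pixel pitch in um.
#' @return `cofi_cube` object (the array with attributes).
#' @export
video_cube <- function(data, timestamps, pixel_pitch) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_cofi("`data` must be a height x width x frames array")
  }
  if (length(timestamps) != dim(data)[3]) {
    stop_cofi("length(timestamps) must equal the number of frames")
  }
  if (any(diff(timestamps) <= 0)) {
    stop_cofi("`timestamps` must be strictly increasing")
  }
  if (any(!is.finite(data))) stop_cofi("cube contains non-finite values")
  structure(data, timestamps = as.numeric(timestamps),
            pixel_pitch = pixel_pitch, class = c("cofi_cube", "array"))
}

#' @export
print.cofi_cube <- function(x, ...) {
  d <- dim(x)
  ts <- attr(x, "timestamps")
  cat(sprintf("<cofi_cube> %d x %d x %d frames, t = [%g, %g] ms, pitch %g um\n",
              d[1], d[2], d[3], min(ts), max(ts), attr(x, "pixel_pitch")))
  invisible(x)
}

#' Frame timestamps of a cube
#' @param cube a [video_cube()].
#' @return numeric vector of times in ms.
#' @export
cube_timestamps <- function(cube) attr(cube, "timestamps")

# Mean-bin a supersampled matrix (dims H*s x W*s) down to H x W.
# Conserves flux: sum(binned) == sum(M)/s^2.
bin_supersampled <- function(M, s) {
  if (s == 1L) return(M)
  H <- nrow(M) %/% s
  W <- ncol(M) %/% s
  a <- array(M, c(s, H, s * W))
  cm <- colMeans(a)                      # H x (s*W), averaged over row blocks
  a2 <- array(cm, c(H, s, W))
  colMeans(aperm(a2, c(2, 1, 3)))        # average over column blocks -> H x W
}

# Supersampled pixel-centre coordinate vectors (um) for a spec axis.
ss_coords <- function(n, pitch, s) {
  ((seq_len(n * s) - 1) + 0.5) / s * pitch - pitch / 2
}

# Target-grid pixel-centre coordinates (um), 0-based convention.
px_coords <- function(n, pitch) (seq_len(n) - 1) * pitch

#' Moving-object trajectory description
#'
#' @param shape one of `"ellipse"`, `"circle"`, `"disk"`.
#' @param position_fn function mapping time (ms) to `c(x_um, y_um)` centre.
#' @param intensity peak emission level added on top of the background.
#' @param diameter_um diameter for `circle`/`disk`, um.
#' @param axes_um semi-axes `c(a, b)` for `ellipse`, um.
#' @param orientation_deg orientation of the ellipse major axis, degrees from
#'   horizontal (x axis), measured toward +y (image-down).
#' @param id object identifier used in ground-truth tables.
#' @return `cofi_object` description.
#' @export
object_trajectory <- function(shape = c("ellipse", "circle", "disk"),
                              position_fn, intensity = 500,
                              diameter_um = NULL, axes_um = NULL,
                              orientation_deg = 0, id = NULL) {
  shape <- match.arg(shape)
  if (!is.function(position_fn)) stop_cofi("`position_fn` must be a function(t_ms)")
  if (!is_scalar_num(intensity) || intensity < 0) stop_cofi("`intensity` must be >= 0")
  if (shape == "ellipse") {
    if (is.null(axes_um) || length(axes_um) != 2L || any(axes_um <= 0)) {
      stop_cofi("ellipse needs `axes_um = c(a, b)` with positive semi-axes")
    }
  } else {
    if (is.null(diameter_um) || !is_scalar_num(diameter_um) || diameter_um <= 0) {
      stop_cofi(shape, " needs a positive `diameter_um`")
    }
  }
  structure(list(shape = shape, position_fn = position_fn,
                 intensity = intensity, diameter_um = diameter_um,
                 axes_um = axes_um, orientation_deg = orientation_deg,
                 id = id %||% shape),
            class = "cofi_object")
}

# Rasterize one object at time t onto preallocated supersampled coord
# matrices X, Y (um). Returns the indicator * intensity contribution.
rasterize_object <- function(obj, t, X, Y) {
  p <- obj$position_fn(t)
  dx <- X - p[1]
  dy <- Y - p[2]
  inside <- switch(obj$shape,
    circle = ,
    disk = (dx * dx + dy * dy) <= (obj$diameter_um / 2)^2,
    ellipse = {
      th <- obj$orientation_deg * pi / 180
      a <- obj$axes_um[1]; b <- obj$axes_um[2]
      xr <- dx * cos(th) + dy * sin(th)
      yr <- -dx * sin(th) + dy * cos(th)
      (xr / a)^2 + (yr / b)^2 <= 1
    })
  obj$intensity * inside
}

check_timestamps_domain <- function(timestamps, duration) {
  if (length(timestamps) == 0L) stop_cofi("`timestamps` must be non-empty")
  if (any(diff(timestamps) <= 0)) stop_cofi("`timestamps` must be strictly increasing")
  bad <- timestamps[timestamps < 0 | timestamps > duration]
  if (length(bad)) {
    stop_cofi(sprintf("timestamp %g ms outside trajectory domain [0, %g]",
                      bad[1], duration))
  }
}

#' Continuous scene of moving shaped objects
#'
#' Returns a continuous-time scene (renderable at any time within the scene
#' duration) of antialiased shaped objects following preset trajectories, the
#' building block of the cell-motion tracking benchmark. Use
#' [render_moving_objects()] for a frame stack at fixed timestamps, or
#' [sample_scene_on_schedule()] to integrate it over coded exposure windows.
#'
#' @param spec a [scene_spec()].
#' @param objects list of [object_trajectory()] descriptions.
#' @return `cofi_scene`: a list with `spec`, `render(t)` (returns one frame),
#'   and `ground_truth(t)` (data.frame of preset object centres).
#' @export
moving_objects_scene <- function(spec, objects) {
  stopifnot(inherits(spec, "cofi_scene_spec"))
  if (!length(objects)) stop_cofi("`objects` must be non-empty")
  for (o in objects) stopifnot(inherits(o, "cofi_object"))
  s <- spec$supersampling
  xs <- ss_coords(spec$grid[2], spec$pixel_pitch, s)
  ys <- ss_coords(spec$grid[1], spec$pixel_pitch, s)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  render <- function(t) {
    check_timestamps_domain(t, spec$duration)
    acc <- matrix(0, nrow(X), ncol(X))
    for (o in objects) acc <- acc + rasterize_object(o, t, X, Y)
    bin_supersampled(acc, s) + spec$background
  }
  ground_truth <- function(t) {
    pos <- t(vapply(objects, function(o) o$position_fn(t), numeric(2)))
    data.frame(object_id = vapply(objects, `[[`, character(1), "id"),
               x_um = pos[, 1], y_um = pos[, 2])
  }
  structure(list(spec = spec, render = render, ground_truth = ground_truth),
            class = "cofi_scene")
}

# Collect per-frame ground-truth centroids into the standard table.
gt_table <- function(scene, timestamps) {
  do.call(rbind, lapply(seq_along(timestamps), function(i) {
    g <- scene$ground_truth(timestamps[i])
    cbind(data.frame(frame_index = i - 1L, time_ms = timestamps[i]), g)
  }))
}

render_scene_frames <- function(scene, timestamps) {
  check_timestamps_domain(timestamps, scene$spec$duration)
  frames <- lapply(timestamps, scene$render)
  cube <- array(unlist(frames, use.names = FALSE),
                c(scene$spec$grid, length(timestamps)))
  video_cube(cube, timestamps, scene$spec$pixel_pitch)
}

#' Render moving shaped objects at fixed timestamps
#'
#' @inheritParams moving_objects_scene
#' @param timestamps frame times, ms, strictly increasing, within the scene
#'   duration.
#' @return A [video_cube()] with attribute `"centroids"`: the ground-truth
#'   table `(frame_index, time_ms, object_id, x_um, y_um)`.
#' @export
render_moving_objects <- function(spec, objects, timestamps) {
  scene <- moving_objects_scene(spec, objects)
  cube <- render_scene_frames(scene, timestamps)
  attr(cube, "centroids") <- gt_table(scene, timestamps)
  cube
}

#' Translating three-group line-pair resolution target
#'
#' A resolution test pattern of parallel bar groups (bar width = half the
#' centre-to-centre spacing, i.e. a 50% duty square-wave profile across the
#' group) oriented at a fixed angle and translating rigidly at constant
#' velocity, emulating a projected bar target swept across the field of view.
#'
#' @inheritParams moving_objects_scene
#' @param spacings_um centre-to-centre line spacings, one per group (um).
#' @param orientation_deg bar long-axis angle from horizontal, degrees.
#' @param velocity_um_per_ms `c(vx, vy)` rigid translation velocity.
#' @param n_lines lines per group.
#' @param bar_length_um bar length along its long axis (um).
#' @param group_centers_um optional 2-column matrix of group centres at t = 0
#'   (um); defaults to three centres spread along the horizontal midline.
#' @param intensity bar peak emission above background.
#' @return `cofi_scene` with `bars`: a table of per-bar identifiers,
#'   `(object_id, group, spacing_um, x0_um, y0_um)`, giving t = 0 centres.
#' @export
bar_target_scene <- function(spec, spacings_um = c(45.6, 60.8, 76),
                             orientation_deg = 45,
                             velocity_um_per_ms = c(-5, 5),
                             n_lines = 3L, bar_length_um = 150,
                             group_centers_um = NULL, intensity = 500) {
  stopifnot(inherits(spec, "cofi_scene_spec"))
  if (any(spacings_um <= 0)) stop_cofi("spacings must be positive")
  min_res <- 2 * spec$pixel_pitch / spec$supersampling
  if (any(spacings_um < min_res)) {
    stop_cofi(sprintf(
      "spacing %g um unresolvable on the supersampled grid (need >= %g um)",
      min(spacings_um), min_res))
  }
  fov_w <- spec$field_of_view[2]; fov_h <- spec$field_of_view[1]
  if (is.null(group_centers_um)) {
    group_centers_um <- cbind(fov_w * seq(0.28, 0.72, length.out = length(spacings_um)),
                              rep(fov_h * 0.45, length(spacings_um)))
  }
  th <- orientation_deg * pi / 180
  along <- c(cos(th), sin(th))          # bar long axis
  perp <- c(-sin(th), cos(th))          # across the bars
  # Per-bar centres at t = 0: lines offset along `perp` by the spacing.
  bars <- do.call(rbind, lapply(seq_along(spacings_um), function(g) {
    sp <- spacings_um[g]
    offs <- (seq_len(n_lines) - (n_lines + 1) / 2) * sp
    data.frame(object_id = sprintf("g%d_l%d", g, seq_len(n_lines)),
               group = g, spacing_um = sp,
               x0_um = group_centers_um[g, 1] + offs * perp[1],
               y0_um = group_centers_um[g, 2] + offs * perp[2])
  }))
  s <- spec$supersampling
  xs <- ss_coords(spec$grid[2], spec$pixel_pitch, s)
  ys <- ss_coords(spec$grid[1], spec$pixel_pitch, s)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  render <- function(t) {
    check_timestamps_domain(t, spec$duration)
    shift <- velocity_um_per_ms * t
    acc <- matrix(0, nrow(X), ncol(X))
    for (b in seq_len(nrow(bars))) {
      dx <- X - (bars$x0_um[b] + shift[1])
      dy <- Y - (bars$y0_um[b] + shift[2])
      a <- dx * along[1] + dy * along[2]
      p <- dx * perp[1] + dy * perp[2]
      acc <- acc + (abs(p) <= bars$spacing_um[b] / 4) *
        (abs(a) <= bar_length_um / 2)
    }
    bin_supersampled(acc, s) * intensity + spec$background
  }
  ground_truth <- function(t) {
    shift <- velocity_um_per_ms * t
    data.frame(object_id = bars$object_id, group = bars$group,
               spacing_um = bars$spacing_um,
               x_um = bars$x0_um + shift[1], y_um = bars$y0_um + shift[2])
  }
  structure(list(spec = spec, render = render, ground_truth = ground_truth,
                 bars = bars, orientation_deg = orientation_deg,
                 bar_length_um = bar_length_um,
                 velocity_um_per_ms = velocity_um_per_ms),
            class = "cofi_scene")
}

#' Render the translating bar target
#'
#' @inheritParams bar_target_scene
#' @param timestamps frame times (ms).
#' @param ... passed on to [bar_target_scene()].
#' @return [video_cube()] with attribute `"centroids"`: ground-truth per-bar
#'   centres `(frame_index, time_ms, object_id, group, spacing_um, x_um, y_um)`.
#' @export
render_bar_target <- function(spec, spacings_um = c(45.6, 60.8, 76),
                              orientation_deg = 45,
                              velocity_um_per_ms = c(-5, 5),
                              timestamps, ...) {
  scene <- bar_target_scene(spec, spacings_um, orientation_deg,
                            velocity_um_per_ms, ...)
  cube <- render_scene_frames(scene, timestamps)
  attr(cube, "centroids") <- gt_table(scene, timestamps)
  attr(cube, "bars") <- scene$bars
  cube
}

#' Mono-exponentially decaying region
#'
#' @param mask logical matrix on the scene grid: where the species sits.
#' @param lifetime_ms decay constant tau, ms (> 0).
#' @param amplitude initial emission amplitude at t = 0, counts.
#' @param id region identifier.
#' @return `cofi_region`.
#' @export
decay_region <- function(mask, lifetime_ms, amplitude = 500, id = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) stop_cofi("`mask` must be a logical matrix")
  if (!is_scalar_num(lifetime_ms) || lifetime_ms <= 0) {
    stop_cofi("`lifetime_ms` must be > 0")
  }
  if (!is_scalar_num(amplitude) || amplitude < 0) stop_cofi("`amplitude` must be >= 0")
  structure(list(mask = mask, lifetime_ms = lifetime_ms,
                 amplitude = amplitude, id = id %||% sprintf("tau%.3g", lifetime_ms)),
            class = "cofi_region")
}

#' Phosphorescence decay phantom
#'
#' Pixel intensity at time t (ms after the end of the excitation pulse) is
#' `background + sum over regions of amplitude * exp(-t / lifetime)` on each
#' region's support. Overlapping regions sum by default, emulating cross-talk
#' between species; set `allow_overlap = FALSE` to reject overlaps.
#'
#' @inheritParams moving_objects_scene
#' @param regions list of [decay_region()].
#' @param allow_overlap if `FALSE`, overlapping region masks are an error.
#' @return `cofi_scene` (render domain `[0, spec$duration]`).
#' @export
decay_phantom_scene <- function(spec, regions, allow_overlap = TRUE) {
  stopifnot(inherits(spec, "cofi_scene_spec"))
  if (!length(regions)) stop_cofi("`regions` must be non-empty")
  for (r in regions) {
    stopifnot(inherits(r, "cofi_region"))
    if (!all(dim(r$mask) == spec$grid)) {
      stop_cofi("region mask dimensions must match the scene grid")
    }
  }
  if (!allow_overlap && length(regions) > 1L) {
    tot <- Reduce(`+`, lapply(regions, function(r) r$mask * 1))
    if (any(tot > 1)) stop_cofi("region masks overlap and allow_overlap = FALSE")
  }
  render <- function(t) {
    if (t < 0) stop_cofi(sprintf("timestamp %g ms outside trajectory domain [0, %g]",
                                 t, spec$duration))
    acc <- matrix(spec$background, spec$grid[1], spec$grid[2])
    for (r in regions) {
      acc <- acc + r$amplitude * exp(-t / r$lifetime_ms) * r$mask
    }
    acc
  }
  structure(list(spec = spec, render = render, regions = regions,
                 ground_truth = function(t) {
                   data.frame(object_id = vapply(regions, `[[`, character(1), "id"),
                              lifetime_ms = vapply(regions, `[[`, numeric(1), "lifetime_ms"))
                 }),
            class = "cofi_scene")
}

#' Render the decay phantom at fixed timestamps
#'
#' @inheritParams decay_phantom_scene
#' @param timestamps times >= 0 (ms after excitation cut-off).
#' @return [video_cube()].
#' @export
render_decay_phantom <- function(spec, regions, timestamps, allow_overlap = TRUE) {
  scene <- decay_phantom_scene(spec, regions, allow_overlap)
  if (any(timestamps < 0)) stop_cofi("decay timestamps must be >= 0")
  frames <- lapply(timestamps, scene$render)
  video_cube(array(unlist(frames), c(spec$grid, length(timestamps))),
             timestamps, spec$pixel_pitch)
}

#' Disk-shaped region mask
#'
#' Convenience constructor for [decay_region()] masks: pixels whose centre
#' lies within `diameter_um / 2` of `center_um`.
#'
#' @inheritParams moving_objects_scene
#' @param center_um `c(x_um, y_um)` disk centre.
#' @param diameter_um disk diameter, um.
#' @return logical matrix on the scene grid.
#' @export
disk_mask <- function(spec, center_um, diameter_um) {
  xs <- px_coords(spec$grid[2], spec$pixel_pitch)
  ys <- px_coords(spec$grid[1], spec$pixel_pitch)
  outer((ys - center_um[2])^2, (xs - center_um[1])^2, `+`) <= (diameter_um / 2)^2
}

#' Three-region "cat head" decay phantom regions
#'
#' A head disk plus two ear disks, one decay species per region, in the
#' layout of a multi-species lifetime mold: ears upper-left and upper-right,
#' head centre-low. Defaults use the three species lifetimes 3.2, 4.5 and
#' 7.2 ms.
#'
#' @inheritParams moving_objects_scene
#' @param lifetimes_ms three decay constants (ear-left, ear-right, head), ms.
#' @param amplitude initial amplitude for every region, counts.
#' @return list of three [decay_region()] objects.
#' @export
cat_head_regions <- function(spec, lifetimes_ms = c(3.2, 4.5, 7.2),
                             amplitude = 500) {
  stopifnot(length(lifetimes_ms) == 3L)
  fw <- spec$field_of_view[2]; fh <- spec$field_of_view[1]
  head_d <- 0.45 * min(fw, fh)
  ear_d <- 0.22 * min(fw, fh)
  list(
    decay_region(disk_mask(spec, c(0.32 * fw, 0.30 * fh), ear_d),
                 lifetimes_ms[1], amplitude, id = "ear_left"),
    decay_region(disk_mask(spec, c(0.68 * fw, 0.30 * fh), ear_d),
                 lifetimes_ms[2], amplitude, id = "ear_right"),
    decay_region(disk_mask(spec, c(0.50 * fw, 0.62 * fh), head_d),
                 lifetimes_ms[3], amplitude, id = "head")
  )
}

#' Flowing-microsphere scene
#'
#' A uniform-brightness disk (the projection of a sphere of the given
#' diameter) translating along the channel axis (+x) at constant speed,
#' emulating a fluorescent microsphere in a straight microfluidic channel.
#'
#' @inheritParams moving_objects_scene
#' @param diameter_um sphere diameter (default the measured 10.14 um bead).
#' @param speed_um_per_ms constant flow speed along +x.
#' @param start_um `c(x, y)` position at t = 0; default places the sphere so
#'   it stays within the FOV over the scene duration.
#' @param intensity peak emission above background.
#' @param wrap if `TRUE`, positions wrap around the FOV instead of erroring
#'   when the sphere would exit.
#' @return `cofi_scene`.
#' @export
microsphere_scene <- function(spec, diameter_um = 10.14, speed_um_per_ms = 1.02,
                              start_um = NULL, intensity = 500, wrap = FALSE) {
  stopifnot(inherits(spec, "cofi_scene_spec"))
  if (!is_scalar_num(diameter_um) || diameter_um <= 0) {
    stop_cofi("`diameter_um` must be > 0")
  }
  fov_w <- spec$field_of_view[2]; fov_h <- spec$field_of_view[1]
  if (is.null(start_um)) {
    travel <- abs(speed_um_per_ms) * spec$duration
    start_um <- c((fov_w - travel) / 2, fov_h / 2)
  }
  r <- diameter_um / 2
  position <- function(t) {
    p <- c(start_um[1] + speed_um_per_ms * t, start_um[2])
    if (wrap) {
      p[1] <- ((p[1] + r) %% fov_w) - r  # keep continuity at the seam
    } else if (p[1] - r < -spec$pixel_pitch / 2 ||
               p[1] + r > fov_w - spec$pixel_pitch / 2) {
      stop_cofi(sprintf("microsphere exits the FOV at t = %g ms (wrap off)", t))
    }
    p
  }
  obj <- object_trajectory("disk", position_fn = position,
                           intensity = intensity, diameter_um = diameter_um,
                           id = "microsphere")
  moving_objects_scene(spec, list(obj))
}

#' Render the flowing microsphere
#'
#' @inheritParams microsphere_scene
#' @param timestamps frame times (ms).
#' @return [video_cube()] with ground-truth `"centroids"` attribute.
#' @export
render_microsphere_flow <- function(spec, diameter_um = 10.14,
                                    speed_um_per_ms = 1.02, timestamps,
                                    start_um = NULL, intensity = 500,
                                    wrap = FALSE) {
  scene <- microsphere_scene(spec, diameter_um, speed_um_per_ms,
                             start_um, intensity, wrap)
  cube <- render_scene_frames(scene, timestamps)
  attr(cube, "centroids") <- gt_table(scene, timestamps)
  cube
}
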