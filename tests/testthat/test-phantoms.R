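test_that("stationary symmetric object renders identical frames centred on its preset position", {
  spec <- small_spec()
  ctr <- c((spec$grid[2] - 1) / 2, (spec$grid[1] - 1) / 2) * spec$pixel_pitch
  obj <- object_trajectory("circle", diameter_um = 10 * spec$pixel_pitch,
                           position_fn = function(t) ctr, intensity = 100)
  cube <- render_moving_objects(spec, list(obj), c(0, 1, 2))
  expect_equal(dim(cube)[3], 3L)
  expect_identical(cube[, , 1], cube[, , 2])
  expect_identical(cube[, , 1], cube[, , 3])
  pos <- centroid(cube[, , 1], pixel_pitch = spec$pixel_pitch)
  expect_equal(unname(pos["x_um"]), ctr[1], tolerance = 1e-8)
  expect_equal(unname(pos["y_um"]), ctr[2], tolerance = 1e-8)
})

test_that("zero-intensity object yields a constant-background cube", {
  spec <- small_spec(background = 7)
  obj <- object_trajectory("circle", diameter_um = 50,
                           position_fn = function(t) c(200, 200),
                           intensity = 0)
  cube <- render_moving_objects(spec, list(obj), c(0, 3))
  expect_true(all(cube == 7))
})

test_that("rendered object centroids follow the preset linear trajectories", {
  spec <- small_spec()
  objs <- list(
    object_trajectory("circle", diameter_um = 60, intensity = 400,
                      position_fn = function(t) c(120 + 20 * t, 150 + 12 * t),
                      id = "circle"),
    object_trajectory("ellipse", axes_um = c(45, 25), orientation_deg = 30,
                      intensity = 400,
                      position_fn = function(t) c(470 - 15 * t, 350 - 10 * t),
                      id = "ellipse"))
  ts <- seq(0, by = 0.3, length.out = 20)
  cube <- render_moving_objects(spec, objs, ts)
  gt <- attr(cube, "centroids")
  expect_equal(nrow(gt), 40L)
  for (k in seq_along(ts)) {
    for (oid in c("circle", "ellipse")) {
      g <- gt[gt$frame_index == k - 1L & gt$object_id == oid, ]
      roi <- cofi:::circle_roi(dim(cube)[1:2], c(g$x_um, g$y_um), 55,
                               spec$pixel_pitch)
      pos <- centroid(cube[, , k], roi, spec$pixel_pitch)
      expect_lt(abs(pos[["x_um"]] - g$x_um), 0.25 * spec$pixel_pitch)
      expect_lt(abs(pos[["y_um"]] - g$y_um), 0.25 * spec$pixel_pitch)
    }
  }
})

test_that("rendering is deterministic and respects the trajectory domain", {
  spec <- small_spec()
  obj <- object_trajectory("circle", diameter_um = 40,
                           position_fn = function(t) c(200 + t, 200),
                           intensity = 300)
  c1 <- render_moving_objects(spec, list(obj), c(0, 1))
  c2 <- render_moving_objects(spec, list(obj), c(0, 1))
  expect_identical(unclass(c1)[], unclass(c2)[])
  expect_error(render_moving_objects(spec, list(obj), c(0, 7)),
               "outside trajectory domain")
  expect_error(render_moving_objects(spec, list(obj), c(1, 1)),
               "strictly increasing")
})

test_that("mean-binning conserves flux and intensities stay at or above background", {
  M <- matrix(runif(64 * 80), 64, 80)
  B <- cofi:::bin_supersampled(M, 4L)
  expect_equal(sum(B), sum(M) / 16, tolerance = 1e-12)
  spec <- small_spec(background = 5)
  obj <- object_trajectory("circle", diameter_um = 45,
                           position_fn = function(t) c(211.7, 187.3),
                           intensity = 250)
  cube <- render_moving_objects(spec, list(obj), 0)
  expect_true(all(is.finite(cube)))
  expect_true(all(cube >= 5))
})

test_that("axis-aligned bar group matches the analytic square-wave rasterization", {
  spec <- small_spec(supersampling = 4L)
  p <- spec$pixel_pitch
  sp <- 10 * p  # period 150 um, bar width 75 um
  cube <- render_bar_target(spec, spacings_um = sp, orientation_deg = 90,
                            velocity_um_per_ms = c(0, 0), timestamps = 0,
                            n_lines = 3L, bar_length_um = 300,
                            group_centers_um = matrix(c(300, 240), 1),
                            intensity = 100)
  # Oracle: per-pixel coverage of [x - p/2, x + p/2] by the bar intervals,
  # computed on the supersampled subpixel centres (exact for this renderer).
  bars_x <- 300 + c(-sp, 0, sp)
  row_y <- 240
  i_row <- round(row_y / p) + 1L
  xs <- cofi:::px_coords(spec$grid[2], p)
  s <- spec$supersampling
  coverage <- vapply(xs, function(x) {
    sub <- x - p / 2 + ((seq_len(s) - 0.5) / s) * p
    mean(vapply(sub, function(u) any(abs(u - bars_x) <= sp / 4), logical(1)))
  }, numeric(1))
  expect_equal(unname(cube[i_row, , 1]), coverage * 100 + spec$background,
               tolerance = 1e-10)
})

test_that("bar target translates rigidly and reports preset centroids", {
  spec <- small_spec()
  v <- c(-spec$pixel_pitch / 0.3, spec$pixel_pitch / 0.3)  # 1 px per 0.3 ms
  cube <- render_bar_target(spec, spacings_um = c(60.8, 76),
                            velocity_um_per_ms = v,
                            timestamps = c(0, 0.3, 0.6),
                            group_centers_um = cbind(c(250, 400), c(250, 250)))
  gt <- attr(cube, "centroids")
  d0 <- gt[gt$frame_index == 1L, c("x_um", "y_um")] -
    gt[gt$frame_index == 0L, c("x_um", "y_um")]
  expect_equal(unique(round(d0$x_um, 9)), v[1] * 0.3)
  expect_equal(unique(round(d0$y_um, 9)), v[2] * 0.3)
  # one-pixel shift: interior of frame 2 equals frame 1 shifted by (+1, -1) px
  f1 <- cube[, , 1]; f2 <- cube[, , 2]
  expect_equal(f2[2:31, 1:39], f1[1:30, 2:40], tolerance = 1e-9)
  # zero velocity: identical frames
  cz <- render_bar_target(spec, spacings_um = 76, velocity_um_per_ms = c(0, 0),
                          timestamps = c(0, 1, 2),
                          group_centers_um = matrix(c(300, 240), 1))
  expect_identical(cz[, , 1], cz[, , 3])
})

test_that("unresolvable bar spacing on the supersampled grid is a configuration error", {
  spec <- small_spec(supersampling = 1L)
  expect_error(bar_target_scene(spec, spacings_um = spec$pixel_pitch),
               "unresolvable")
})

test_that("decay phantom follows background + sum of exponentials, with scalar oracle", {
  spec <- small_spec(background = 2, duration = 30)
  m1 <- disk_mask(spec, c(200, 200), 150)
  m2 <- disk_mask(spec, c(280, 220), 150)  # overlaps m1
  r1 <- decay_region(m1, lifetime_ms = 7.2, amplitude = 300)
  r2 <- decay_region(m2, lifetime_ms = 3.2, amplitude = 200)
  cube <- render_decay_phantom(spec, list(r1, r2), c(0, 7.2))
  # t = 0: background + full amplitude
  expect_equal(cube[, , 1][m1 & !m2], rep(302, sum(m1 & !m2)))
  # t = tau: amplitude * exp(-1) in the pure region
  expect_equal(unique(round(cube[, , 2][m1 & !m2], 9)),
               round(2 + 300 * exp(-1), 9))
  # overlap: per-pixel scalar brute force
  for (t_idx in 1:2) {
    t <- c(0, 7.2)[t_idx]
    for (px in utils::head(which(m1 & m2), 3)) {
      expected <- 2 + 300 * exp(-t / 7.2) * m1[px] + 200 * exp(-t / 3.2) * m2[px]
      expect_equal(cube[, , t_idx][px], expected, tolerance = 1e-12)
    }
  }
  expect_error(decay_region(m1, lifetime_ms = -1), "must be > 0")
  expect_error(render_decay_phantom(spec, list(r1), c(-1, 0)), ">= 0")
  expect_error(decay_phantom_scene(spec, list(r1, r2), allow_overlap = FALSE),
               "overlap")
})

test_that("microsphere flow renders a sub-pixel-accurate translating disk", {
  spec <- small_spec(duration = 20, supersampling = 8L)
  ts <- seq(0.5, by = 1, length.out = 20)
  cube <- render_microsphere_flow(spec, diameter_um = 10.14,
                                  speed_um_per_ms = 1.02, timestamps = ts)
  gt <- attr(cube, "centroids")
  # preset displacement across the sequence: speed * elapsed time
  expect_equal(gt$x_um[20] - gt$x_um[1], 1.02 * 19, tolerance = 1e-9)
  # rendered centroid within a quarter pixel of the preset position
  for (k in c(1, 10, 20)) {
    g <- gt[gt$frame_index == k - 1L, ]
    roi <- cofi:::circle_roi(dim(cube)[1:2], c(g$x_um, g$y_um), 40,
                             spec$pixel_pitch)
    pos <- centroid(cube[, , k], roi, spec$pixel_pitch)
    expect_lt(abs(pos[["x_um"]] - g$x_um), 0.25 * spec$pixel_pitch)
    expect_lt(abs(pos[["y_um"]] - g$y_um), 0.25 * spec$pixel_pitch)
  }
  # speed 0: stationary disk
  cz <- render_microsphere_flow(spec, speed_um_per_ms = 0,
                                timestamps = c(0, 5), start_um = c(300, 240))
  expect_identical(cz[, , 1], cz[, , 2])
  # sphere exiting the FOV without wrap-around is a domain error
  expect_error(
    render_microsphere_flow(spec, speed_um_per_ms = 100, timestamps = c(0, 19),
                            start_um = c(300, 240)),
    "exits the FOV")
})
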