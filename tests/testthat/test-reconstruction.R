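test_that("TV denoising is the identity at strength 0, fixes constants, and denoises a step edge", {
  img <- matrix(runif(400), 20, 20)
  expect_identical(tv_denoise(img, 0), img)
  cst <- matrix(3.7, 15, 12)
  expect_equal(tv_denoise(cst, 5), cst, tolerance = 1e-10)
  cst3 <- array(1.1, c(8, 9, 4))
  expect_equal(tv_denoise(cst3, 2), cst3, tolerance = 1e-10)
  # noisy step edge: TV output strictly closer to the clean image
  clean <- matrix(rep(c(0, 1), each = 200), 20, 20)
  set.seed(5)
  noisy <- clean + matrix(rnorm(400, 0, 0.1), 20, 20)
  den <- tv_denoise(noisy, 0.1)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
})

test_that("denoiser plugin registration enforces the constant-preservation contract", {
  expect_error(denoiser_plugin(function(cube, sigma) cube * 0.5),
               "constant input not preserved")
  expect_error(denoiser_plugin(function(cube, sigma) cube[, , 1, drop = FALSE]),
               "shape mismatch")
  ident <- denoiser_identity()
  probe <- array(runif(24), c(2, 3, 4))
  expect_identical(ident$fn(probe, 0.3), probe)
})

test_that("closed-form x-update matches the dense linear-algebra oracle", {
  # scalar example: one pixel, two frames, both codes on, y = 3, z = (1, 1)
  masks <- all_on_masks(c(1, 1), 2)
  op <- sensing_operator(masks)
  st <- list(theta = array(1, c(1, 1, 2)), u = array(0, c(1, 1, 2)))
  st <- admm_x_update(st, snapshot(matrix(3, 1, 1)), op, rho = 1)
  expect_equal(as.vector(st$x), c(4, 4) / 3, tolerance = 1e-12)

  # random instances up to 8x8x5 against solve((Phi^T Phi + rho I)) oracle
  set.seed(11)
  for (rep in 1:6) {
    d <- c(sample(2:8, 1), sample(2:8, 1), sample(2:5, 1))
    masks <- make_mask_stack(d[1:2], d[3], 0.5, seed = rep)
    op <- sensing_operator(masks)
    hw <- d[1] * d[2]
    y <- matrix(runif(hw, 0, 5), d[1], d[2])
    theta <- array(runif(prod(d)), d)
    u <- array(rnorm(prod(d)), d)
    rho <- runif(1, 0.5, 3)
    st <- admm_x_update(list(theta = theta, u = u), snapshot(y), op, rho)
    Phi <- dense_phi(masks)
    z <- as.vector(theta + u / rho)
    x_dense <- solve(crossprod(Phi) + rho * diag(hw * d[3]),
                     crossprod(Phi, as.vector(y)) + rho * z)
    expect_lt(max(abs(as.vector(st$x) - x_dense)) / max(abs(x_dense)), 1e-10)
  }
  expect_error(admm_x_update(st, snapshot(y), op, rho = 0), "> 0")
})

test_that("x-update leaves a measurement-consistent iterate unchanged", {
  masks <- make_mask_stack(c(5, 6), 3, 0.5, seed = 2)
  op <- sensing_operator(masks)
  z <- array(runif(90), c(5, 6, 3))
  y <- op$forward(z)
  st <- admm_x_update(list(theta = z, u = array(0, dim(z))), snapshot(y), op, 1)
  expect_equal(st$x, z, tolerance = 1e-12)
})

test_that("theta- and u-updates follow the scaled-dual recurrences", {
  d <- c(4, 5, 3)
  x <- array(runif(prod(d)), d)
  u <- array(rnorm(prod(d)), d)
  rho <- 2
  # identity cascade: theta = x - u / rho (the denoiser input point)
  st <- admm_theta_update(list(x = x, u = u), list(denoiser_identity()),
                          sigma = 0.1, rho = rho)
  expect_equal(st$theta, x - u / rho, tolerance = 1e-12)
  # constant cube: TV cascade leaves it unchanged
  stc <- admm_theta_update(list(x = array(2, d), u = array(0, d)),
                           list(denoiser_tv2d()), sigma = 0.5, rho = 1)
  expect_equal(stc$theta, array(2, d), tolerance = 1e-8)
  # u-update: x == theta leaves u unchanged; constant offset accumulates linearly
  st2 <- admm_u_update(list(x = x, theta = x, u = u), rho)
  expect_identical(st2$u, u)
  st3 <- list(x = array(0, d), theta = array(1, d), u = array(0, d))
  for (k in 1:3) st3 <- admm_u_update(st3, rho)
  expect_equal(st3$u, array(3 * rho, d), tolerance = 1e-12)
})

test_that("noiseless single-code all-on encoding is reconstructed exactly", {
  fr <- matrix(runif(30, 1, 10), 5, 6)
  masks <- all_on_masks(c(5, 6), 1)
  snap <- forward_encode(array(fr, c(5, 6, 1)), masks)
  rec <- run_pnp_admm(snap, masks,
                      solver_config(cascade = list(denoiser_identity())))
  expect_lt(max(abs(rec$cube[, , 1] - fr)) / max(fr), 1e-6)
})

test_that("PnP-ADMM is deterministic, monotone at start, and reaches its primal tolerance", {
  spec <- small_spec()
  obj <- object_trajectory("disk", diameter_um = 90, intensity = 400,
                           position_fn = function(t) c(150 + 25 * t, 200 + 15 * t))
  sched <- make_schedule("uniform", n_codes = 10, interval_ms = 0.3,
                         exposure_ms = 0.15)
  frames <- sample_scene_on_schedule(moving_objects_scene(spec, list(obj)), sched)
  masks <- make_mask_stack(dim(frames)[1:2], 10, 0.5, seed = 4)
  snap <- forward_encode(frames, masks, sched)
  cfg <- fast_solver(iters = 15L)
  r1 <- run_pnp_admm(snap, masks, cfg)
  r2 <- run_pnp_admm(snap, masks, cfg)
  expect_identical(unclass(r1$cube)[], unclass(r2$cube)[])
  hist <- r1$state$residual_history
  # data-fidelity residual after iteration 1 is at most the initialization's
  op <- sensing_operator(masks)
  x0 <- op$adjoint(snap$image / pmax(op$R, 1))
  expect_lte(hist$data_residual[1], cofi:::fnorm(snap$image - op$forward(x0)))
  # the reconstruction keeps the cube shape and timestamps
  expect_equal(dim(r1$cube), dim(frames))
  expect_equal(cube_timestamps(r1$cube), schedule_midtimes(sched))
})

test_that("noiseless coded moving-disk video is recovered with sub-pixel centroid accuracy", {
  spec <- small_spec(grid = c(64L, 80L))
  obj <- object_trajectory("disk", diameter_um = 90, intensity = 400,
                           position_fn = function(t) c(300 + 12 * t, 350 + 7 * t),
                           id = "disk")
  scene <- moving_objects_scene(spec, list(obj))
  sched <- make_schedule("uniform", n_codes = 10, interval_ms = 0.3,
                         exposure_ms = 0.15)
  frames <- sample_scene_on_schedule(scene, sched)
  masks <- make_mask_stack(dim(frames)[1:2], 10, 0.5, seed = 8)
  snap <- forward_encode(frames, masks, sched)
  rec <- run_pnp_admm(snap, masks, fast_solver(
    iters = 15L,
    cascade = list(denoiser_tv2d(), denoiser_tv3d(temporal_weight = 3))))
  gt <- cofi:::gt_table(scene, schedule_midtimes(sched))
  for (k in seq_len(dim(rec$cube)[3])) {
    g <- gt[gt$frame_index == k - 1L, ]
    roi <- cofi:::circle_roi(dim(rec$cube)[1:2], c(g$x_um, g$y_um), 120,
                             spec$pixel_pitch)
    pos <- centroid(rec$cube[, , k], roi, spec$pixel_pitch)
    err <- sqrt((pos[["x_um"]] - g$x_um)^2 + (pos[["y_um"]] - g$y_um)^2)
    expect_lt(err, spec$pixel_pitch)
  }
})

test_that("identity-cascade ADMM stays finite and terminates", {
  masks <- make_mask_stack(c(10, 12), 4, 0.5, seed = 5)
  scene <- array(runif(480, 0, 100), c(10, 12, 4))
  snap <- forward_encode(scene, masks)
  rec <- run_pnp_admm(snap, masks,
                      solver_config(cascade = list(denoiser_identity())))
  expect_true(all(is.finite(rec$cube)))
  expect_lte(rec$state$k, 60L)
})

test_that("pixel super-resolution preserves constants, flux, and line-pair contrast", {
  cube <- video_cube(array(2.5, c(8, 10, 2)), c(0, 1), 15)
  expect_identical(apply_psr(cube, 1L), cube)
  up <- apply_psr(cube, 2L)
  expect_equal(dim(up), c(16L, 20L, 2L))
  expect_equal(attr(up, "pixel_pitch"), 7.5)
  expect_equal(max(abs(up - 2.5)), 0, tolerance = 1e-9)
  # flux normalization: per-frame mean preserved for arbitrary content
  set.seed(21)
  rcube <- video_cube(array(runif(160, 0, 7), c(8, 10, 2)), c(0, 1), 15)
  up2 <- apply_psr(rcube, 4L)
  expect_equal(mean(up2[, , 1]), mean(rcube[, , 1]), tolerance = 1e-9)
  # bar-target frame: modulation contrast at 60.8-um spacing not degraded
  spec <- small_spec(grid = c(48L, 60L))
  bt <- render_bar_target(spec, spacings_um = 60.8, orientation_deg = 45,
                          velocity_um_per_ms = c(0, 0), timestamps = 0,
                          group_centers_um = matrix(c(450, 360), 1))
  ctr <- c(450, 360)
  c_lo <- resolvability(bt[, , 1], ctr, 45, 60.8, 3, spec$pixel_pitch)$contrast
  upb <- apply_psr(bt, 4L)
  c_hi <- resolvability(upb[, , 1], ctr, 45, 60.8, 3,
                        attr(upb, "pixel_pitch"))$contrast
  expect_gte(c_hi, c_lo)
  # plugin contract: wrong shape is rejected
  expect_error(apply_psr(cube, 2L, plugin = function(c, f) c),
               "wrong-shape")
})
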