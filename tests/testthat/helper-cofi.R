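# Shared fixtures, built in code.

# Small grid for fast unit tests.
small_spec <- function(grid = c(32L, 40L), duration = 6, ...) {
  scene_spec(grid = grid, duration = duration, ...)
}

# Fast solver for smoke-level reconstructions.
fast_solver <- function(iters = 10L, cascade = list(denoiser_tv2d())) {
  solver_config(sigma_schedule = data.frame(sigma_frac = c(0.10, 0.05, 0.02),
                                            iters = rep(as.integer(iters), 3L)),
                cascade = cascade)
}

# Dense sensing matrix (HW x HW*T) built by brute force from a mask stack,
# the oracle for the closed-form ADMM data-fidelity update.
dense_phi <- function(masks) {
  d <- dim(masks)
  hw <- d[1] * d[2]
  Phi <- matrix(0, hw, hw * d[3])
  for (k in seq_len(d[3])) {
    Phi[, (k - 1) * hw + seq_len(hw)] <- diag(as.vector(masks[, , k]))
  }
  Phi
}

# Triple-loop scalar forward encoding, the oracle for forward_encode().
brute_force_encode <- function(scene, masks) {
  d <- dim(masks)
  Y <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    Y[i, j] <- Y[i, j] + scene[i, j, k] * masks[i, j, k]
  }
  Y
}

# A hand-built continuous scene whose intensity is an arbitrary function of
# time, constant over space (for schedule-sampling tests).
flat_scene <- function(spec, intensity_fn) {
  structure(list(
    spec = spec,
    render = function(t) matrix(intensity_fn(t), spec$grid[1], spec$grid[2]),
    ground_truth = function(t) data.frame()
  ), class = "cofi_scene")
}
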