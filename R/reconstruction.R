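# --- total-variation proximal denoiser (Chambolle dual projection) ---------

grad_x2 <- function(u) cbind(u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE], 0)
grad_y2 <- function(u) rbind(u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE], 0)
div2 <- function(px, py) {
  W <- ncol(px); H <- nrow(px)
  dx <- px - cbind(0, px[, -W, drop = FALSE])
  dy <- py - rbind(0, py[-H, , drop = FALSE])
  dx + dy
}

tv_denoise_2d <- function(f, strength, iters, step) {
  px <- py <- matrix(0, nrow(f), ncol(f))
  fl <- f / strength
  for (i in seq_len(iters)) {
    u <- div2(px, py) - fl
    gx <- grad_x2(u); gy <- grad_y2(u)
    ng <- sqrt(gx * gx + gy * gy)
    px <- (px + step * gx) / (1 + step * ng)
    py <- (py + step * gy) / (1 + step * ng)
  }
  f - strength * div2(px, py)
}

# Forward differences (Neumann boundary) and their negative adjoints on a
# H x W x T array, written with direct slicing for speed.
grad3 <- function(a, axis) {
  d <- dim(a)
  g <- array(0, d)
  switch(axis,
    y = { g[-d[1], , ] <- a[-1, , ] - a[-d[1], , ] },
    x = { g[, -d[2], ] <- a[, -1, ] - a[, -d[2], ] },
    t = { g[, , -d[3]] <- a[, , -1] - a[, , -d[3]] })
  g
}

div3 <- function(p, axis) {
  d <- dim(p)
  out <- p
  switch(axis,
    y = { out[-1, , ] <- p[-1, , ] - p[-d[1], , ] },
    x = { out[, -1, ] <- p[, -1, ] - p[, -d[2], ] },
    t = { out[, , -1] <- p[, , -1] - p[, , -d[3]] })
  out
}

tv_denoise_3d <- function(f, strength, iters, step, temporal_weight = 1) {
  py <- px <- pt <- array(0, dim(f))
  fl <- f / strength
  wt <- temporal_weight
  for (i in seq_len(iters)) {
    u <- div3(py, "y") + div3(px, "x") + wt * div3(pt, "t") - fl
    gy <- grad3(u, "y"); gx <- grad3(u, "x"); gt <- wt * grad3(u, "t")
    ng <- sqrt(gy * gy + gx * gx + gt * gt)
    den <- 1 + step * ng
    py <- (py + step * gy) / den
    px <- (px + step * gx) / den
    pt <- (pt + step * gt) / den
  }
  f - strength * (div3(py, "y") + div3(px, "x") + wt * div3(pt, "t"))
}

#' Isotropic total-variation denoising (proximal operator)
#'
#' Solves `min_z 0.5 * ||z - x||^2 + strength * TV(z)` by Chambolle's dual
#' projection scheme with a fixed inner-iteration count (determinism over
#' adaptive stopping). A matrix input uses the 2-D gradient; a 3-D array uses
#' the spatiotemporal 3-D gradient. `strength = 0` is the identity, and a
#' constant input is returned unchanged for any strength.
#'
#' @param x matrix or 3-D array.
#' @param strength TV weight (same units as the data), >= 0.
#' @param iters fixed number of dual iterations.
#' @param step dual step size.
#' @return denoised array, same shape.
#' @export
tv_denoise <- function(x, strength, iters = 30L, step = 0.25) {
  if (!is_scalar_num(strength) || strength < 0) stop_cofi("`strength` must be >= 0")
  if (strength == 0) return(x)
  if (is.matrix(x)) {
    tv_denoise_2d(x, strength, iters, step)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    tv_denoise_3d(x, strength, iters, step)
  } else stop_cofi("`x` must be a matrix or 3-D array")
}

# --- denoiser cascade -------------------------------------------------------

#' Denoiser specifications for the plug-and-play cascade
#'
#' A cascade stage maps an iterate (video cube) and a noise level `sigma` to
#' a same-shape denoised cube. `denoiser_tv2d()` applies the TV proximal
#' operator frame by frame with `strength = strength_scale * sigma`;
#' `denoiser_tv3d()` applies it to the full spatiotemporal cube;
#' `denoiser_plugin()` wraps any callable honouring the contract
#' `fn(cube, sigma) -> cube`, so trained denoisers can be dropped into the
#' cascade without code changes. Plugin registration verifies the
#' constant-preservation invariant (a constant input must be returned within
#' 1e-6 relative) on a small probe.
#'
#' @param strength_scale multiplier mapping sigma to TV strength.
#' @param iters,step TV inner-solver parameters (see [tv_denoise()]).
#' @param fn plugin callable `function(cube, sigma)`.
#' @param name stage name used in error messages.
#' @return `cofi_denoiser` object.
#' @export
denoiser_tv2d <- function(strength_scale = 1, iters = 30L, step = 0.25) {
  structure(list(kind = "tv2d", name = "tv2d",
                 fn = function(cube, sigma) {
                   out <- cube
                   for (k in seq_len(dim(cube)[3])) {
                     out[, , k] <- tv_denoise_2d(cube[, , k],
                                                 strength_scale * sigma,
                                                 iters, step)
                   }
                   out
                 }),
            class = "cofi_denoiser")
}

#' @rdname denoiser_tv2d
#' @param temporal_weight relative weight of the temporal gradient in the
#'   3-D TV norm (larger favours temporal smoothness, apt for slowly moving
#'   scenes).
#' @export
denoiser_tv3d <- function(strength_scale = 1, iters = 30L, step = 0.25,
                          temporal_weight = 1) {
  structure(list(kind = "tv3d", name = "tv3d",
                 fn = function(cube, sigma) {
                   tv_denoise_3d(cube, strength_scale * sigma, iters, step,
                                 temporal_weight)
                 }),
            class = "cofi_denoiser")
}

#' @rdname denoiser_tv2d
#' @export
denoiser_plugin <- function(fn, name = "plugin") {
  if (!is.function(fn)) stop_cofi("plugin must be a function(cube, sigma)")
  probe <- array(1.234, c(4, 5, 2))
  out <- fn(probe, 0.1)
  if (!is.array(out) || !all(dim(out) == dim(probe))) {
    stop_cofi(sprintf("plugin '%s' failed registration: output shape mismatch", name))
  }
  if (max(abs(out - probe)) > 1e-6 * 1.234) {
    stop_cofi(sprintf(
      "plugin '%s' failed registration: constant input not preserved", name))
  }
  structure(list(kind = "plugin", name = name, fn = fn),
            class = "cofi_denoiser")
}

#' Identity denoiser (pass-through cascade stage)
#' @return `cofi_denoiser`.
#' @export
denoiser_identity <- function() {
  denoiser_plugin(function(cube, sigma) cube, name = "identity")
}

apply_cascade <- function(cascade, cube, sigma) {
  for (d in cascade) {
    stopifnot(inherits(d, "cofi_denoiser"))
    out <- d$fn(cube, sigma)
    if (!is.array(out) || !all(dim(out) == dim(cube))) {
      stop_cofi(sprintf("denoiser stage '%s' returned a wrong-shape output", d$name))
    }
    cube <- out
  }
  cube
}

# --- solver configuration and ADMM updates ---------------------------------

#' Plug-and-play ADMM solver configuration
#'
#' The sigma schedule is a ladder of denoiser noise levels expressed as
#' fractions of the data dynamic range (estimated from the initialization
#' unless `dynamic_range` is given), each run for a fixed iteration count;
#' the fractions must be non-increasing (coarse-to-fine denoising).
#'
#' @param rho ADMM penalty parameter, > 0.
#' @param sigma_schedule data.frame with columns `sigma_frac`
#'   (non-increasing) and `iters`; the total iteration budget is
#'   `sum(iters)`.
#' @param tol_primal relative primal-residual threshold
#'   `||x - theta|| / ||x||` for early stopping.
#' @param cascade ordered list of [denoiser_tv2d()]-style stages.
#' @param dynamic_range data dynamic range in counts; `NULL` = estimate at
#'   run time as the maximum of the normalized backprojection.
#' @param seed seed recorded in the config (the solver itself is
#'   deterministic).
#' @param verbose print per-iteration residuals.
#' @return `cofi_solver_config`.
#' @export
solver_config <- function(rho = 1,
                          sigma_schedule = data.frame(
                            sigma_frac = c(0.10, 0.05, 0.02),
                            iters = c(20L, 20L, 20L)),
                          tol_primal = 1e-4,
                          cascade = list(denoiser_tv2d()),
                          dynamic_range = NULL,
                          seed = 1L, verbose = FALSE) {
  if (!is_scalar_num(rho) || rho <= 0) stop_cofi("`rho` must be > 0")
  stopifnot(is.data.frame(sigma_schedule),
            all(c("sigma_frac", "iters") %in% names(sigma_schedule)))
  if (any(diff(sigma_schedule$sigma_frac) > 0)) {
    stop_cofi("sigma schedule must be non-increasing")
  }
  if (!length(cascade)) stop_cofi("cascade must be non-empty")
  structure(list(rho = rho, sigma_schedule = sigma_schedule,
                 max_iters = sum(sigma_schedule$iters),
                 tol_primal = tol_primal, cascade = cascade,
                 dynamic_range = dynamic_range,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "cofi_solver_config")
}

#' ADMM update steps
#'
#' The three subproblem updates of the plug-and-play ADMM scheme, exposed
#' individually so each can be checked against independent oracles. The
#' solver state is a list with cubes `x` (data-consistent iterate), `theta`
#' (denoised auxiliary iterate) and `u` (dual), all of the mask-stack shape.
#'
#' `admm_x_update` solves the data-fidelity subproblem exactly: with
#' `z = theta + u / rho`, the minimizer of
#' `0.5 * ||y - Phi x||^2 + (rho/2) * ||x - z||^2` is
#' `x = z + Phi^T ((y - Phi z) / (R + rho))`, using the diagonal
#' `Phi Phi^T = diag(R)`. `admm_theta_update` applies the denoiser cascade
#' to `x - u / rho` at noise level `sigma`. `admm_u_update` performs the
#' dual ascent `u <- u + rho * (theta - x)`.
#'
#' @param state list with cubes `x`, `theta`, `u`.
#' @param snap a `cofi_snapshot` (measurement `y`).
#' @param op a [sensing_operator()].
#' @param rho penalty parameter, > 0.
#' @param cascade list of denoiser stages.
#' @param sigma denoiser noise level (counts).
#' @return the updated state.
#' @export
admm_x_update <- function(state, snap, op, rho) {
  if (!is_scalar_num(rho) || rho <= 0) stop_cofi("`rho` must be > 0")
  y <- if (inherits(snap, "cofi_snapshot")) snap$image else snap
  z <- state$theta + state$u / rho
  resid <- (y - op$forward(z)) / (op$R + rho)
  state$x <- z + op$adjoint(resid)
  state
}

#' @rdname admm_x_update
#' @export
admm_theta_update <- function(state, cascade, sigma, rho) {
  v <- state$x - state$u / rho
  state$theta <- apply_cascade(cascade, v, sigma)
  state
}

#' @rdname admm_x_update
#' @export
admm_u_update <- function(state, rho) {
  state$u <- state$u + rho * (state$theta - state$x)
  state
}

#' Reconstruct a coded snapshot by plug-and-play ADMM
#'
#' Recovers the T-frame video from one compressed snapshot by alternating
#' the closed-form data-fidelity update, the denoiser-cascade proximal step,
#' and the dual ascent, through a coarse-to-fine sigma ladder.
#' Initialization is the mask-normalized backprojection
#' `x0 = Phi^T y / max(R, 1)` (scale-correct and parameter-free); the
#' returned reconstruction is the final `theta` (the prior-consistent
#' iterate, standard plug-and-play practice). Deterministic given inputs
#' and config.
#'
#' @param snap `cofi_snapshot`.
#' @param masks the mask stack used for encoding.
#' @param config a [solver_config()].
#' @param pixel_pitch pitch (um) attached to the returned cube.
#' @return list: `cube` ([video_cube()] reconstruction) and `state`
#'   (final iterates plus `residual_history`, a data.frame of per-iteration
#'   data-fidelity and primal residuals).
#' @export
run_pnp_admm <- function(snap, masks, config = solver_config(),
                         pixel_pitch = NULL) {
  stopifnot(inherits(snap, "cofi_snapshot"),
            inherits(config, "cofi_solver_config"))
  y <- snap$image
  if (!all(dim(y) == dim(masks)[1:2])) {
    stop_cofi("snapshot and mask spatial dimensions differ")
  }
  op <- sensing_operator(masks)
  rho <- config$rho
  x <- op$adjoint(y / pmax(op$R, 1))
  theta <- x
  u <- array(0, dim(x))
  DR <- config$dynamic_range %||% max(x)
  if (!is.finite(DR) || DR <= 0) DR <- 1
  state <- list(x = x, theta = theta, u = u)
  hist_data <- numeric(0); hist_primal <- numeric(0)
  k <- 0L
  done <- FALSE
  for (s in seq_len(nrow(config$sigma_schedule))) {
    sigma <- config$sigma_schedule$sigma_frac[s] * DR
    for (i in seq_len(config$sigma_schedule$iters[s])) {
      state <- admm_x_update(state, snap, op, rho)
      state <- admm_theta_update(state, config$cascade, sigma, rho)
      state <- admm_u_update(state, rho)
      k <- k + 1L
      if (any(!is.finite(state$x)) || any(!is.finite(state$theta))) {
        stop_cofi(sprintf("numerical failure (NaN/Inf) at iteration %d", k))
      }
      dres <- fnorm(y - op$forward(state$x))
      pres <- fnorm(state$x - state$theta)
      hist_data <- c(hist_data, dres)
      hist_primal <- c(hist_primal, pres)
      if (config$verbose) {
        message(sprintf("iter %3d  sigma %8.3g  data %10.4g  primal %10.4g",
                        k, sigma, dres, pres))
      }
      if (pres / max(fnorm(state$x), .Machine$double.eps) < config$tol_primal) {
        done <- TRUE
        break
      }
    }
    if (done) break
  }
  ts <- if (!is.null(snap$schedule)) schedule_midtimes(snap$schedule)
        else seq_len(dim(x)[3]) - 1
  cube <- video_cube(pmax(state$theta, 0), ts,
                     pixel_pitch %||% NA_real_)
  state$k <- k
  state$residual_history <- data.frame(iteration = seq_len(k),
                                       data_residual = hist_data,
                                       primal_residual = hist_primal)
  list(cube = cube, state = state)
}

# --- pixel super-resolution -------------------------------------------------

# Catmull-Rom interpolation weight matrix mapping n_in samples to n_in*f
# output samples. Output pixel jo (0-based) sits at input coordinate jo/f,
# so position jo * (pitch/f) in physical um stays in the package's 0-based
# pixel-centre convention (every f-th output sample coincides with an input
# sample; the last f-1 rows extrapolate by edge clamping).
cr_weight_matrix <- function(n_in, f) {
  n_out <- n_in * f
  W <- matrix(0, n_out, n_in)
  for (jo in seq_len(n_out)) {
    ci <- (jo - 1) / f                  # 0-based input coordinate
    i0 <- floor(ci)
    t <- ci - i0
    w <- c((-t^3 + 2 * t^2 - t) / 2,
           (3 * t^3 - 5 * t^2 + 2) / 2,
           (-3 * t^3 + 4 * t^2 + t) / 2,
           (t^3 - t^2) / 2)
    idx <- pmin(pmax(i0 + (-1:2), 0L), n_in - 1L) + 1L
    for (m in 1:4) W[jo, idx[m]] <- W[jo, idx[m]] + w[m]
  }
  W
}

#' Pixel super-resolution upsampling of a reconstruction
#'
#' Default path: separable cubic (Catmull-Rom) interpolation on the
#' pixel-centre grid, clipping at zero and rescaling each frame to preserve
#' its mean intensity (flux normalization). The output pixel pitch is the
#' input pitch divided by the factor. A registered plugin (a callable
#' `fn(cube, factor) -> upsampled cube`, e.g. a trained super-resolver)
#' replaces the default path under the same contract.
#'
#' @param cube a [video_cube()] (or 3-D array).
#' @param factor integer upsampling factor: 1, 2 or 4.
#' @param plugin optional plugin callable.
#' @return upsampled cube with adjusted `pixel_pitch`.
#' @export
apply_psr <- function(cube, factor, plugin = NULL) {
  if (!factor %in% c(1L, 2L, 4L)) stop_cofi("`factor` must be 1, 2 or 4")
  if (factor == 1L) return(cube)
  d <- dim(cube)
  pitch <- attr(cube, "pixel_pitch")
  ts <- attr(cube, "timestamps") %||% (seq_len(d[3]) - 1)
  if (!is.null(plugin)) {
    out <- plugin(unclass(cube), as.integer(factor))
    if (!is.array(out) || !all(dim(out) == c(d[1:2] * factor, d[3]))) {
      stop_cofi("PSR plugin returned a wrong-shape output")
    }
  } else {
    Wr <- cr_weight_matrix(d[1], factor)
    Wc <- cr_weight_matrix(d[2], factor)
    out <- array(0, c(d[1:2] * factor, d[3]))
    for (k in seq_len(d[3])) {
      fr <- pmax(Wr %*% cube[, , k] %*% t(Wc), 0)
      m_in <- mean(cube[, , k]); m_out <- mean(fr)
      if (m_out > 0) fr <- fr * (m_in / m_out)
      out[, , k] <- fr
    }
  }
  video_cube(out, ts, if (is.null(pitch) || is.na(pitch)) NA_real_
                      else pitch / factor)
}
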