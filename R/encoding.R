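#' Binary random coding-mask stack
#'
#' The per-code spatial patterns the modulator loads during one snapshot
#' exposure: `n_codes` binary images, i.i.d. Bernoulli(`fill`) per pixel,
#' deterministic given the seed. Values are exactly 0 or 1.
#'
#' @param shape `c(height, width)` in pixels.
#' @param n_codes number of codes T (the compression ratio).
#' @param fill Bernoulli probability of a pixel being "on"; strictly in (0,1).
#' @param seed RNG seed.
#' @return `cofi_masks`: an `c(height, width, n_codes)` 0/1 array with
#'   attributes `fill` and `seed`.
#' @export
make_mask_stack <- function(shape, n_codes, fill = 0.5, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stop_cofi("`shape` must be c(height, width)")
  n_codes <- as.integer(n_codes)
  if (n_codes < 1L) stop_cofi("`n_codes` must be >= 1")
  if (!is_scalar_num(fill) || fill <= 0 || fill >= 1) {
    stop_cofi("`fill` must lie strictly in (0, 1)")
  }
  vals <- with_seed(seed, {
    stats::rbinom(prod(shape) * n_codes, 1L, fill)
  })
  structure(array(as.double(vals), c(shape, n_codes)),
            fill = fill, seed = as.integer(seed),
            class = c("cofi_masks", "array"))
}

#' All-on mask stack
#'
#' Every code fully transmissive; with one code this makes the forward model
#' the identity (useful for sanity checks and calibration).
#' @inheritParams make_mask_stack
#' @return `cofi_masks` of ones.
#' @export
all_on_masks <- function(shape, n_codes = 1L) {
  structure(array(1, c(as.integer(shape), as.integer(n_codes))),
            fill = 1, seed = NA_integer_,
            class = c("cofi_masks", "array"))
}

#' @export
print.cofi_masks <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cofi_masks> %d x %d, %d codes, fill %.3g (empirical %.4g)\n",
              d[1], d[2], d[3], attr(x, "fill"), mean(x)))
  invisible(x)
}

#' Temporal coding schedule
#'
#' Per-code start times and exposure durations during one snapshot. Windows
#' must be non-overlapping and in increasing order. The reference timestamp
#' of code i, used by all downstream fitting and tracking, is the window
#' midpoint `start + exposure / 2`.
#'
#' `mode = "uniform"`: `n_codes` windows every `interval_ms`, each open for
#' `exposure_ms`. `mode = "segmented"`: a list of `(n_codes, interval_ms,
#' exposure_ms)` segments laid out back to back (segment k starts where the
#' previous segment's last interval ends), enabling nonuniform coding such as
#' dense early sampling of a fast decay followed by sparse late sampling.
#'
#' @param mode `"uniform"` or `"segmented"`.
#' @param n_codes,interval_ms,exposure_ms uniform-mode parameters.
#' @param segments segmented-mode parameter: list of numeric vectors
#'   `c(n_codes, interval_ms, exposure_ms)`.
#' @param start_ms start time of the first window (ms).
#' @param label free-text label carried in the object.
#' @return `cofi_schedule`: a data.frame `(code_index, start_ms, exposure_ms)`
#'   with 0-based code indices.
#' @export
make_schedule <- function(mode = c("uniform", "segmented"),
                          n_codes = NULL, interval_ms = NULL, exposure_ms = NULL,
                          segments = NULL, start_ms = 0, label = mode[1]) {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    segments <- list(c(n_codes, interval_ms, exposure_ms))
  }
  if (is.null(segments) || !length(segments)) stop_cofi("no schedule segments given")
  starts <- numeric(0); expos <- numeric(0); t0 <- start_ms
  for (seg in segments) {
    if (length(seg) != 3L) stop_cofi("each segment is c(n_codes, interval_ms, exposure_ms)")
    n <- as.integer(seg[1]); iv <- seg[2]; ex <- seg[3]
    if (n < 1L || iv <= 0 || ex <= 0) stop_cofi("segment parameters must be positive")
    if (ex > iv) {
      stop_cofi(sprintf("exposure %g ms exceeds interval %g ms: windows would overlap",
                        ex, iv))
    }
    starts <- c(starts, t0 + (seq_len(n) - 1) * iv)
    expos <- c(expos, rep(ex, n))
    t0 <- t0 + n * iv
  }
  sched <- data.frame(code_index = seq_along(starts) - 1L,
                      start_ms = starts, exposure_ms = expos)
  validate_schedule(sched)
  structure(sched, label = label, class = c("cofi_schedule", "data.frame"))
}

validate_schedule <- function(sched) {
  need <- c("code_index", "start_ms", "exposure_ms")
  if (!all(need %in% names(sched))) {
    stop_cofi("schedule needs columns code_index, start_ms, exposure_ms")
  }
  if (any(diff(sched$start_ms) <= 0)) stop_cofi("schedule starts must be strictly increasing")
  if (any(sched$exposure_ms <= 0)) stop_cofi("exposures must be positive")
  n <- nrow(sched)
  if (n > 1L) {
    ends <- sched$start_ms[-n] + sched$exposure_ms[-n]
    if (any(ends > sched$start_ms[-1] + 1e-12)) {
      stop_cofi("schedule windows overlap")
    }
  }
  invisible(sched)
}

#' Library coding-schedule presets
#'
#' `"lifetime_snapshot1"`: compression ratio 20 with flexible intervals —
#' 10 codes at 300-us intervals densely sampling the fast initial decay,
#' then 10 codes at 600-us intervals, every exposure 150 us (span 8.55 ms).
#' `"lifetime_snapshot2"`: compression ratio 10 targeting the slow decay
#' tail — 10 codes at 1-ms intervals with 500-us exposures.
#'
#' @param name preset name.
#' @return `cofi_schedule`.
#' @export
schedule_preset <- function(name = c("lifetime_snapshot1", "lifetime_snapshot2")) {
  name <- match.arg(name)
  switch(name,
    lifetime_snapshot1 = make_schedule("segmented",
      segments = list(c(10, 0.3, 0.15), c(10, 0.6, 0.15)), label = name),
    lifetime_snapshot2 = make_schedule("uniform",
      n_codes = 10, interval_ms = 1, exposure_ms = 0.5, label = name))
}

#' Mid-exposure reference timestamps of a schedule
#' @param sched a `cofi_schedule`.
#' @return numeric vector, ms.
#' @export
schedule_midtimes <- function(sched) sched$start_ms + sched$exposure_ms / 2

#' Total span of a schedule
#'
#' Time from the first window's start to the last window's close (ms); the
#' snapshot exposure duration. With the code count this gives the effective
#' frame rate `n_codes / span`.
#' @param sched a `cofi_schedule`.
#' @return span in ms.
#' @export
schedule_span <- function(sched) {
  n <- nrow(sched)
  sched$start_ms[n] + sched$exposure_ms[n] - sched$start_ms[1]
}

#' Coded sensing operator
#'
#' The linear map of the snapshot forward model: `forward(x)` multiplies each
#' frame elementwise by its code and sums over codes; `adjoint(y)` replicates
#' the 2-D image through the codes. Because the codes are binary,
#' `forward(adjoint(y)) = R * y` with the diagonal normalizer
#' `R = sum_i C_i^2 = sum_i C_i` — the structural fact the closed-form ADMM
#' data-fidelity update exploits.
#'
#' @param masks a [make_mask_stack()] stack.
#' @return list with `forward(cube) -> matrix`, `adjoint(image) -> array`,
#'   `R` (matrix), `dim` (mask dimensions).
#' @export
sensing_operator <- function(masks) {
  d <- dim(masks)
  H <- d[1]; W <- d[2]; T_ <- d[3]
  Cm <- matrix(masks, H * W, T_)
  R <- matrix(rowSums(Cm * Cm), H, W)
  list(
    forward = function(x) {
      if (!all(dim(x)[1:2] == c(H, W)) || dim(x)[3] != T_) {
        stop_cofi("scene dimensions do not match the mask stack")
      }
      matrix(rowSums(matrix(x, H * W, T_) * Cm), H, W)
    },
    adjoint = function(y) {
      if (!all(dim(y) == c(H, W))) stop_cofi("image dimensions do not match the masks")
      array(Cm * as.vector(y), c(H, W, T_))
    },
    R = R,
    dim = d
  )
}

#' Compressed snapshot container
#'
#' @param image 2-D nonnegative matrix of camera counts.
#' @param schedule optional `cofi_schedule` describing the coding windows.
#' @param mask_ref optional identifier of the mask stack used.
#' @param noise_params `NULL` for a noiseless integral, otherwise
#'   `list(gain, read_sigma, seed)`.
#' @return `cofi_snapshot`.
#' @export
snapshot <- function(image, schedule = NULL, mask_ref = NULL, noise_params = NULL) {
  if (!is.matrix(image)) stop_cofi("`image` must be a matrix")
  if (any(!is.finite(image)) || any(image < 0)) {
    stop_cofi("snapshot image must be finite and nonnegative")
  }
  structure(list(image = image, schedule = schedule, mask_ref = mask_ref,
                 noise_params = noise_params),
            class = "cofi_snapshot")
}

#' @export
print.cofi_snapshot <- function(x, ...) {
  cat(sprintf("<cofi_snapshot> %d x %d, max %.4g counts, %s\n",
              nrow(x$image), ncol(x$image), max(x$image),
              if (is.null(x$noise_params)) "noiseless" else
                sprintf("noise(gain=%g, read=%g)", x$noise_params$gain,
                        x$noise_params$read_sigma)))
  invisible(x)
}

#' Encode a frame stack into one compressed snapshot
#'
#' The noiseless forward model: each frame is modulated elementwise by its
#' binary code and the modulated frames are summed over the exposure,
#' `Y = sum_i frame_i * C_i`. Linear in the scene.
#'
#' @param scene a [video_cube()] (or plain 3-D array) with exactly one frame
#'   per code, each frame already integrated/averaged over its exposure
#'   window (see [sample_scene_on_schedule()]).
#' @param masks matching mask stack.
#' @param schedule optional schedule stored with the snapshot.
#' @return `cofi_snapshot` (noiseless).
#' @export
forward_encode <- function(scene, masks, schedule = NULL) {
  d <- dim(masks)
  if (!all(dim(scene) == d)) {
    stop_cofi(sprintf("scene is %s but masks are %s",
                      paste(dim(scene), collapse = "x"),
                      paste(d, collapse = "x")))
  }
  op <- sensing_operator(masks)
  snapshot(op$forward(scene), schedule = schedule,
           mask_ref = attr(masks, "seed"))
}

#' Apply the sensor noise model to a snapshot
#'
#' Shot noise plus read noise: `Poisson(image * gain) / gain +
#' Normal(0, read_sigma)`, clipped at zero. Deterministic given the seed.
#'
#' @param snap a `cofi_snapshot`.
#' @param gain camera gain (photoelectrons per count), > 0.
#' @param read_sigma read-noise standard deviation in counts, >= 0.
#' @param seed RNG seed.
#' @return noisy `cofi_snapshot` with `noise_params` recorded.
#' @export
add_sensor_noise <- function(snap, gain = 1, read_sigma = 3, seed = 1L) {
  stopifnot(inherits(snap, "cofi_snapshot"))
  if (!is_scalar_num(gain) || gain <= 0) stop_cofi("`gain` must be > 0")
  if (!is_scalar_num(read_sigma) || read_sigma < 0) {
    stop_cofi("`read_sigma` must be >= 0")
  }
  img <- snap$image
  noisy <- with_seed(seed, {
    shot <- stats::rpois(length(img), as.vector(img) * gain) / gain
    shot + stats::rnorm(length(img), 0, read_sigma)
  })
  out <- matrix(pmax(noisy, 0), nrow(img), ncol(img))
  snapshot(out, schedule = snap$schedule, mask_ref = snap$mask_ref,
           noise_params = list(gain = gain, read_sigma = read_sigma,
                               seed = as.integer(seed)))
}

#' Sample a continuous scene on a coding schedule
#'
#' Produces the per-code frame stack the forward model consumes: each frame
#' is the camera's view of the scene through one exposure window,
#' approximated as the mean of `K` sub-renderings at the midpoints of `K`
#' equal sub-intervals of the window (exact for intensity linear in time;
#' relative error below `(exposure / lifetime)^2 / 24` for an exponential
#' decay). With `integrate = TRUE` the mean is multiplied by the exposure
#' duration, giving absolute integrated counts; the default mean keeps
#' frames comparable across nonuniform exposures.
#'
#' @param scene a `cofi_scene` (continuous phantom).
#' @param sched a `cofi_schedule`.
#' @param K sub-samples per window.
#' @param integrate multiply by the exposure duration.
#' @return [video_cube()] with the schedule's mid-exposure timestamps.
#' @export
sample_scene_on_schedule <- function(scene, sched, K = 3L, integrate = FALSE) {
  stopifnot(inherits(scene, "cofi_scene"))
  validate_schedule(sched)
  K <- as.integer(K)
  if (K < 1L) stop_cofi("`K` must be >= 1")
  spec <- scene$spec
  frames <- lapply(seq_len(nrow(sched)), function(i) {
    t0 <- sched$start_ms[i]; ex <- sched$exposure_ms[i]
    sub <- t0 + (seq_len(K) - 0.5) * ex / K
    f <- Reduce(`+`, lapply(sub, scene$render)) / K
    if (integrate) f * ex else f
  })
  video_cube(array(unlist(frames), c(spec$grid, nrow(sched))),
             schedule_midtimes(sched), spec$pixel_pitch)
}
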