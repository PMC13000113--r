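#' Merge reconstructions of consecutively coded snapshots onto one clock
#'
#' Places the frames of a second snapshot's reconstruction after the first
#' snapshot's span (plus an optional inter-snapshot gap), producing a single
#' decay series per pixel with strictly increasing mid-exposure timestamps.
#' With the two library presets this yields a 30-point series (20 + 10).
#'
#' @param recon1 [video_cube()] reconstruction of the first snapshot.
#' @param sched1 its `cofi_schedule`.
#' @param recon2,sched2 optional second snapshot reconstruction + schedule.
#' @param gap_ms camera readout gap between the two exposures (ms).
#' @return [video_cube()] with merged frames and common-clock timestamps.
#' @export
merge_snapshot_series <- function(recon1, sched1, recon2 = NULL, sched2 = NULL,
                                  gap_ms = 0) {
  validate_schedule(sched1)
  t1 <- schedule_midtimes(sched1)
  if (is.null(recon2)) {
    return(video_cube(array(recon1, dim(recon1)), t1,
                      attr(recon1, "pixel_pitch")))
  }
  validate_schedule(sched2)
  if (!all(dim(recon1)[1:2] == dim(recon2)[1:2])) {
    stop_cofi("the two reconstructions are on different spatial grids")
  }
  offset <- sched1$start_ms[1] + schedule_span(sched1) + gap_ms
  t2 <- offset + schedule_midtimes(sched2)
  ts <- c(t1, t2)
  if (any(diff(ts) <= 0)) {
    stop_cofi("schedules overlap after merging; check gap_ms")
  }
  d <- dim(recon1)
  merged <- array(c(recon1, recon2), c(d[1], d[2], d[3] + dim(recon2)[3]))
  video_cube(merged, ts, attr(recon1, "pixel_pitch"))
}

#' Fit a mono-exponential decay
#'
#' Least-squares fit of `I(t) = baseline + A * exp(-t / tau)` by
#' Levenberg-Marquardt with box constraints (tau bounded in
#' `tau_bounds`), initialized from a log-linear regression on
#' baseline-subtracted intensities. The estimate is invariant to global
#' intensity scaling (amplitude and baseline scale, tau does not).
#'
#' @param timestamps sample times, ms, strictly increasing.
#' @param intensities nonnegative intensities, same length.
#' @param tau_bounds `c(lower, upper)` bounds on tau, ms.
#' @param fit_baseline if `FALSE`, the baseline is fixed at 0.
#' @return `cofi_lifetime_fit`: list with `tau`, `amplitude`, `baseline`,
#'   `r_squared`, `converged`.
#' @export
fit_monoexponential <- function(timestamps, intensities,
                                tau_bounds = c(0.1, 100),
                                fit_baseline = TRUE) {
  t <- as.numeric(timestamps); y <- as.numeric(intensities)
  if (length(t) != length(y)) stop_cofi("timestamps/intensities length mismatch")
  if (length(t) < 4L) stop_cofi("need at least 4 points to fit a decay")
  if (any(diff(t) <= 0)) stop_cofi("timestamps must be strictly increasing")
  failed <- function() {
    structure(list(tau = NA_real_, amplitude = NA_real_, baseline = NA_real_,
                   r_squared = NA_real_, converged = FALSE),
              class = "cofi_lifetime_fit")
  }
  if (stats::sd(y) == 0) return(failed())
  span <- diff(range(t))
  # Log-linear initialization for tau: slope of log intensity vs time,
  # computed on the raw series (subtracting min(y) would be badly biased
  # when the observation window truncates the decay).
  loglin_tau <- function(yy) {
    ok <- yy > 0
    if (sum(ok) < 2L) return(NA_real_)
    slope <- stats::coef(stats::lm(log(yy[ok]) ~ t[ok]))[2]
    if (is.finite(slope) && slope < 0) -1 / slope else NA_real_
  }
  clamp_tau <- function(tau) {
    if (!is.finite(tau)) return(span / 3)
    min(max(tau, tau_bounds[1], span / 50), tau_bounds[2])
  }
  amp0 <- max(y) - min(y)
  starts <- list(
    c(b = 0, A = max(y), tau = clamp_tau(loglin_tau(y))),
    c(b = 0, A = max(y), tau = clamp_tau(span / 3)),
    c(b = min(y) / 2, A = amp0,
      tau = clamp_tau(loglin_tau(y - min(y) / 2))))
  model <- function(par) par[["b"]] + par[["A"]] * exp(-t / par[["tau"]])
  lower <- c(b = 0, A = 0, tau = tau_bounds[1])
  upper <- c(b = Inf, A = Inf, tau = tau_bounds[2])
  best <- NULL
  for (st in starts) {
    if (!fit_baseline) { st["b"] <- 0; lower["b"] <- 0; upper["b"] <- 0 }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = function(par) y - model(par),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:3 &&
        (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) return(failed())
  cf <- best$par
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - best$deviance / sstot else NA_real_
  structure(list(tau = unname(cf[["tau"]]),
                 amplitude = unname(cf[["A"]]),
                 baseline = unname(cf[["b"]]),
                 r_squared = r2,
                 converged = cf[["tau"]] > 0),
            class = "cofi_lifetime_fit")
}

#' @export
print.cofi_lifetime_fit <- function(x, ...) {
  cat(sprintf("<lifetime fit> tau %.4g ms, A %.4g, baseline %.4g, R^2 %.4f%s\n",
              x$tau, x$amplitude, x$baseline, x$r_squared,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Spatial-mean decay series over a region
#'
#' @param merged merged reconstruction cube (see [merge_snapshot_series()]).
#' @param region_mask logical matrix on the cube grid, non-empty.
#' @param normalize divide by the series maximum.
#' @return data.frame `(time_ms, intensity)`.
#' @export
region_mean_decay <- function(merged, region_mask, normalize = FALSE) {
  if (!any(region_mask)) stop_cofi("region mask is empty")
  if (!all(dim(region_mask) == dim(merged)[1:2])) {
    stop_cofi("region mask does not match the cube grid")
  }
  n <- dim(merged)[3]
  idx <- which(region_mask)
  hw <- prod(dim(merged)[1:2])
  m <- matrix(merged, hw, n)
  y <- colMeans(m[idx, , drop = FALSE])
  if (normalize) y <- y / max(y)
  data.frame(time_ms = cube_timestamps(merged), intensity = y)
}

#' Fit the mean decay of a region
#'
#' @inheritParams region_mean_decay
#' @param ... passed to [fit_monoexponential()].
#' @return `cofi_lifetime_fit`.
#' @export
region_lifetime <- function(merged, region_mask, ...) {
  s <- region_mean_decay(merged, region_mask)
  fit_monoexponential(s$time_ms, s$intensity, ...)
}

#' Per-pixel phosphorescence lifetime map
#'
#' Fits a mono-exponential decay at every pixel whose peak intensity reaches
#' the amplitude threshold; elsewhere the validity mask is `FALSE` and the
#' tau image holds `NA`. The threshold is either a number (counts) or
#' `"auto"`, in which case it is `5 *` the robust background sigma (median
#' absolute deviation) of `background_mask`. Pixels where species overlap
#' legitimately yield intermediate lifetimes (cross-talk).
#'
#' @param merged merged reconstruction cube.
#' @param amplitude_threshold number, or `"auto"` with `background_mask`.
#' @param background_mask logical matrix of known-background pixels (used by
#'   `"auto"`).
#' @param tau_bounds passed to [fit_monoexponential()].
#' @return `cofi_lifetime_map`: list of images `tau` (ms), `amplitude`,
#'   `r_squared`, `validity` (logical), plus the threshold used.
#' @export
build_lifetime_map <- function(merged, amplitude_threshold = "auto",
                               background_mask = NULL,
                               tau_bounds = c(0.1, 100)) {
  d <- dim(merged)
  hw <- prod(d[1:2])
  m <- matrix(merged, hw, d[3])
  peak <- apply(m, 1, max)
  if (identical(amplitude_threshold, "auto")) {
    if (is.null(background_mask)) {
      stop_cofi("`amplitude_threshold = \"auto\"` needs a `background_mask`")
    }
    bgvals <- m[which(background_mask), , drop = FALSE]
    thr <- stats::median(bgvals) + 5 * stats::mad(as.vector(bgvals))
  } else {
    thr <- amplitude_threshold
  }
  ts <- cube_timestamps(merged)
  tau_img <- amp_img <- r2_img <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  for (i in which(peak >= thr)) {
    f <- tryCatch(fit_monoexponential(ts, m[i, ], tau_bounds = tau_bounds),
                  error = function(e) NULL)
    if (!is.null(f) && isTRUE(f$converged)) {
      tau_img[i] <- f$tau; amp_img[i] <- f$amplitude; r2_img[i] <- f$r_squared
      valid[i] <- TRUE
    }
  }
  structure(list(tau = tau_img, amplitude = amp_img, r_squared = r2_img,
                 validity = valid, threshold = thr),
            class = "cofi_lifetime_map")
}

#' @export
print.cofi_lifetime_map <- function(x, ...) {
  cat(sprintf("<lifetime map> %d x %d, %d valid px, tau range [%.3g, %.3g] ms\n",
              nrow(x$tau), ncol(x$tau), sum(x$validity),
              suppressWarnings(min(x$tau, na.rm = TRUE)),
              suppressWarnings(max(x$tau, na.rm = TRUE))))
  invisible(x)
}
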