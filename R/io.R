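# Power-of-two scale factor so values fit the [0,1] range of 32-bit TIFF
# storage; scaling by a power of two is exact in IEEE arithmetic, so the
# only loss in a round-trip is the writer's uniform 32-bit quantization
# (absolute error <= scale * 2^-32).
tiff_scale <- function(x) {
  mx <- max(x, 0)
  if (mx <= 0) return(1)
  2^ceiling(log2(mx))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a video cube as multi-page float TIFF
#'
#' One 32-bit page per frame plus a JSON sidecar (`<path>.json`) holding
#' the intensity scale factor, timestamps, and pixel pitch. Values are
#' stored divided by a power-of-two scale (exact in IEEE arithmetic), so a
#' round-trip is lossless up to the writer's uniform 32-bit quantization:
#' absolute error at most `scale * 2^-32`, i.e. one part in 2^32 of the
#' dynamic range.
#'
#' @param cube a [video_cube()].
#' @param path output TIFF path.
#' @param extra named list merged into the sidecar (provenance etc.).
#' @return `path`, invisibly.
#' @export
write_cube_tiff <- function(cube, path, extra = list()) {
  sc <- tiff_scale(cube)
  pages <- lapply(seq_len(dim(cube)[3]), function(k) cube[, , k] / sc)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  meta <- c(list(kind = "cube", scale = sc,
                 timestamps_ms = cube_timestamps(cube),
                 pixel_pitch_um = attr(cube, "pixel_pitch")),
            extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cube_tiff
#' @return for `read_cube_tiff`, the restored [video_cube()].
#' @export
read_cube_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  sc <- meta$scale %||% 1
  d <- dim(pages[[1]])
  cube <- array(unlist(pages), c(d[1], d[2], length(pages))) * sc
  pitch <- meta$pixel_pitch_um
  if (is.null(pitch) || !is.numeric(pitch) || !is.finite(pitch)) pitch <- NA_real_
  video_cube(cube, meta$timestamps_ms %||% (seq_along(pages) - 1), pitch)
}

#' Write / read a binary mask stack as multi-page 8-bit TIFF
#'
#' Masks are stored as 0/255 with a JSON sidecar recording fill fraction and
#' seed. Reading rejects any page containing values other than 0 and 255.
#'
#' @param masks a [make_mask_stack()] stack.
#' @param path TIFF path.
#' @return `path` invisibly; for `read_mask_tiff`, the `cofi_masks` stack.
#' @export
write_mask_tiff <- function(masks, path) {
  pages <- lapply(seq_len(dim(masks)[3]), function(k) masks[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(kind = "masks", fill = attr(masks, "fill"),
                            seed = attr(masks, "seed")),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, convert = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  vals <- unlist(pages)
  # 8-bit pages read back as 0..1 in steps of 1/255
  if (!all(vals %in% c(0, 1))) {
    bad <- round(utils::head(vals[!vals %in% c(0, 1)], 1) * 255)
    stop_cofi(sprintf("mask TIFF is not binary: found value %d", bad))
  }
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else list()
  d <- dim(pages[[1]])
  structure(array(unlist(pages), c(d[1], d[2], length(pages))),
            fill = meta$fill %||% NA_real_, seed = meta$seed %||% NA_integer_,
            class = c("cofi_masks", "array"))
}

#' Write / read a coding schedule as CSV
#'
#' Fixed header `code_index,start_ms,exposure_ms`. On read, rows out of
#' order are rejected under `strict = TRUE` (the default) or sorted
#' otherwise; the schedule invariants are always enforced.
#'
#' @param sched a `cofi_schedule`.
#' @param path CSV path.
#' @param strict reject unsorted rows instead of sorting.
#' @return `path` invisibly; for `read_schedule_csv`, the schedule.
#' @export
write_schedule_csv <- function(sched, path) {
  validate_schedule(sched)
  utils::write.csv(as.data.frame(sched)[, c("code_index", "start_ms", "exposure_ms")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path, strict = TRUE) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop_cofi("cannot parse schedule CSV: ",
                                               conditionMessage(e)))
  need <- c("code_index", "start_ms", "exposure_ms")
  if (!all(need %in% names(df))) {
    stop_cofi("schedule CSV must have header code_index,start_ms,exposure_ms")
  }
  if (is.unsorted(df$start_ms, strictly = TRUE)) {
    if (strict) stop_cofi("schedule CSV rows are not sorted by start_ms (strict mode)")
    df <- df[order(df$start_ms), ]
    df$code_index <- seq_len(nrow(df)) - 1L
  }
  validate_schedule(df)
  structure(df, class = c("cofi_schedule", "data.frame"))
}

#' Write / read a snapshot as single-page float TIFF
#'
#' @param snap a `cofi_snapshot`.
#' @param path TIFF path.
#' @return `path` invisibly; for `read_snapshot_tiff`, the snapshot.
#' @export
write_snapshot_tiff <- function(snap, path) {
  sc <- tiff_scale(snap$image)
  suppressWarnings(tiff::writeTIFF(snap$image / sc, path,
                                   bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  meta <- list(kind = "snapshot", scale = sc,
               mask_ref = snap$mask_ref, noise_params = snap$noise_params)
  if (!is.null(snap$schedule)) {
    meta$schedule <- as.data.frame(snap$schedule)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_snapshot_tiff
#' @export
read_snapshot_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  sched <- if (!is.null(meta$schedule)) {
    structure(as.data.frame(meta$schedule),
              class = c("cofi_schedule", "data.frame"))
  } else NULL
  np <- meta$noise_params
  snapshot(img * (meta$scale %||% 1), schedule = sched,
           mask_ref = meta$mask_ref,
           noise_params = if (length(np)) np else NULL)
}

#' Read a solver / experiment configuration file
#'
#' YAML or JSON, decided by extension.
#' @param path config path (`.yaml`/`.yml`/`.json`).
#' @return named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_cofi("config must be .yaml, .yml or .json")
}

#' Experiment presets
#'
#' Fully-specified end-to-end benchmark configurations mirroring the four
#' benchtop experiments: `tracking` (two shaped objects on preset linear
#' trajectories, 20 frames at 300-us intervals, compression ratio 20),
#' `resolution` (the translating three-group line-pair target),
#' `lifetime` (the three-species decay phantom with two flexibly coded
#' snapshots), and `microfluidics` (a 10.14-um microsphere flowing at
#' 1.02 um/ms, 20 frames at 1-ms intervals). Every stochastic stage derives
#' its seed from the preset seed.
#'
#' @param name preset name.
#' @param seed master seed.
#' @param grid reconstruction grid `c(height, width)`; smaller grids give
#'   faster smoke runs.
#' @param admm_iters_per_stage iterations per sigma stage.
#' @return named config list consumed by [run_experiment()].
#' @export
experiment_preset <- function(name = c("tracking", "resolution", "lifetime",
                                       "microfluidics"),
                              seed = 1L, grid = c(128L, 160L),
                              admm_iters_per_stage = 20L) {
  name <- match.arg(name)
  list(experiment = name, seed = as.integer(seed), grid = as.integer(grid),
       # microfluidics is imaged through a 50x objective (15 / 50 um pitch)
       pixel_pitch_um = if (name == "microfluidics") 0.3 else 15,
       supersampling = 4L,
       fill = 0.5, gain = 1, read_sigma = 3,
       admm_iters_per_stage = as.integer(admm_iters_per_stage))
}

stage_seed <- function(seed, k) (as.integer(seed) * 101L + k * 7919L) %% 2147483629L

#' Run an end-to-end benchmark experiment
#'
#' Executes phantom rendering, schedule sampling, coded encoding with sensor
#' noise, plug-and-play ADMM reconstruction, and the experiment's metric
#' suite, writing all intermediates and a machine-readable `run.json` to the
#' output directory (`phantom/`, `encoded/`, `recon/`, `metrics/`,
#' `run.json`, `run.log`). Re-running with the same config yields identical
#' results.
#'
#' @param config a preset from [experiment_preset()], a config list of the
#'   same shape, or a path to a YAML/JSON file of one.
#' @param out_dir output directory (created).
#' @return the results list (also serialized to `run.json`), invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  need <- c("experiment", "seed", "grid")
  bad <- setdiff(need, names(config))
  if (length(bad)) stop_cofi("config is missing keys: ", paste(bad, collapse = ", "))
  if (!config$experiment %in% c("tracking", "resolution", "lifetime",
                                "microfluidics")) {
    stop_cofi("unknown experiment '", config$experiment, "'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("phantom", "encoded", "recon", "metrics")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  }
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cfg_hash <- object_hash(config)
  cat(sprintf("config %s\n", cfg_hash), file = logf)
  t_start <- Sys.time()

  it <- config$admm_iters_per_stage %||% 20L
  # scene-appropriate cascade: spatiotemporal TV for translating extended
  # patterns; spatial-only TV for decays and for the fast compact bead
  cascade <- switch(config$experiment,
    tracking = ,
    resolution = list(denoiser_tv2d(), denoiser_tv3d(temporal_weight = 3)),
    lifetime = list(denoiser_tv2d()),
    microfluidics = list(denoiser_tv2d(strength_scale = 2)))
  solver <- solver_config(
    sigma_schedule = data.frame(sigma_frac = c(0.10, 0.05, 0.02),
                                iters = rep(as.integer(it), 3L)),
    cascade = cascade)
  res <- switch(config$experiment,
    tracking = run_tracking_experiment(config, solver, out_dir, logline),
    resolution = run_resolution_experiment(config, solver, out_dir, logline),
    lifetime = run_lifetime_experiment(config, solver, out_dir, logline),
    microfluidics = run_microfluidics_experiment(config, solver, out_dir, logline))

  res$config_hash <- cfg_hash
  res$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  out <- res
  out$elapsed_s <- NULL  # keep run.json byte-stable across runs
  jsonlite::write_json(out, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("done in %.1f s", res$elapsed_s)
  invisible(res)
}

# Shared encode + reconstruct step; writes intermediates.
encode_reconstruct <- function(scene, sched, config, solver, out_dir, tag,
                               logline) {
  frames <- sample_scene_on_schedule(scene, sched)
  write_cube_tiff(frames, file.path(out_dir, "phantom",
                                    sprintf("%s_frames.tiff", tag)))
  masks <- make_mask_stack(config$grid, nrow(sched), config$fill %||% 0.5,
                           stage_seed(config$seed, 1L))
  snap <- forward_encode(frames, masks, schedule = sched)
  snap <- add_sensor_noise(snap, config$gain %||% 1, config$read_sigma %||% 3,
                           stage_seed(config$seed, 2L))
  write_snapshot_tiff(snap, file.path(out_dir, "encoded",
                                      sprintf("%s_snapshot.tiff", tag)))
  write_schedule_csv(sched, file.path(out_dir, "encoded",
                                      sprintf("%s_schedule.csv", tag)))
  rec <- run_pnp_admm(snap, masks, solver,
                      pixel_pitch = config$pixel_pitch_um %||% 15)
  logline("%s: %d ADMM iterations, final data residual %.4g", tag,
          rec$state$k, utils::tail(rec$state$residual_history$data_residual, 1))
  write_cube_tiff(rec$cube, file.path(out_dir, "recon",
                                      sprintf("%s_recon.tiff", tag)))
  list(frames = frames, recon = rec$cube, state = rec$state)
}

run_tracking_experiment <- function(config, solver, out_dir, logline) {
  spec <- scene_spec(config$grid, config$pixel_pitch_um %||% 15,
                     config$supersampling %||% 4L, duration = 6,
                     seed = config$seed)
  fw <- spec$field_of_view[2]; fh <- spec$field_of_view[1]
  objs <- list(
    object_trajectory("circle", diameter_um = 0.10 * fh, intensity = 500,
                      position_fn = function(t) c(0.30 * fw + 40 * t,
                                                  0.35 * fh + 25 * t),
                      id = "circle"),
    object_trajectory("ellipse", axes_um = c(0.075, 0.045) * fh,
                      orientation_deg = 30, intensity = 500,
                      position_fn = function(t) c(0.70 * fw - 35 * t,
                                                  0.65 * fh - 20 * t),
                      id = "ellipse"))
  scene <- moving_objects_scene(spec, objs)
  sched <- make_schedule("uniform", n_codes = 20, interval_ms = 0.3,
                         exposure_ms = 0.15)
  er <- encode_reconstruct(scene, sched, config, solver, out_dir, "tracking",
                           logline)
  gt <- gt_table(scene, schedule_midtimes(sched))
  utils::write.csv(gt, file.path(out_dir, "phantom", "ground_truth.csv"),
                   row.names = FALSE)
  init <- gt[gt$frame_index == 0L, c("object_id", "x_um", "y_um")]
  tracks <- track_nearest_neighbor(er$recon, init, window_radius_um = 120)
  utils::write.csv(tracks, file.path(out_dir, "metrics", "tracks.csv"),
                   row.names = FALSE)
  pe <- positional_error(tracks, gt)
  list(experiment = "tracking",
       n_frames = nrow(sched),
       max_abs_error_um = pe$max_abs_um,
       mean_abs_error_um = mean(abs(pe$table$mean_error_um)))
}

run_resolution_experiment <- function(config, solver, out_dir, logline) {
  spec <- scene_spec(config$grid, config$pixel_pitch_um %||% 15,
                     config$supersampling %||% 4L, duration = 6,
                     seed = config$seed)
  scene <- bar_target_scene(spec)
  sched <- make_schedule("uniform", n_codes = 20, interval_ms = 0.3,
                         exposure_ms = 0.15)
  er <- encode_reconstruct(scene, sched, config, solver, out_dir,
                           "resolution", logline)
  gt <- gt_table(scene, schedule_midtimes(sched))
  up <- apply_psr(er$recon, 4L)  # line positions measured after PSR
  measured <- do.call(rbind, lapply(seq_len(dim(up)[3]), function(k) {
    bars_k <- gt[gt$frame_index == k - 1L, ]
    mc <- measure_bar_centroids(up[, , k], bars_k,
                                scene$orientation_deg, scene$bar_length_um,
                                attr(up, "pixel_pitch"))
    cbind(data.frame(frame_index = k - 1L), mc)
  }))
  utils::write.csv(measured, file.path(out_dir, "metrics", "bar_centroids.csv"),
                   row.names = FALSE)
  pe <- positional_error(measured, gt)
  # contrast of each group in the mid-sequence frame
  kmid <- ceiling(dim(er$recon)[3] / 2)
  tmid <- cube_timestamps(er$recon)[kmid]
  shift <- scene$velocity_um_per_ms * tmid
  groups <- unique(scene$bars$group)
  contr <- vapply(groups, function(g) {
    bg <- scene$bars[scene$bars$group == g, ]
    ctr <- c(mean(bg$x0_um) + shift[1], mean(bg$y0_um) + shift[2])
    resolvability(er$recon[, , kmid], ctr, scene$orientation_deg,
                  bg$spacing_um[1], nrow(bg), spec$pixel_pitch)$contrast
  }, numeric(1))
  list(experiment = "resolution",
       max_abs_error_um = pe$max_abs_um,
       contrast_by_group = as.list(stats::setNames(
         contr, sprintf("spacing_%g_um", unique(scene$bars$spacing_um)))))
}

run_lifetime_experiment <- function(config, solver, out_dir, logline) {
  spec <- scene_spec(config$grid, config$pixel_pitch_um %||% 15,
                     config$supersampling %||% 4L, duration = 20,
                     seed = config$seed)
  regions <- cat_head_regions(spec)
  scene <- decay_phantom_scene(spec, regions)
  s1 <- schedule_preset("lifetime_snapshot1")
  s2 <- schedule_preset("lifetime_snapshot2")
  er1 <- encode_reconstruct(scene, s1, config, solver, out_dir, "lifetime1",
                            logline)
  # snapshot 2 views the decay after snapshot 1's span
  shifted <- shift_scene(scene, schedule_span(s1))
  er2 <- encode_reconstruct(shifted, s2, config, solver, out_dir, "lifetime2",
                            logline)
  merged <- merge_snapshot_series(er1$recon, s1, er2$recon, s2)
  fits <- lapply(regions, function(r) region_lifetime(merged, r$mask))
  taus <- vapply(fits, `[[`, numeric(1), "tau")
  df <- data.frame(region_id = vapply(regions, `[[`, character(1), "id"),
                   tau_true_ms = vapply(regions, `[[`, numeric(1), "lifetime_ms"),
                   tau_ms = taus,
                   r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
  utils::write.csv(df, file.path(out_dir, "metrics", "region_lifetimes.csv"),
                   row.names = FALSE)
  list(experiment = "lifetime",
       region_lifetimes_ms = as.list(stats::setNames(taus, df$region_id)),
       true_lifetimes_ms = as.list(stats::setNames(df$tau_true_ms, df$region_id)))
}

run_microfluidics_experiment <- function(config, solver, out_dir, logline) {
  # imaged through a 50x objective: sample-plane pitch = native pitch / 50
  pitch <- config$pixel_pitch_um %||% 0.3
  spec <- scene_spec(config$grid, pitch,
                     config$supersampling %||% 4L, duration = 20,
                     seed = config$seed)
  scene <- microsphere_scene(spec)
  sched <- make_schedule("uniform", n_codes = 20, interval_ms = 1,
                         exposure_ms = 0.5)
  er <- encode_reconstruct(scene, sched, config, solver, out_dir,
                           "microfluidics", logline)
  gt <- gt_table(scene, schedule_midtimes(sched))
  init <- gt[gt$frame_index == 0L, c("object_id", "x_um", "y_um")]
  tracks <- track_nearest_neighbor(er$recon, init, window_radius_um = 8)
  utils::write.csv(tracks, file.path(out_dir, "metrics", "track.csv"),
                   row.names = FALSE)
  vfit <- fit_velocity(tracks)
  # SNR: signal around the mid-trajectory bead, background in a far corner
  kmid <- ceiling(dim(er$recon)[3] / 2)
  pos <- gt[gt$frame_index == kmid - 1L, ]
  r_roi <- spec$field_of_view[1] * 0.12
  sig <- circle_roi(dim(er$recon)[1:2], c(pos$x_um, pos$y_um), r_roi, pitch)
  bgr <- circle_roi(dim(er$recon)[1:2],
                    c(spec$field_of_view[2] * 0.12,
                      spec$field_of_view[1] * 0.12), r_roi, pitch)
  sn <- snr(er$recon[, , kmid], sig, bgr)
  list(experiment = "microfluidics",
       speed_um_per_ms = vfit$speed_um_per_ms,
       speed_r_squared = vfit$r_squared,
       snr = sn$snr)
}

# Time-shifted view of a continuous scene (render(t) = scene$render(t + dt)).
shift_scene <- function(scene, dt) {
  out <- scene
  out$render <- function(t) scene$render(t + dt)
  out$ground_truth <- function(t) scene$ground_truth(t + dt)
  out$spec$duration <- max(scene$spec$duration - dt, 0)
  out
}
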