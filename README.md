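# cofi — snapshot compressive temporal fluorescence imaging

`cofi` is an R toolkit for **coded-exposure snapshot compressive imaging**
(SCI) of fast fluorescence dynamics, aimed at researchers who want to
simulate, reconstruct and quantitatively evaluate this acquisition scheme
without access to hardware. A fast spatial light modulator imposes `T`
binary random codes `C_i` during a single camera exposure, so the sensor
records one compressed 2-D measurement of `T` video frames:

    Y = Σᵢ Iᵢ ⊙ Cᵢ            y = Φ x + n

`T` is the compression ratio (CR, typically 10–20): a low-frame-rate
camera gains an order of magnitude in effective frame rate, and because
the coded signal is integrated in one exposure the sensor's read noise is
paid once instead of per frame (the multiplexing advantage).

The video is recovered by **plug-and-play ADMM**: the data-fidelity
subproblem has a closed-form solution because `Φ Φᵀ = diag(R)` with
`R = Σᵢ Cᵢ`, and the prior enters as a denoiser cascade (total variation
by default; trained denoisers can be plugged in). Nonuniform temporal
coding turns the same hardware into a single-shot **phosphorescence
lifetime imager**: two consecutively coded snapshots sample a
mono-exponential decay densely early and sparsely late, and per-pixel
fits of `I(t) = b + A·exp(−t/τ)` yield a lifetime map.

The package covers the full chain:

* **Phantoms** — moving shaped objects, a translating three-group
  line-pair resolution target (45.6/60.8/76 µm at 45°), multi-region
  decay phantoms (τ = 3.2/4.5/7.2 ms), flowing microspheres (10.14 µm at
  1.02 µm/ms), all antialiased on a physical µm grid with ground truth.
* **Encoding** — Bernoulli mask stacks, uniform and segmented coding
  schedules, the forward model, Poisson + read-noise sensor model.
* **Reconstruction** — PnP-ADMM with 2-D/3-D TV and plugin slots, plus a
  cubic-interpolation pixel-super-resolution stage.
* **Lifetime** — schedule merging, bounded Levenberg–Marquardt decay
  fits, per-region estimates and validity-masked lifetime maps.
* **Metrics** — centroid tracking, velocity fits, line-pair positional
  error, ratio-of-means SNR, modulation-contrast resolvability, and
  space–bandwidth–time product bookkeeping.

## Worked example

Encode a translating microsphere into one CR-20 snapshot, reconstruct it,
and recover the flow speed:

```r
library(cofi)

spec  <- scene_spec(pixel_pitch = 0.3, duration = 20)  # 50x objective view
scene <- microsphere_scene(spec)            # 10.14-um bead, 1.02 um/ms
sched <- make_schedule("uniform", n_codes = 20, interval_ms = 1,
                       exposure_ms = 0.5)
frames <- sample_scene_on_schedule(scene, sched)
masks  <- make_mask_stack(dim(frames)[1:2], 20, 0.5, seed = 31)
snap   <- add_sensor_noise(forward_encode(frames, masks, sched),
                           gain = 1, read_sigma = 3, seed = 32)

rec <- run_pnp_admm(snap, masks,
                    solver_config(cascade = list(denoiser_tv2d(strength_scale = 2))),
                    pixel_pitch = spec$pixel_pitch)

gt   <- attr(render_microsphere_flow(spec, timestamps = schedule_midtimes(sched)),
             "centroids")
init <- gt[gt$frame_index == 0, c("object_id", "x_um", "y_um")]
trk  <- track_nearest_neighbor(rec$cube, init, window_radius_um = 8)
fit_velocity(trk)$speed_um_per_ms
#> [1] 1.004591
```

The fitted speed (here `1.0046` µm/ms against the simulated ground truth
of 1.02, i.e. 1.5% off) is what the microfluidic benchmark below reports.
The same pattern — phantom → schedule sampling → coded snapshot →
reconstruction → metric — is wrapped for all four benchmarks in
`run_experiment(experiment_preset("microfluidics"), "out/")`.

## Command-line use

A thin CLI over the same functions ships in `inst/cli/cofi.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cofi.R", package = "cofi"))')" \
    run --preset tracking --seed 1 --out runs/tracking
```

Subcommands: `run`, `encode`, `reconstruct`, `lifetime`, `track`, `snr`.
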