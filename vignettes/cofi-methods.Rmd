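---
title: "Coded snapshot compressive fluorescence imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coded snapshot compressive fluorescence imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofi)
```

## The acquisition model

A fast spatial light modulator imposes a sequence of $T$ binary spatial
codes $C_i \in \{0,1\}^{H\times W}$ during one camera exposure. The camera
integrates the modulated scene, so the single recorded snapshot is

$$ Y \;=\; \sum_{i=1}^{T} I_i \odot C_i , \qquad y = \Phi x + n, $$

where $I_i$ is the scene intensity averaged over code $i$'s exposure
window, $\odot$ is the elementwise product, and $n$ is sensor noise. One
2-D measurement therefore carries $T$ video frames; $T$ is the compression
ratio (CR). Because each code acts diagonally on its own frame,
$\Phi\Phi^{\mathsf T} = \mathrm{diag}(R)$ with
$R = \sum_i C_i^2 = \sum_i C_i$ — the structural fact the reconstruction
exploits.

The sensor model is Poisson shot noise plus additive Gaussian read noise,
clipped at zero:
$y \sim \mathrm{Pois}(\mu\,g)/g + \mathcal N(0,\sigma_r^2)$, with defaults
$g = 1$, $\sigma_r = 3$ counts. Phantom intensities are expected
photoelectron counts (default object peak 500, background 5), so this model
applies without unit conversion. Integrating the coded signal in one
exposure incurs read noise once rather than once per frame — the
multiplexing advantage of coded-exposure imaging, which the test suite
verifies as an SNR ordering against per-frame short exposures in the
read-noise-limited regime.

Masks are i.i.d. Bernoulli with fill 0.5 by default. The fill fraction is
a free design parameter of such systems; 0.5 maximizes code variance and
is the common choice in snapshot compressive imaging. No inter-code
exclusivity is imposed — the diagonal $\Phi\Phi^{\mathsf T}$ update needs
no structure beyond binarity.

## Plug-and-play ADMM reconstruction

The video is recovered by minimizing
$\tfrac12\lVert y-\Phi x\rVert_2^2 + \lambda R(x)$ with the regularizer
expressed implicitly through a denoiser (plug-and-play priors). With an
auxiliary variable $\theta = x$ and augmented-Lagrangian penalty $\rho$,
ADMM alternates three updates:

1. **Data fidelity (closed form).** With $z = \theta + u/\rho$,
   $$x \leftarrow z + \Phi^{\mathsf T}\!\big[(y - \Phi z) \oslash (R + \rho)\big],$$
   the exact minimizer of
   $\tfrac12\lVert y-\Phi x\rVert^2 + \tfrac\rho2\lVert x-z\rVert^2$,
   because $\Phi\Phi^{\mathsf T}$ is diagonal. The unit tests verify this
   update against a dense-matrix solve of the normal equations.
2. **Denoising.** $\theta \leftarrow \mathcal D_\sigma(x - u/\rho)$, where
   $\mathcal D$ is a cascade of denoiser stages.
3. **Dual ascent.** $u \leftarrow u + \rho(\theta - x)$.

A note on sign conventions: textbook treatments differ in whether the
multiplier is attached to $(x-\theta)$ or $(\theta-x)$, and mixing the two
produces a scheme that does not converge. This package uses the
internally consistent set above (multiplier on $\theta - x$); it is the
standard scaled-dual ADMM under the substitution $u \mapsto -u$.

Design choices, all exposed through `solver_config()`:

* **Initialization** $x^0 = \Phi^{\mathsf T}y \oslash \max(R,1)$, the
  mask-normalized backprojection — scale-correct and parameter-free. Note
  its limitation: every frame starts at the same temporally averaged
  image, and the per-frame data term (one equation per pixel for $T$
  unknowns) only gradually separates the frames.
* **Sigma ladder.** The denoiser noise level decreases in stages,
  $\sigma = \{0.10, 0.05, 0.02\} \times$ dynamic range with 20 iterations
  each by default (coarse-to-fine, the common ladder in snapshot
  compressive imaging); $\rho = 1$; the regularization weight is absorbed
  into $\sigma$.
* **Returned estimate.** The final $\theta$ (the prior-consistent,
  denoised iterate), standard plug-and-play practice.
* **Termination.** Fixed iteration budget with early exit when the
  relative primal residual $\lVert x-\theta\rVert/\lVert x\rVert$ falls
  below `tol_primal`. A NaN/Inf iterate aborts with the iteration index.
* All solver arithmetic is double precision; cubes are written to disk as
  32-bit float.

### The denoiser cascade and plugins

The cascade mirrors the slot order of hybrid learned reconstruction
pipelines (a classical TV stage followed by frame-wise and video denoiser
slots), so trained denoisers can be dropped in without code changes: any
callable `fn(cube, sigma)` returning a same-shape array is accepted via
`denoiser_plugin()`. Registration enforces the one invariant every
denoiser must satisfy — a constant input is returned unchanged (to 1e-6
relative). Training such networks is out of scope here; the shipped stages
are classical total variation.

The TV proximal operator
$\min_z \tfrac12\lVert z-x\rVert^2 + \lambda\,\mathrm{TV}(z)$ is solved by
Chambolle's dual projection with a **fixed** 30 inner iterations and dual
step 0.25 — determinism is preferred over adaptive stopping so that
reconstructions are bit-reproducible. `denoiser_tv2d()` applies it per
frame; `denoiser_tv3d()` uses the spatiotemporal gradient with a
configurable temporal weight. The cascade must match the scene's
temporal statistics, and the benchmark experiments make that choice
explicit:

* *Translating extended patterns* (moving cells, the bar target): a
  two-stage cascade — frame-wise TV followed by 3-D TV with temporal
  weight 3. Motion between 300-us frames is sub-pixel, so the temporal
  gradient is the most informative regularization direction, while the
  frame-wise stage limits the temporal mixing ("ghosting") a purely
  spatiotemporal prior leaves behind.
* *Decaying static scenes* (lifetime imaging): frame-wise TV **only**.
  The decay itself lives in the temporal gradient; a temporal-TV prior
  flattens it and biases fitted lifetimes upward.
* *Fast compact objects* (the flowing bead, ~3 px displacement per
  code): frame-wise TV with doubled strength. At that displacement the
  temporal gradient is dominated by genuine motion, so temporal TV
  ghosts the object; stronger spatial TV suppresses the mask-correlated
  background instead.

The middle of the sigma ladder does the ghost suppression; driving sigma
very low late in the ladder reverts the iterate toward the ghost-laden
backprojection and is deliberately avoided.

### Pixel super-resolution

`apply_psr()` upsamples each reconstructed frame on the pixel-centre grid
by separable Catmull-Rom cubic interpolation (factor 2 or 4), clips at
zero, and rescales to preserve each frame's mean intensity. The output
pixel pitch is divided by the factor, and all metric functions then work
in physical micrometres on the finer grid. Line-pair positional metrics
are measured on the 4x-upsampled reconstruction, mirroring pipelines
that place the measurement after the super-resolution module; on the
native 15-um grid the rotated band windows are only a few pixels wide
and their quantization dominates the measurement. A trained
super-resolver can replace the default path through the same plugin
contract. GAN-based super-resolution itself is out of scope.

## Synthetic phantoms: what they emulate

No public raw data exist for the benchtop experiments this package
replicates, so all inputs are generated by the phantom module on a
physical coordinate grid:

* **Moving shaped objects** (`render_moving_objects()`): antialiased
  ellipses/circles on preset trajectories — the cell-motion tracking
  scenario.
* **Line-pair resolution target** (`render_bar_target()`): three groups of
  three bars with centre-to-centre spacings 45.6, 60.8 and 76 um, oriented
  at 45 deg and translating rigidly — the resolution/positional-stability
  scenario. Bar width is half the spacing (a 50% duty square wave across
  the group).
* **Decay phantom** (`render_decay_phantom()`): regions with
  mono-exponential lifetimes (defaults 3.2, 4.5, 7.2 ms, equal amplitude
  500) in a "cat head" layout; overlapping regions sum, emulating
  cross-talk between species, and overlap can be forbidden for clean
  tests.
* **Flowing microsphere** (`render_microsphere_flow()`): a 10.14-um disk
  translating at 1.02 um/ms along the channel axis. This benchmark is
  imaged through a 50x objective, so its scene grid uses the sample-plane
  pixel pitch of 15/50 = 0.3 um (the bead spans ~34 px and moves ~3.4 px
  per 1-ms code interval); on the unmagnified 15-um grid the bead would
  be sub-pixel and its 0.07 px/frame motion unresolvable at CR 20.

Conventions, stated once and used everywhere: 0-based pixel indices;
physical positions in micrometres from the top-left pixel centre (x along
columns, y along rows-down); time in milliseconds from the snapshot
exposure start. The default grid is 128 x 160 pixels at 15-um pitch
(2.4 mm x 1.92 mm field of view). The native camera grid of such systems
is not publicly specified, so the grid is an explicit free parameter and
no particular grid is presented as "the" hardware grid; 15 um makes the
finest bar group about 3 px, a deliberately demanding configuration.

Rendering uses supersampled rasterization (default factor 4; 8 where
sub-pixel centroid ground truth is itself under test) followed by
mean-binning, which conserves flux exactly and gives meaningful sub-pixel
centroid ground truth. What the phantoms do **not** model: optical PSF and
tissue scattering, polarization-optics throughput, modulator switching
transients, camera nonlinearity. Passing tests therefore demonstrate the
correctness of the computational pipeline under an idealized optical
chain, not end-to-end hardware performance.

## Temporal coding schedules and lifetime imaging

`make_schedule()` builds uniform or segmented (nonuniform) code timing;
windows must not overlap, and each code's reference timestamp is its
mid-exposure time — the midpoint rule is exact for locally linear decay
and keeps bias negligible at the exposure/lifetime ratios used here
(relative error below $(\mathrm{exposure}/\tau)^2/24$).

Two library presets implement flexible two-snapshot lifetime coding: the
first snapshot (CR 20) samples the fast initial decay with 10 codes at
300-us intervals then 10 at 600-us (150-us exposures, 8.55-ms span); the
second (CR 10) covers the slow tail with 1-ms intervals and 500-us
exposures. The two snapshots are reconstructed **independently** and
merged on a common clock (`merge_snapshot_series()`), giving 30 samples
per pixel; joint reconstruction across snapshots is not specified by the
acquisition scheme and is not attempted. The inter-snapshot readout gap is
explicit configuration (default 0 ms).

Lifetimes are estimated by least-squares fits of
$I(t) = b + A e^{-t/\tau}$ (Levenberg-Marquardt with box bounds
$\tau \in [0.1, 100]$ ms), initialized from a log-linear regression on the
raw series. The baseline is fitted freely by default; each species is
treated as single-lifetime. The initializer deliberately avoids
subtracting $\min(y)$ — when the observation window truncates the decay,
$\min(y)$ sits far above the true baseline and such an initialization
fails. Scaling the phantom intensity globally leaves $\tau$ invariant
(amplitude and baseline scale). Per-pixel maps (`build_lifetime_map()`)
fit only pixels whose peak intensity reaches an amplitude threshold —
either explicit or `5 x` the robust (MAD) background sigma of a
user-specified background region — and report a validity mask; cross-talk
pixels legitimately show intermediate lifetimes. Multi-exponential and
phasor analyses are out of scope.

## Evaluation metrics

* **Centroid**: intensity-weighted mean position of
  $\max(\mathrm{frame}-\mathrm{bg}, 0)$ over an ROI, in micrometres; the
  default background is the ROI minimum (robust for high-contrast
  targets, configurable).
* **Tracking**: greedy nearest-neighbour — a centroid in a circular window
  centred on the previous position; suitable for the few, well-separated
  objects of these scenes. Lost objects truncate with a warning.
* **Velocity**: per-axis ordinary least squares against time; speed is the
  slope-vector norm.
* **Positional error**: per frame and axis, the mean over line pairs of
  (measured - preset) centroid, each bar measured in a rotated band window
  (within half a spacing perpendicular to the bar, half a length along
  it); the summary is the maximum absolute mean error.
* **SNR**: ratio of the mean intensity in a signal ROI to that in a
  disjoint background ROI, with **no** background subtraction — exactly
  the ratio-of-means definition used for such systems, not a
  variance-based SNR.
* **Resolvability**: modulation contrast
  $(\bar P - \bar T)/(\bar P + \bar T)$ between line-centre peaks and
  mid-gap troughs of the mean profile across a group, plus a local-maxima
  count; a group is resolvable when contrast >= 0.1 (a config-exposed
  threshold reported alongside the contrast, since no standard criterion
  exists) and all expected peaks are found. Spacing converts to spatial
  frequency as $1000/d$ lp/mm.
* **SBTP**: effective resolved pixels x frame rate. The effective pixel
  count is an explicit input — it is not derivable from the field of view
  and resolution limit alone.

## Numerical choices and degenerate inputs

* Schedule windows must be strictly ordered and non-overlapping; reading a
  shuffled schedule CSV fails under `strict = TRUE` or sorts otherwise.
* An all-constant decay series yields `converged = FALSE` rather than an
  arbitrary lifetime; fewer than 4 points is an error.
* A centroid with no positive mass after background subtraction is an
  error, not a silent `NaN`; a tracking window that loses its object
  truncates the track with a warning.
* Tracking ties (equidistant candidates) do not arise in the greedy
  window scheme; the window centre carries identity.
* Intensity TIFFs store values divided by a power-of-two scale (recorded
  in a JSON sidecar) because the TIFF writer maps [0,1] onto 32-bit
  samples; power-of-two scaling is exact in IEEE arithmetic, so the only
  round-trip loss is the writer's uniform quantization, one part in
  $2^{32}$ of the dynamic range.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; repeated runs are bit-identical.

## Problem sizes used in the shipped experiments

The end-to-end benchmark replications (`run_experiment()`, the acceptance
script) run on the default 128 x 160 grid: one CR-20 snapshot for the bar
target and the microsphere, and the CR-20 + CR-10 snapshot pair for the
lifetime phantom, each reconstructed with the three-stage sigma ladder
(60 ADMM iterations, 3-D TV cascade). Unit tests exercise the same code
paths on smaller grids (24 x 30 to 64 x 80) where full-scale runs would
add nothing but time; the spatial scale enters only through the pixel
pitch, which is identical.

## Known limitations

* At CR 20 with a purely classical TV prior, per-frame detail near the
  resolution limit is softer than what trained denoiser cascades achieve;
  the finest (45.6-um, ~3 px) bar group is at the edge of what TV
  recovers on the default grid. On the translating bar target the
  reconstructed line positions retain a residual frame-dependent
  displacement of a fraction of a pixel at the sequence ends (temporal
  mixing that TV alone does not fully undo) — the acceptance script
  reports the exact figure. The plugin contract exists precisely so
  learned video denoisers and super-resolvers can close that gap.
* The backprojection initialization starts every frame at the temporal
  mean, so very fast motion (many pixels per code interval) converges
  slowly; the benchmark scenes move sub-pixel per interval, matching the
  regime the acquisition scheme targets.
* Lifetime accuracy for decays much slower than the coded span degrades
  gracefully (wider confidence, not bias); using both snapshots restores
  precision, which the test suite checks as a variance ordering.
* No convergence theory is claimed for non-expansive-violating plugins;
  the shipped TV stages are proximal operators and inherit standard ADMM
  behaviour.
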