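---
title: "Quantifying chromatin-domain mobility in live-cell 3D movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin-domain mobility in live-cell 3D movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromodyn quantifies how mobile replication-labeled chromatin domains are
inside living nuclei. The input is a two-channel 3D time-lapse movie — a
DNA-dye channel showing the whole nucleus and a nucleotide-label channel
showing point-like chromatin foci — and the output is a set of motion
statistics per experimental condition: the short-range diffusion
coefficient $D$, the anomalous exponent $\alpha$, and the radius of
gyration of each trajectory. This vignette explains the models behind each
stage, the parameters that matter, and what the synthetic-data generator
does and does not emulate.

## The analysis chain

1. **Registration** (`register_sequence()`): every frame of the DNA
   channel is registered onto frame 1 so that whole-cell motion and
   deformation do not masquerade as chromatin motion. The estimated
   transforms are applied to the focus detections, never to the focus
   images, so the foci channel is interpolated zero times.
2. **Detection** (`detect_movie()`): foci are enhanced with a
   scale-normalized Laplacian-of-Gaussian filter and thresholded at
   `mean + k * sd` of the responses pooled over the whole sequence.
3. **Tracking** (`track()`): detections are linked frame to frame with a
   constant-position Kalman filter, a gate, and a globally optimal
   (Hungarian) assignment.
4. **Mobility** (`compute_msd()`, `fit_diffusion()`, `fit_anomalous()`,
   `radius_of_gyration()`): time-averaged mean-square displacement per
   trajectory, ensemble averaging with one vote per trajectory, and two
   model fits.
5. **Nuclear state** (`classify_two_class()`, `classify_seven_class()`,
   `assign_track_class()`): intensity-derived chromatin compaction maps
   and per-trajectory class labels.
6. **Resolution gain** (`resolution_gain()`): full-width-at-half-maximum
   comparison of matched foci in image pairs from two modalities.

## Motion models

For a focus position $r(t)$ in 3D, Brownian motion with diffusion
coefficient $D$ has $\mathrm{MSD}(t) = 6Dt$. Localization error with
isotropic per-axis standard deviation $\sigma$ adds a constant offset, so
the short-range model fitted to the first 50 s of the ensemble curve is

$$\mathrm{MSD}(t) = 6Dt + b, \qquad b \approx 6\sigma^2 ,$$

by least squares with $D \ge 0$, $b \ge 0$. At a frame interval of 5 s
the 50 s window contains exactly 10 lags. Constrained, slower-than-
Brownian motion is captured by the anomalous model fitted to the whole
curve,

$$\mathrm{MSD}(t) = 6\,\Gamma\, t^{\alpha},$$

by nonlinear least squares in linear space, initialized from the log-log
regression (log-space-only fitting would overweight the long, noisy
lags). An exponent $\alpha < 0.9$ (strict) is labeled sub-diffusive. The
radius of gyration $R_g = \sqrt{\langle |r_i - \bar r|^2\rangle}$ is
computed over the first 500 s of each trajectory, so trajectories of
different lengths are compared over the same observation window.

Ensemble averaging weights each trajectory equally rather than each
displacement pair: a long trajectory does not dominate the curve, and the
estimate matches the per-trajectory-then-average definition used for the
fits.

## The synthetic-data generator

Real acquisitions of this kind cannot be shipped with a package, so every
stage is validated by parameter recovery on synthetic movies
(`sim_config()`, `simulate_trajectories()`, `simulate_nucleus()`,
`render_movie()`, `render_psf_pair()`). Defaults follow the acquisition
geometry the analysis is designed for: 48 nm lateral and 170 nm axial
voxels, 5 z-slices, 5 s frame interval, 200 frames, two channels, and an
iPSC-like coefficient $D = 14.99\times10^{-5}\,\mu m^2/s$.

Design choices, each the standard option for its job:

* **Sub-diffusion generator.** The anomalous model only constrains the
  MSD, not the process. We simulate per-axis fractional Brownian motion
  with Hurst $H = \alpha/2$, the stationary-increment Gaussian process
  with exactly $\mathrm{MSD} = 6\Gamma t^\alpha$ (with $\Gamma = D$ at
  $t = 1$ s); increments are drawn by Cholesky factorization of the fBm
  increment covariance.
* **Localization error** is additive isotropic Gaussian noise on the
  reported positions — the textbook origin of the bias term $b$.
* **Nucleus boundary.** Positions are reflected specularly across the
  tangent plane of the ellipsoidal boundary at the radially-projected
  surface point. A whole-vector radial rescale (the obvious shortcut)
  injects large tangential jumps in flat nuclei and visibly inflates the
  MSD; the specular rule moves a point by about twice its penetration
  depth along the local normal and leaves the MSD of interior motion
  untouched.
* **Global cell motion** is a per-frame small-angle rotation plus a
  linear drift (direction drawn once per simulation, mostly lateral) and
  an optional low-frequency sinusoidal displacement field — exactly the
  transform family the registration module estimates, so recovery is
  well-posed.
* **Imaging model.** Foci are anisotropic Gaussians with per-axis sigma
  `psf_fwhm / 2.3548` combined with the focus's own size; amplitudes
  decay as $e^{-\text{bleach\_rate}\, t}$; Poisson shot noise is applied
  before Gaussian read noise. With noise off, the frame-summed signal
  decays exactly at the bleach rate, and the integrated spot mass matches
  the analytic Gaussian integral — both are asserted in the tests.
* **Foci size** is a free parameter (`focus_sigma_range`), not asserted:
  the true physical size distribution of labeled domains is unknown.

What the generator does **not** emulate: camera-specific noise
calibration, spectral cross-talk, z-dependent PSF aberrations, focus
blinking, and replication biology. Passing recovery tests therefore shows
the chain is unbiased under the stated model, not that it is robust to
every real-microscope artifact.

## Registration

The transform class is affine plus a dense displacement field, stored as
the pull-back map from reference coordinates to moving-frame coordinates.
The affine stage initializes the translation by FFT cross-correlation and
refines a translation-only or rigid parameterization by Nelder-Mead on
normalized cross-correlation over a 3-level lateral resolution pyramid
(4x, 2x, 1x; the 5-slice axis is never downsampled). The non-rigid stage
is a multi-resolution Thirion demons iteration: the update field is
smoothed with a Gaussian of `sigma_reg = 2` voxels (fluid-like
regularization) and the accumulated field with `0.7` voxels. Smoothing
the accumulated field at the full `sigma_reg` every iteration — the other
common variant — steadily erodes the recovered amplitude and roughly
doubles the residual on sinusoidal test fields, which is why the split
regularization is the default here. Registration never degrades the
similarity metric: if the optimized transform scores below identity, the
identity is returned with a non-convergence flag.

Frames are registered on the DNA channel only and the transforms applied
to detections from the foci channel as exact point mappings
(`register_detections()`), avoiding a second interpolation of the signal
of interest. Anisotropic voxels are handled by working in physical
micrometres throughout.

## Detection and tracking

The LoG scale should match the spot size (the PSF sigma for
diffraction-limited foci) and is a required, visible parameter; the
default threshold factor `k_factor = 4` is set by the false-positive
property that pure-noise volumes yield no detections at `k = 8` in at
least 95% of seeded repeats, while SNR >= 5 spots are kept with recall
and precision >= 0.95. Threshold statistics are pooled over the whole
sequence so detection counts are comparable across frames. Sub-voxel
positions come from per-axis parabolic interpolation of the response peak
(a weighted centroid over a 3-voxel window is biased toward the grid and
misses the 0.1-voxel noiseless bound; the parabola meets it with an
order of magnitude to spare). With 5 z-slices, z-localization is
intrinsically coarse and z positions should be treated as low-precision.

The tracker is the Kalman/global-assignment core of the probabilistic
scheme used in this field: a constant-position random-walk motion model
(chromatin shows constrained diffusion, so zero velocity is the right
prior), squared-Euclidean gated costs, Hungarian assignment (implemented
in-package and tested against the exhaustive-permutation minimum), and a
one-frame default gap allowance with no interpolation across gaps — MSD
lags always use true frame differences. Track merging/splitting and
intensity-based re-identification are out of scope. Two duration presets
mirror the two analysis stages: 10 steps (about 50 s) for MSD fitting,
100 steps (500 s) for the radius-of-gyration analysis.

## Compaction classification

The live-cell path fits a 2-component Gaussian mixture to the inside-mask
DNA intensities per frame (mclust, deterministic seeded subsample) and
hard-assigns voxels; class 1 is the lower-mean euchromatin-like class.
Degenerate fits fall back to an Otsu split and say so. The fixed-cell
path is a 7-class model: quantile-initialized Gaussian classes refined by
iterated conditional modes under a Potts prior (`beta = 0.5` default) on
the 6-neighbourhood, with class parameters re-estimated each sweep.
Class means are relabeled to increase with the class index, so class 1 is
interchromatin and classes 4-7 the most compacted compartment. At
`beta = 0` the result provably equals per-voxel maximum-likelihood
classification, which is the oracle test. Whether the live-cell GMM
should be fitted per frame or pooled is not determined by the method
description we follow; per-frame is the default, and pooled fitting is a
one-line change (classify once, reuse the map).

Nucleus segmentation uses a two-level Otsu: the first threshold on the
smoothed volume can land between the euchromatin and heterochromatin
modes, so a second Otsu on the sub-threshold intensities separates
background from nucleus. A one-voxel lateral erosion recenters the
smoothing-dilated boundary. The morphometric shape factor is 3D
sphericity $\pi^{1/3}(6V)^{2/3}/A$ with the surface area $A$ from the
coarea formula on a lightly smoothed indicator (within a few tenths of a
percent on digital balls, clipped at the isoperimetric bound of 1).

## Resolution gain

Foci detected independently in the two modality images are matched
one-to-one by minimum total distance with a 0.3 um gate (about one
confocal FWHM; the method description gives no gate). Intensity profiles
are sampled along a horizontal 1 um line at each matched detection with
linear interpolation at the subpixel row, averaged, min-max normalized,
and the FWHM read off between the half-maximum crossings by linear
interpolation. The horizontal-only line is deliberate (it follows the
measurement definition); FWHM is invariant to affine intensity changes.

## Numerical and scale choices

Tests and the acceptance script scale the simulations to desk size:
500-2000 trajectories of about 100 steps for the mobility recoveries,
5 x 64 x 64 to 5 x 96 x 96 voxel movies with 3-100 frames for the imaging
stages, and 50 emitters per modality for the FWHM chain. These sizes keep
every recovery within its stated tolerance (10% on $D$ and FWHM, 0.05 on
$\alpha$) with comfortable margins while a full suite run stays in the
minutes range. Degenerate inputs are contracts, not surprises: constant
volumes are rejected by registration and return empty detection sets with
a flag; all-outside trajectories vote "unassigned"; empty signal
segmentations return zero fractions with a flag rather than NaNs.

## Known limitations

* The tracker omits the particle-filter/multi-sensor fusion layer of the
  full published scheme; at the spot densities the recovery tests use,
  the Kalman/Hungarian core links >= 90% of ground-truth connections, but
  very dense scenes would benefit from the fuller model.
* The 7-class map is a documented quantile-init + Potts/ICM scheme, not a
  re-implementation of any specific published HMRF estimation procedure.
* z-localization with 5 slices is coarse; mobility statistics are
  dominated by the lateral components in this geometry.
* Registration assumes the first frame is a usable reference; no
  groupwise or temporally regularized registration is attempted.
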