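# chromodyn

Chromatin-domain mobility analysis for live-cell 3D fluorescence
microscopy.

Replication-labeled chromatin appears in a microscope as hundreds of
diffraction-limited foci per nucleus. How far and how freely those foci
move reports on chromatin compaction and changes with cell state — for
example, chromatin slows down as pluripotent stem cells differentiate
into neurons. Measuring that motion from a 5-D movie
(time × channel × z × y × x) requires a chain of image computations, each
of which can silently bias the result. chromodyn implements the whole
chain as composable, tested R functions for microscopists and
computational biologists:

* **Drift correction** — joint affine + non-rigid 3D registration of the
  DNA channel onto frame 1; transforms are applied to focus *detections*,
  so the signal channel is never resampled.
* **Focus detection** — spot-enhancing filter: scale-normalized
  Laplacian-of-Gaussian, automatic `mean + k·sd` threshold pooled over
  the sequence, sub-voxel localization.
* **Tracking** — Kalman-predicted, gated, globally optimal (Hungarian)
  frame-to-frame assignment with gap tolerance and duration filters.
* **Mobility statistics** — time-averaged MSD per trajectory, ensemble
  average with one vote per trajectory, and two fits:
  `MSD(t) = 6Dt + b` over the first 50 s (the bias `b ≈ 6σ²` absorbs
  localization error) and `MSD(t) = 6Γt^α` over the whole curve
  (α < 0.9 ⇒ sub-diffusion); radius of gyration over 500 s windows.
* **Chromatin state** — nucleus segmentation, 2-class GMM
  (euchromatin/heterochromatin) and 7-class Potts/ICM compaction maps,
  majority-vote trajectory stratification, nuclear morphometry
  (volume, sphericity, DNA sum/sd).
* **Resolution gain** — FWHM of normalized averaged 1 µm intensity
  profiles through Hungarian-matched foci in confocal/STED image pairs.
* **Synthetic data** — a forward generator (Brownian/fractional-Brownian
  foci, PSF blur, Poisson+Gaussian noise, photobleaching, global cell
  motion) with full ground truth, so every stage is validated by
  parameter recovery rather than by eye.

## Worked example

Simulate 500 trajectories at the iPSC-like diffusion coefficient
`D = 14.99e-5 µm²/s` with 30 nm localization noise, then recover the
mobility statistics:

```r
library(chromodyn)

cfg    <- sim_config(n_foci = 500, n_frames = 101, D = 14.99e-5,
                     loc_noise_sigma = 0.03, seed = 1)
truth  <- simulate_trajectories(cfg, nucleus_ellipsoid(c(10, 10, 10)))
tracks <- truth_tracks(truth, "observed")

msd <- compute_msd(tracks, dt = cfg$dt, max_lag = 250)
head(tibble::as_tibble(msd), 3)
#> # A tibble: 3 × 4
#>   lag_s msd_um2 n_tracks n_pairs
#>   <dbl>   <dbl>    <dbl>   <dbl>
#> 1     5 0.00988      500   50000
#> 2    10 0.0144       500   49500
#> 3    15 0.0189       500   49000

fit_diffusion(msd, fit_window = 50)
#> <diffusion_fit> MSD = 6 D t + b: D = 0.0001466 um^2/s, b = 0.005611 um^2 (window 50 s, rms 6.64e-05)

fit_anomalous(msd)
#> <anomalous_fit> MSD = 6 G t^a: Gamma = 0.0002158, alpha = 0.930 (normal-or-super)

rg <- radius_of_gyration(tracks, dt = cfg$dt, duration = 500)
mean(rg$rg_um)
#> [1] 0.266
```

The fitted `D = 1.466e-4` recovers the simulated `1.499e-4` within
2.2%, and `b = 0.0056` matches the localization floor
`6σ² = 6·(0.03)² = 0.0054`. The MSD at the first lag, 0.00988 µm²,
equals the closed form `6·D·Δt + 6σ² = 0.0099`. α near 1 correctly
reports free diffusion for this unconfined simulation.

For image-level work, `run_pipeline()` chains
register → detect → track → stratify → fit on a `movie5d` object (or on
a rendered simulation) and writes tracks/MSD/rg/fit tables stamped with
a config hash; `read_movie()`/`write_movie()` handle multi-page TIFF
with a JSON metadata sidecar (OME-style ImageDescription metadata is
parsed when present). `autoplot()` methods plot MSD curves and intensity
profiles; `tidy()`/`glance()` extract fit parameters as tibbles.

See the vignette (`vignettes/chromatin-mobility.Rmd`) for the models,
parameter choices, and the limits of what synthetic-data validation
shows.

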