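#' Simulation configuration for synthetic chromatin movies
#'
#' Defaults emulate the study acquisition geometry: 48 nm lateral and
#' 170 nm axial voxels, 5 z-slices, frame interval dt = 5 s, 200 frames,
#' and an iPSC-like short-range diffusion coefficient
#' D = 14.99e-5 um^2/s with 30 nm per-axis localization error.
#'
#' @param n_foci number of chromatin foci.
#' @param n_frames number of time points.
#' @param dt frame interval, seconds.
#' @param voxel_size (z, y, x) voxel edges, um.
#' @param image_shape (z, y, x) volume size in voxels.
#' @param D diffusion coefficient, um^2/s. For `alpha != 1` this is the
#'   generalized coefficient Gamma in MSD = 6 * Gamma * t^alpha (um^2/s^alpha),
#'   i.e. D at t = 1 s.
#' @param alpha anomalous exponent in (0, 2]; 1 = Brownian.
#' @param loc_noise_sigma isotropic per-axis localization error, um.
#' @param psf_fwhm (z, y, x) PSF full width at half maximum, um.
#' @param focus_sigma_range range (min, max) of true focus Gaussian sigma, um;
#'   c(0, 0) renders diffraction-limited points.
#' @param photon_scale expected peak signal photons per focus at t = 0.
#' @param background expected background photons per voxel.
#' @param read_noise_sd Gaussian read noise sd, photons (0 = none).
#' @param shot_noise apply Poisson noise?
#' @param bleach_rate photobleaching decay rate, 1/s.
#' @param motion_amplitude scale of the global cell drift, um (0 = none).
#' @param motion_rotation max global rotation, degrees.
#' @param nonrigid_amplitude amplitude of the smooth non-rigid motion
#'   component, um (0 = none).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_foci = 100L,
                       n_frames = 200L,
                       dt = 5,
                       voxel_size = c(0.170, 0.048, 0.048),
                       image_shape = c(5L, 128L, 128L),
                       D = 14.99e-5,
                       alpha = 1,
                       loc_noise_sigma = 0.03,
                       psf_fwhm = c(0.5, 0.2, 0.2),
                       focus_sigma_range = c(0, 0),
                       photon_scale = 200,
                       background = 5,
                       read_noise_sd = 2,
                       shot_noise = TRUE,
                       bleach_rate = 0.001,
                       motion_amplitude = 0,
                       motion_rotation = 0,
                       nonrigid_amplitude = 0,
                       seed = 1L) {
  cfg <- list(n_foci = as.integer(n_foci), n_frames = as.integer(n_frames),
              dt = dt, voxel_size = as.numeric(voxel_size),
              image_shape = as.integer(image_shape), D = D, alpha = alpha,
              loc_noise_sigma = loc_noise_sigma, psf_fwhm = as.numeric(psf_fwhm),
              focus_sigma_range = as.numeric(focus_sigma_range),
              photon_scale = photon_scale, background = background,
              read_noise_sd = read_noise_sd, shot_noise = shot_noise,
              bleach_rate = bleach_rate, motion_amplitude = motion_amplitude,
              motion_rotation = motion_rotation,
              nonrigid_amplitude = nonrigid_amplitude, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$dt <= 0) abort("dt must be > 0")
  if (cfg$D < 0) abort("D must be >= 0")
  if (cfg$alpha <= 0 || cfg$alpha > 2) abort("alpha must lie in (0, 2]")
  if (any(cfg$voxel_size <= 0) || any(cfg$image_shape <= 0)) {
    abort("voxel sizes and image shape must be positive")
  }
  if (cfg$n_frames < 1L || cfg$n_foci < 0L) abort("n_frames >= 1 and n_foci >= 0 required")
  if (cfg$loc_noise_sigma < 0) abort("loc_noise_sigma must be >= 0")
  invisible(cfg)
}
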