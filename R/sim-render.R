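# Forward imaging model: render ground-truth trajectories and DNA texture
# into a noisy two-channel movie with global cell motion, PSF blur,
# photobleaching, and Poisson + Gaussian noise.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548

# True per-frame global motion (reference -> frame coords), frame 1 identity.
make_motion_series <- function(config, nz_ny_nx = config$image_shape) {
  nf <- config$n_frames
  vs <- config$voxel_size
  extent <- vs * (nz_ny_nx - 1L)
  center <- extent / 2
  set.seed(config$seed + 1000L)
  # drift is almost purely lateral: thin 5-slice stacks track focus, and
  # axial stage drift is small compared to lateral drift in practice
  dir <- rnorm(3); dir[1L] <- dir[1L] * 0.05
  dir <- dir / sqrt(sum(dir^2))
  ph <- runif(4, 0, 2 * pi)
  lapply(seq_len(nf), function(t) {
    s <- if (nf > 1L) (t - 1) / (nf - 1) else 0
    theta <- config$motion_rotation * pi / 180 * s
    R <- diag(3)
    R[2:3, 2:3] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
    b <- as.numeric(center - R %*% center) + config$motion_amplitude * s * dir
    disp <- NULL
    if (config$nonrigid_amplitude > 0 && s > 0) {
      d <- nz_ny_nx
      yc <- (seq_len(d[2L]) - 1L) * vs[2L]
      xc <- (seq_len(d[3L]) - 1L) * vs[3L]
      wy <- sin(pi * yc / max(extent[2L], 1e-9))
      wx <- sin(pi * xc / max(extent[3L], 1e-9))
      base_y <- outer(wy, sin(2 * pi * xc / max(extent[3L], 1e-9) + ph[1L]))
      base_x <- outer(sin(2 * pi * yc / max(extent[2L], 1e-9) + ph[2L]), wx)
      a <- config$nonrigid_amplitude * s
      dy <- aperm(array(rep(a * base_y, each = d[1L]), dim = d), c(1L, 2L, 3L))
      dx <- aperm(array(rep(a * base_x, each = d[1L]), dim = d), c(1L, 2L, 3L))
      disp <- list(dz = array(0, d), dy = dy, dx = dx)
    }
    transform3d(A = R, b = b, disp = disp, voxel_size = vs)
  })
}

# Add one anisotropic Gaussian spot (amplitude photons at peak) in place.
add_spot <- function(vol, center_um, sigma_um, amplitude, voxel_size) {
  d <- dim(vol)
  ci <- center_um / voxel_size + 1           # continuous 1-based index
  half <- pmax(ceiling(4 * sigma_um / voxel_size), 1L)
  lo <- pmax(floor(ci - half), 1L)
  hi <- pmin(ceiling(ci + half), d)
  if (any(lo > hi)) return(vol)
  zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
  gz <- exp(-((zi - ci[1L]) * voxel_size[1L])^2 / (2 * sigma_um[1L]^2))
  gy <- exp(-((yi - ci[2L]) * voxel_size[2L])^2 / (2 * sigma_um[2L]^2))
  gx <- exp(-((xi - ci[3L]) * voxel_size[3L])^2 / (2 * sigma_um[3L]^2))
  vol[zi, yi, xi] <- vol[zi, yi, xi, drop = FALSE] +
    amplitude * outer(outer(gz, gy), gx)
  vol
}

#' Render a synthetic two-channel movie from ground truth
#'
#' Channel 1 is the DNA texture transported by the global cell motion;
#' channel 2 is the sum of anisotropic Gaussian spots (per-axis sigma =
#' `psf_fwhm / 2.3548`, combined with each focus's true size) at the true
#' focus positions, with amplitude decaying as `exp(-bleach_rate * t)`,
#' plus background. Poisson shot noise is applied first, then Gaussian
#' read noise. The true per-frame transform series is recorded.
#'
#' @param truth a `sim_truth` from [simulate_trajectories()].
#' @param config the [sim_config()] used to generate it.
#' @return A list: `movie` ([movie5d()]), `truth` (with `$transforms`
#'   filled in: one [transform3d()] per frame, frame 1 = identity).
#' @export
render_movie <- function(truth, config) {
  validate_sim_config(config)
  d <- config$image_shape
  vs <- config$voxel_size
  nucleus <- truth$nucleus
  if (is.null(nucleus$dna)) {
    nucleus <- simulate_nucleus(shape = d, voxel_size = vs,
                                semiaxes = nucleus$semiaxes, seed = config$seed)
    truth$nucleus <- nucleus
  }
  if (!all(dim(nucleus$dna) == d)) abort("nucleus texture does not match image_shape")

  transforms <- make_motion_series(config)
  moving_any <- config$motion_amplitude > 0 || config$motion_rotation > 0 ||
    config$nonrigid_amplitude > 0

  nf <- config$n_frames
  psf_sigma <- config$psf_fwhm * FWHM_TO_SIGMA
  tr <- truth$tracks
  sizes <- truth$focus_sizes$sigma_um
  data <- array(0, dim = c(nf, 2L, d))
  grid <- if (moving_any) grid_coords(d, vs) else NULL

  set.seed(config$seed + 2000L)
  for (t in seq_len(nf)) {
    m <- transforms[[t]]
    # channel 1: DNA texture transported by the motion
    if (moving_any && !is_identity_transform(m)) {
      X <- t3d_inverse(m, grid)
      dna_t <- interp3(nucleus$dna, X[, 1L] / vs[1L] + 1,
                       X[, 2L] / vs[2L] + 1, X[, 3L] / vs[3L] + 1)
      dim(dna_t) <- d
    } else {
      dna_t <- nucleus$dna
    }
    # channel 2: foci
    foci <- array(config$background, d)
    rows <- which(tr$frame == t)
    amp <- config$photon_scale * exp(-config$bleach_rate * (t - 1) * config$dt)
    if (length(rows)) {
      P <- as.matrix(tr[rows, c("z_um", "y_um", "x_um")])
      if (moving_any) P <- t3d_forward(m, P)
      for (i in seq_along(rows)) {
        fs <- if (length(sizes)) sizes[tr$focus_id[rows[i]]] else 0
        sig <- sqrt(psf_sigma^2 + fs^2)
        foci <- add_spot(foci, P[i, ], sig, amp, vs)
      }
    }
    if (config$shot_noise) {
      dna_t <- array(rpois(length(dna_t), pmax(dna_t, 0)), d)
      foci <- array(rpois(length(foci), pmax(foci, 0)), d)
    }
    if (config$read_noise_sd > 0) {
      dna_t <- dna_t + rnorm(length(dna_t), 0, config$read_noise_sd)
      foci <- foci + rnorm(length(foci), 0, config$read_noise_sd)
    }
    data[t, 1L, , , ] <- dna_t
    data[t, 2L, , , ] <- foci
  }

  truth$transforms <- transforms
  list(movie = movie5d(data, vs, config$dt, c("dna", "foci")), truth = truth)
}

#' Render a matched confocal/STED-like image pair
#'
#' The same point emitters rendered twice with different PSF widths,
#' emulating confocal and STED acquisitions of the same cell.
#'
#' @param points n x 2 matrix or data frame with `y_um`, `x_um` emitter
#'   positions.
#' @param fwhm_a,fwhm_b PSF FWHM of the two modalities, um.
#' @param pixel pixel size, um.
#' @param shape (ny, nx) image size in pixels; default fits the points
#'   with a 1 um margin.
#' @param amplitude expected peak photons per emitter.
#' @param background expected background photons per pixel.
#' @param shot_noise apply Poisson noise?
#' @param seed integer seed.
#' @return List: `image_a`, `image_b` ((y, x) matrices), `points` (tibble,
#'   um), `pixel`.
#' @export
render_psf_pair <- function(points, fwhm_a, fwhm_b, pixel = 0.02,
                            shape = NULL, amplitude = 500, background = 5,
                            shot_noise = TRUE, seed = 1L) {
  if (is.data.frame(points)) points <- cbind(points$y_um, points$x_um)
  points <- matrix(as.numeric(points), ncol = 2L)
  if (nrow(points) > 1L) {
    dm <- as.matrix(stats::dist(points))
    diag(dm) <- Inf
    if (min(dm) < 2 * max(fwhm_a, fwhm_b)) {
      warn("emitters closer than 2 x max(FWHM): intensity profiles will mix")
    }
  }
  if (is.null(shape)) {
    shape <- ceiling((apply(points, 2L, max) + 1) / pixel) + 1L
  }
  render_one <- function(fwhm) {
    sig <- fwhm * FWHM_TO_SIGMA
    vol <- array(background, dim = c(1L, shape))
    for (i in seq_len(nrow(points))) {
      vol <- add_spot(vol, c(0, points[i, ]), c(Inf, sig, sig), amplitude,
                      c(1, pixel, pixel))
    }
    img <- vol[1L, , ]
    if (shot_noise) img <- matrix(rpois(length(img), pmax(img, 0)), shape[1L])
    img
  }
  set.seed(seed)
  image_a <- render_one(fwhm_a)
  image_b <- render_one(fwhm_b)
  list(image_a = image_a, image_b = image_b,
       points = tibble(y_um = points[, 1L], x_um = points[, 2L]), pixel = pixel)
}
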