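#' Simulate a nucleus mask and DNA-intensity texture
#'
#' Builds an ellipsoidal nucleus (optionally with a smooth radial
#' perturbation) and fills it with a two-component intensity mixture:
#' low-mean euchromatin-like voxels and high-mean heterochromatin-like
#' voxels arranged in smooth spatial blobs (thresholded Gaussian random
#' field), emulating a DNA-dye channel. True per-voxel class labels are
#' retained for parameter-recovery tests.
#'
#' @param shape (z, y, x) volume size in voxels.
#' @param voxel_size (z, y, x) voxel edges, um.
#' @param semiaxes ellipsoid semi-axes (z, y, x), um; default 42.5% of the
#'   field extent.
#' @param mean_eu,mean_het mixture component mean intensities.
#' @param sd_intensity within-class intensity sd.
#' @param het_fraction target heterochromatin volume fraction inside the mask.
#' @param blob_sigma_um correlation length of the compaction blobs, um.
#' @param perturb relative amplitude of the smooth boundary perturbation.
#' @param seed integer seed.
#' @return A `sim_nucleus` list: `mask` (logical z,y,x), `dna` (numeric),
#'   `labels` (0 outside, 1 = euchromatin-like, 2 = heterochromatin-like),
#'   `center`, `semiaxes`, `voxel_size`.
#' @export
simulate_nucleus <- function(shape = c(5L, 128L, 128L),
                             voxel_size = c(0.170, 0.048, 0.048),
                             semiaxes = NULL,
                             mean_eu = 100, mean_het = 300,
                             sd_intensity = 20,
                             het_fraction = 0.5,
                             blob_sigma_um = 0.25,
                             perturb = 0,
                             seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 1L)) abort("degenerate nucleus shape")
  set.seed(seed)
  extent <- voxel_size * (shape - 1L)
  center <- extent / 2
  if (is.null(semiaxes)) semiaxes <- 0.425 * extent
  if (any(semiaxes > extent / 2 + 1e-9)) abort("nucleus does not fit inside the volume")

  zc <- (seq_len(shape[1L]) - 1L) * voxel_size[1L]
  yc <- (seq_len(shape[2L]) - 1L) * voxel_size[2L]
  xc <- (seq_len(shape[3L]) - 1L) * voxel_size[3L]
  U2 <- outer(outer(((zc - center[1L]) / semiaxes[1L])^2,
                    ((yc - center[2L]) / semiaxes[2L])^2, `+`),
              ((xc - center[3L]) / semiaxes[3L])^2, `+`)
  dim(U2) <- shape

  radius <- 1
  if (perturb > 0) {
    # low-order angular modulation of the boundary radius
    ph <- runif(3, 0, 2 * pi)
    Y <- outer(outer(rep(1, shape[1L]), yc - center[2L]), rep(1, shape[3L]))
    X <- outer(outer(rep(1, shape[1L]), rep(1, shape[2L])), xc - center[3L])
    theta <- atan2(Y, X)
    radius <- 1 + perturb * (sin(2 * theta + ph[1L]) * 0.6 + sin(3 * theta + ph[2L]) * 0.4)
    dim(radius) <- shape
  }
  mask <- U2 <= radius^2

  # smooth random field -> heterochromatin blobs at the target fraction
  sig_vox <- blob_sigma_um / voxel_size
  field <- gauss_smooth(array(rnorm(prod(shape)), shape), sig_vox)
  thr <- quantile(field[mask], probs = 1 - het_fraction, names = FALSE)
  labels <- array(0L, shape)
  labels[mask] <- 1L
  labels[mask & field >= thr] <- 2L

  dna <- array(0, shape)
  nin <- sum(mask)
  dna[labels == 1L] <- rnorm(sum(labels == 1L), mean_eu, sd_intensity)
  dna[labels == 2L] <- rnorm(sum(labels == 2L), mean_het, sd_intensity)
  dna[dna < 0] <- 0

  structure(list(mask = mask, dna = dna, labels = labels,
                 center = center, semiaxes = semiaxes,
                 voxel_size = as.numeric(voxel_size)),
            class = "sim_nucleus")
}
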