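# Ground-truth trajectory simulation: Brownian motion (alpha = 1) or
# per-axis fractional Brownian motion with Hurst H = alpha/2, scaled so
# the ensemble 3-D MSD is 6 * Gamma * t^alpha with Gamma = D at t = 1 s.

#' Simulate ground-truth chromatin focus trajectories
#'
#' For `alpha = 1` per-axis increments are i.i.d. Gaussian with variance
#' `2 * D * dt` (3-D MSD `6 D t`). For `alpha != 1` each axis is a
#' fractional Brownian motion with Hurst `alpha/2` and per-axis variance
#' `2 * D * t^alpha`, so the 3-D MSD is `6 * D * t^alpha`. Positions are
#' reflected at the nucleus boundary; reported (observed) positions add
#' isotropic Gaussian localization noise of sd `loc_noise_sigma` per axis.
#'
#' @param config a [sim_config()].
#' @param nucleus a [simulate_nucleus()] result, or `NULL` for a smooth
#'   ellipsoid filling 85% of the field of view.
#' @param min_separation minimum initial distance between foci, um
#'   (0 = unconstrained); use >= the PSF width to emulate resolvable foci.
#' @return A `sim_truth` list with `$tracks` (tibble: focus_id, frame,
#'   true `z_um,y_um,x_um` and observed `z_obs_um,y_obs_um,x_obs_um`),
#'   `$focus_sizes`, `$nucleus`, and `$config`.
#' @export
simulate_trajectories <- function(config, nucleus = NULL, min_separation = 0) {
  validate_sim_config(config)
  set.seed(config$seed)
  if (is.null(nucleus)) nucleus <- analytic_nucleus(config)
  if (!is.null(nucleus$mask) && !any(nucleus$mask)) abort("nucleus mask is empty")

  n <- config$n_foci
  nf <- config$n_frames
  p0 <- place_foci(nucleus, n, min_separation)

  pos <- array(0, dim = c(nf, 3L, n))
  pos[1L, , ] <- t(p0)
  if (nf > 1L && n > 0L) {
    inc <- simulate_increments(config, n)   # (nf-1) x 3 x n
    for (f in 2:nf) {
      prev <- matrix(pos[f - 1L, , ], nrow = 3L)
      step <- matrix(inc[f - 1L, , ], nrow = 3L)
      pos[f, , ] <- reflect_nucleus(prev + step, nucleus)
    }
  }

  sizes <- if (n > 0L) {
    runif(n, config$focus_sigma_range[1L], config$focus_sigma_range[2L])
  } else numeric(0)

  obs <- pos
  if (config$loc_noise_sigma > 0 && n > 0L) {
    obs <- pos + array(rnorm(length(pos), 0, config$loc_noise_sigma), dim(pos))
  }

  tracks <- tibble(
    focus_id = rep(seq_len(n), each = nf),
    frame = rep(seq_len(nf), times = n),
    z_um = as.vector(pos[, 1L, ]), y_um = as.vector(pos[, 2L, ]),
    x_um = as.vector(pos[, 3L, ]),
    z_obs_um = as.vector(obs[, 1L, ]), y_obs_um = as.vector(obs[, 2L, ]),
    x_obs_um = as.vector(obs[, 3L, ]))

  structure(list(
    tracks = tracks,
    focus_sizes = tibble(focus_id = seq_len(n), sigma_um = sizes),
    nucleus = nucleus, config = config, transforms = NULL),
    class = "sim_truth")
}

# Increment array (nf-1) x 3 x n_foci.
simulate_increments <- function(config, n) {
  nf <- config$n_frames
  m <- nf - 1L
  if (config$alpha == 1) {
    sdd <- sqrt(2 * config$D * config$dt)
    return(array(rnorm(m * 3L * n, 0, sdd), dim = c(m, 3L, n)))
  }
  a <- config$alpha
  k <- 0:(m - 1L)
  g <- config$D * config$dt^a * (abs(k + 1)^a - 2 * abs(k)^a + abs(k - 1)^a)
  G <- stats::toeplitz(g)
  diag(G) <- diag(G) + 1e-12 * max(g)
  R <- chol(G)
  Z <- matrix(rnorm(m * 3L * n), nrow = m)
  array(crossprod(R, Z), dim = c(m, 3L, n))
}

#' Analytic ellipsoidal nucleus
#'
#' A mask-free ellipsoid usable wherever a [simulate_nucleus()] result is
#' accepted, e.g. to simulate trajectories in a roomy volume where
#' boundary confinement is negligible.
#'
#' @param semiaxes (z, y, x) semi-axes, um.
#' @param center (z, y, x) centre, um; default = semiaxes.
#' @param voxel_size (z, y, x) voxel size, um.
#' @return A `sim_nucleus` without mask or texture.
#' @export
nucleus_ellipsoid <- function(semiaxes, center = semiaxes,
                              voxel_size = c(0.170, 0.048, 0.048)) {
  structure(list(mask = NULL, dna = NULL, labels = NULL,
                 center = as.numeric(center), semiaxes = as.numeric(semiaxes),
                 voxel_size = as.numeric(voxel_size)),
            class = "sim_nucleus")
}

# Analytic ellipsoid stand-in when no textured nucleus is supplied.
analytic_nucleus <- function(config) {
  extent <- config$voxel_size * (config$image_shape - 1L)
  structure(list(mask = NULL, dna = NULL, labels = NULL,
                 center = extent / 2, semiaxes = 0.425 * extent,
                 voxel_size = config$voxel_size),
            class = "sim_nucleus")
}

inside_nucleus <- function(p, nucleus) {
  # p: 3 x n matrix of (z, y, x) um
  u <- (p - nucleus$center) / nucleus$semiaxes
  colSums(u^2) <= 1
}

place_foci <- function(nucleus, n, min_separation = 0) {
  if (n == 0L) return(matrix(0, 0L, 3L))
  lo <- nucleus$center - nucleus$semiaxes
  hi <- nucleus$center + nucleus$semiaxes
  out <- matrix(NA_real_, 3L, n)
  filled <- 0L
  for (it in 1:200) {
    need <- n - filled
    if (need <= 0L) break
    nb <- max(need * 10L, 50L)
    cand <- rbind(runif(nb, lo[1L], hi[1L]),
                  runif(nb, lo[2L], hi[2L]),
                  runif(nb, lo[3L], hi[3L]))
    ok <- inside_nucleus(cand, nucleus)
    if (!is.null(nucleus$mask)) {
      vi <- round(cand / nucleus$voxel_size) + 1L
      d <- dim(nucleus$mask)
      inb <- vi[1L, ] >= 1 & vi[1L, ] <= d[1L] & vi[2L, ] >= 1 & vi[2L, ] <= d[2L] &
        vi[3L, ] >= 1 & vi[3L, ] <= d[3L]
      okm <- inb
      okm[inb] <- nucleus$mask[cbind(vi[1L, inb], vi[2L, inb], vi[3L, inb])]
      ok <- ok & okm
    }
    cand <- cand[, ok, drop = FALSE]
    # greedy spacing against accepted foci and within the candidate batch
    for (j in seq_len(ncol(cand))) {
      if (filled >= n) break
      if (min_separation > 0 && filled > 0L) {
        dd <- sqrt(colSums((out[, seq_len(filled), drop = FALSE] - cand[, j])^2))
        if (min(dd) < min_separation) next
      }
      filled <- filled + 1L
      out[, filled] <- cand[, j]
    }
  }
  if (filled < n) abort("nucleus too small to place the requested number of foci")
  t(out)
}

# Specular reflection at the ellipsoid boundary: points outside are
# mirrored across the tangent plane at the radially-projected boundary
# point, so the correction is ~2x the penetration depth along the local
# surface normal (not a whole-vector rescale). Two passes handle curved
# corners; a final radial clamp catches pathological overshoots.
reflect_nucleus <- function(p, nucleus) {
  # p: 3 x n
  s <- nucleus$semiaxes; ctr <- nucleus$center
  for (pass in 1:2) {
    u <- (p - ctr) / s
    r <- sqrt(colSums(u^2))
    out <- which(r > 1)
    if (!length(out)) return(p)
    ub <- u[, out, drop = FALSE] / rep(r[out], each = 3L)
    pb <- ub * s + ctr
    nv <- ub / s
    nv <- nv / rep(sqrt(colSums(nv^2)), each = 3L)
    delta <- colSums((p[, out, drop = FALSE] - pb) * nv)
    p[, out] <- p[, out, drop = FALSE] - 2 * rep(delta, each = 3L) * nv
  }
  u <- (p - ctr) / s
  r <- sqrt(colSums(u^2))
  out <- which(r > 1)
  if (length(out)) {
    fac <- 0.999 / r[out]
    p[, out] <- u[, out, drop = FALSE] * rep(fac, each = 3L) * s + ctr
  }
  p
}

#' Extract standard tracks from simulation ground truth
#'
#' @param truth a `sim_truth` from [simulate_trajectories()].
#' @param positions `"observed"` (with localization noise) or `"true"`.
#' @return Tibble with columns track_id, frame, z_um, y_um, x_um.
#' @export
truth_tracks <- function(truth, positions = c("observed", "true")) {
  positions <- match.arg(positions)
  tr <- truth$tracks
  if (positions == "observed") {
    tibble(track_id = tr$focus_id, frame = tr$frame,
           z_um = tr$z_obs_um, y_um = tr$y_obs_um, x_um = tr$x_obs_um)
  } else {
    tibble(track_id = tr$focus_id, frame = tr$frame,
           z_um = tr$z_um, y_um = tr$y_um, x_um = tr$x_um)
  }
}
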