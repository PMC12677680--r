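# Spot-enhancing focus detection: scale-normalized negated Laplacian of
# Gaussian, automatic mean + k*sd thresholding over the whole sequence,
# strict local maxima with minimum separation, sub-voxel localization by
# intensity-weighted centroid, size by local second moments.

#' Detection parameters
#'
#' @param sigma (z, y, x) LoG scale in um; should roughly match the spot
#'   size (PSF sigma for diffraction-limited foci).
#' @param k_factor threshold multiplier: threshold = mean + k_factor * sd
#'   of the filter responses, pooled over the whole sequence.
#' @param min_separation minimum distance between accepted maxima, um.
#' @return A `detection_params` list.
#' @export
detection_params <- function(sigma = c(0.21, 0.085, 0.085), k_factor = 4,
                             min_separation = 0.25) {
  sigma <- as.numeric(sigma)
  if (any(sigma < 0) || all(sigma == 0)) abort("sigma must be positive")
  if (k_factor <= 0) abort("k_factor must be > 0")
  structure(list(sigma = sigma, k_factor = k_factor,
                 min_separation = min_separation),
            class = "detection_params")
}

#' Scale-normalized LoG filter response
#'
#' Gaussian smoothing at per-axis scale `sigma / voxel_size` followed by a
#' physical-unit Laplacian, negated and multiplied by the geometric-mean
#' squared scale so bright blobs give positive peaks whose height is
#' comparable across scales. A 2-D matrix is treated as a single-slice
#' volume (z axis skipped).
#'
#' @param volume 3-D (z, y, x) array or 2-D matrix.
#' @param voxel_size physical voxel size per axis, um (length 3, or 2 for
#'   a matrix input).
#' @param sigma LoG scale per axis, um (same length as `voxel_size`).
#' @return Response array, same shape as `volume`.
#' @export
log_filter <- function(volume, voxel_size, sigma) {
  pv <- promote_vol(volume)
  if (pv$was2d) {
    voxel_size <- c(1, voxel_size)
    sigma <- c(0, sigma)
  }
  vol <- pv$vol
  d <- dim(vol)
  if (any(sigma > 0 & sigma < voxel_size & d > 1L)) {
    warn("LoG scale below one voxel on some axis: undersampled scale")
  }
  sig_vox <- ifelse(d > 1L, sigma / voxel_size, 0)
  sm <- gauss_smooth(vol, sig_vox)
  active <- sigma > 0 & d > 1L
  norm <- prod(sigma[active])^(2 / sum(active))
  resp <- -norm * laplacian3(sm, voxel_size)
  if (pv$was2d) resp <- resp[1L, , ] else resp
  resp
}

#' Detect foci in a single volume with the spot-enhancing filter
#'
#' Local maxima of the LoG response above `threshold` (or the automatic
#' per-volume mean + k*sd when `threshold = NULL`), separated by at least
#' `min_separation`, localized to sub-voxel precision by intensity-weighted
#' centroid over a 3x3x3 (z-limited) neighbourhood of the response.
#'
#' @param volume 3-D array (z, y, x) or 2-D matrix.
#' @param voxel_size per-axis voxel size, um.
#' @param params a [detection_params()].
#' @param threshold optional fixed response threshold (used by
#'   [detect_movie()] to pool statistics over a sequence).
#' @param frame frame index stored in the output.
#' @return Tibble: frame, z_um, y_um, x_um, response, intensity, size_um.
#' @export
sef_detect <- function(volume, voxel_size, params = detection_params(),
                       threshold = NULL, frame = 1L) {
  pv <- promote_vol(volume)
  vs <- if (pv$was2d) c(1, voxel_size) else as.numeric(voxel_size)
  sg <- if (pv$was2d) c(0, params$sigma[(length(params$sigma) - 1):length(params$sigma)]) else params$sigma
  vol <- pv$vol
  resp <- log_filter(volume, voxel_size, if (pv$was2d) sg[2:3] else sg)
  resp <- promote_vol(resp)$vol
  empty <- tibble(frame = integer(), z_um = numeric(), y_um = numeric(),
                  x_um = numeric(), response = numeric(),
                  intensity = numeric(), size_um = numeric())
  if (sd(resp) == 0) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  tau <- threshold %||% (mean(resp) + params$k_factor * sd(resp))
  cand <- which(local_maxima3(resp) & resp > tau)
  if (!length(cand)) return(empty)
  d <- dim(vol)
  idx <- arrayInd(cand, d)
  ord <- order(resp[cand], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  rs <- resp[cand][ord]
  # greedy minimum-separation suppression in physical coordinates; when
  # the stack is thinner than the axial PSF support the z axis carries no
  # resolving power, so separation is measured laterally there
  pos_vox <- idx
  pos_um <- sweep(pos_vox - 1, 2L, vs, `*`)
  z_resolved <- (d[1L] - 1L) * vs[1L] >= 4 * sg[1L]
  keep <- rep(TRUE, nrow(idx))
  if (params$min_separation > 0 && nrow(idx) > 1L) {
    for (i in 2:nrow(idx)) {
      earlier <- which(keep[seq_len(i - 1L)])
      if (length(earlier)) {
        dif <- pos_um[earlier, , drop = FALSE] -
          matrix(pos_um[i, ], length(earlier), 3L, byrow = TRUE)
        if (!z_resolved) dif[, 1L] <- 0
        dd <- sqrt(rowSums(dif^2))
        if (any(dd < params$min_separation)) keep[i] <- FALSE
      }
    }
  }
  idx <- idx[keep, , drop = FALSE]
  rs <- rs[keep]

  out <- lapply(seq_len(nrow(idx)), function(i) {
    ctr <- refine_centroid(resp, idx[i, ], vs)
    sz <- moment_size(vol, idx[i, ], vs, sg)
    inten <- spot_intensity(vol, idx[i, ], vs, sg)
    tibble(frame = as.integer(frame), z_um = ctr[1L], y_um = ctr[2L],
           x_um = ctr[3L], response = rs[i], intensity = inten,
           size_um = sz)
  })
  dplyr::bind_rows(out)
}

# Sub-voxel refinement: per-axis parabolic interpolation of the LoG
# response through the peak and its two axis neighbours (offset clamped
# to half a voxel; border axes keep the integer position).
refine_centroid <- function(resp, vox, vs) {
  d <- dim(resp)
  out <- numeric(3L)
  for (a in 1:3) {
    i <- vox[a]
    if (i <= 1L || i >= d[a]) {
      out[a] <- (i - 1) * vs[a]
      next
    }
    g <- switch(a,
      resp[(i - 1L):(i + 1L), vox[2L], vox[3L]],
      resp[vox[1L], (i - 1L):(i + 1L), vox[3L]],
      resp[vox[1L], vox[2L], (i - 1L):(i + 1L)])
    den <- 2 * (2 * g[2L] - g[1L] - g[3L])
    off <- if (abs(den) > .Machine$double.eps) (g[3L] - g[1L]) / den else 0
    out[a] <- (i - 1 + max(min(off, 0.5), -0.5)) * vs[a]
  }
  out
}

# Local window around a peak: +-3 scale units per axis, clipped.
peak_window <- function(d, vox, vs, sg) {
  half <- pmax(ceiling(3 * pmax(sg, vs) / vs), 1L)
  lapply(1:3, function(a) max(1L, vox[a] - half[a]):min(d[a], vox[a] + half[a]))
}

# Background-subtracted summed intensity in the local window.
spot_intensity <- function(vol, vox, vs, sg) {
  rng <- peak_window(dim(vol), vox, vs, sg)
  w <- vol[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
  bg <- quantile(w, 0.1, names = FALSE)
  sum(pmax(w - bg, 0))
}

# Geometric-mean Gaussian sigma from local second moments after
# background subtraction; axes with a single sample are excluded.
moment_size <- function(vol, vox, vs, sg) {
  d <- dim(vol)
  rng <- peak_window(d, vox, vs, sg)
  w <- vol[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
  bg <- quantile(w, 0.1, names = FALSE)
  w <- pmax(w - bg, 0)
  tot <- sum(w)
  if (tot <= 0) return(min(vs[vs > 0]))
  coords <- list((rng[[1L]] - 1) * vs[1L], (rng[[2L]] - 1) * vs[2L],
                 (rng[[3L]] - 1) * vs[3L])
  sig <- numeric(0)
  for (a in 1:3) {
    if (length(rng[[a]]) < 3L) next
    wa <- apply(w, a, sum)
    mu <- sum(wa * coords[[a]]) / tot
    v <- sum(wa * (coords[[a]] - mu)^2) / tot
    if (v > 0) sig <- c(sig, sqrt(v))
  }
  if (!length(sig)) return(min(vs[vs > 0]))
  exp(mean(log(sig)))
}

#' Estimate the size of one detected focus
#'
#' Geometric-mean Gaussian sigma from background-subtracted local second
#' moments around the detection.
#'
#' @param volume 3-D array (z, y, x).
#' @param detection one-row tibble with z_um, y_um, x_um.
#' @param voxel_size per-axis voxel size, um.
#' @param sigma scale used to set the moment window, um.
#' @return Size in um (geometric-mean sigma).
#' @export
estimate_focus_size <- function(volume, detection, voxel_size,
                                sigma = c(0.21, 0.085, 0.085)) {
  vox <- round(c(detection$z_um, detection$y_um, detection$x_um) / voxel_size) + 1L
  d <- dim(volume)
  if (any(vox < 1L) || any(vox > d)) abort("detection outside volume bounds")
  moment_size(volume, vox, voxel_size, sigma)
}

#' Detect foci across a whole movie with a pooled threshold
#'
#' The automatic threshold (mean + k*sd of LoG responses) is computed over
#' the responses of every frame of the sequence, then applied per frame,
#' keeping counts comparable across time.
#'
#' @param movie a [movie5d()].
#' @param channel 1-based channel index to detect on.
#' @param params a [detection_params()].
#' @return Tibble of detections for all frames.
#' @export
detect_movie <- function(movie, channel = 2L, params = detection_params()) {
  nf <- dim(movie$data)[1L]
  vs <- movie$voxel_size
  resp_stats_n <- 0; resp_sum <- 0; resp_sum2 <- 0
  for (t in seq_len(nf)) {
    r <- log_filter(movie_volume(movie, t, channel), vs, params$sigma)
    resp_sum <- resp_sum + sum(r)
    resp_sum2 <- resp_sum2 + sum(r^2)
    resp_stats_n <- resp_stats_n + length(r)
  }
  mu <- resp_sum / resp_stats_n
  sdv <- sqrt(max(resp_sum2 / resp_stats_n - mu^2, 0))
  if (sdv == 0) {
    out <- tibble(frame = integer(), z_um = numeric(), y_um = numeric(),
                  x_um = numeric(), response = numeric(),
                  intensity = numeric(), size_um = numeric())
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tau <- mu + params$k_factor * sdv
  dplyr::bind_rows(lapply(seq_len(nf), function(t) {
    sef_detect(movie_volume(movie, t, channel), vs, params,
               threshold = tau, frame = t)
  }))
}
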