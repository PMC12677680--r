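# Drift correction: every frame of the DNA channel is registered onto
# frame 1. Affine stage: integer-shift initialization by FFT
# cross-correlation, then multi-resolution Nelder-Mead refinement of a
# rigid (or translation-only) parameterization maximizing normalized
# cross-correlation. Optional non-rigid stage: diffusion-regularized
# demons refinement with Gaussian smoothing of the update field.

#' Registration parameters
#'
#' @param dof `"translation"` or `"rigid"` (translation + rotation) for
#'   the affine stage.
#' @param levels lateral downsampling factors of the resolution pyramid,
#'   coarse to fine.
#' @param nonrigid run the dense demons refinement after the affine stage?
#' @param sigma_reg Gaussian regularization of the demons update field,
#'   voxels.
#' @param demons_iter demons iterations per call.
#' @param maxit Nelder-Mead iterations per pyramid level.
#' @return A `registration_params` list.
#' @export
registration_params <- function(dof = c("rigid", "translation"),
                                levels = c(4L, 2L, 1L),
                                nonrigid = FALSE, sigma_reg = 2,
                                demons_iter = 40L, maxit = 60L) {
  dof <- match.arg(dof)
  structure(list(dof = dof, levels = as.integer(levels), nonrigid = nonrigid,
                 sigma_reg = sigma_reg, demons_iter = as.integer(demons_iter),
                 maxit = as.integer(maxit)),
            class = "registration_params")
}

ncc <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# Integer-voxel shift estimate by FFT cross-correlation (circular).
cc_shift <- function(fixed, moving) {
  d <- dim(fixed)
  Ff <- fft(fixed - mean(fixed))
  Fm <- fft(moving - mean(moving))
  cc <- Re(fft(Fm * Conj(Ff), inverse = TRUE))
  peak <- arrayInd(which.max(cc), d)
  sh <- peak - 1L
  # wrap negative shifts
  ifelse(sh > d / 2, sh - d, sh)
}

# Downsample laterally by factor f (z kept when thin), after smoothing.
downsample_vol <- function(vol, f) {
  if (f <= 1L) return(vol)
  d <- dim(vol)
  fz <- if (d[1L] >= 4L * f) f else 1L
  sm <- gauss_smooth(vol, c(if (fz > 1L) fz / 2 else 0, f / 2, f / 2))
  sm[seq(1L, d[1L], by = fz), seq(1L, d[2L], by = f), seq(1L, d[3L], by = f),
     drop = FALSE]
}

rigid_from_theta <- function(theta, center, dof) {
  b <- theta[1:3]
  A <- diag(3)
  if (dof == "rigid" && length(theta) >= 6L) {
    ang <- theta[4:6]
    Rz <- diag(3); Rz[2:3, 2:3] <- matrix(c(cos(ang[1L]), sin(ang[1L]),
                                            -sin(ang[1L]), cos(ang[1L])), 2L)
    Ry <- diag(3); Ry[c(1L, 3L), c(1L, 3L)] <- matrix(c(cos(ang[2L]), sin(ang[2L]),
                                                        -sin(ang[2L]), cos(ang[2L])), 2L)
    Rx <- diag(3); Rx[1:2, 1:2] <- matrix(c(cos(ang[3L]), sin(ang[3L]),
                                            -sin(ang[3L]), cos(ang[3L])), 2L)
    A <- Rz %*% Ry %*% Rx
  }
  list(A = A, b = as.numeric(center - A %*% center) + b)
}

warp_ncc <- function(theta, fixed, moving, vs, grid, center, dof) {
  rt <- rigid_from_theta(theta, center, dof)
  Q <- grid %*% t(rt$A) + matrix(rt$b, nrow(grid), 3L, byrow = TRUE)
  w <- interp3(moving, Q[, 1L] / vs[1L] + 1, Q[, 2L] / vs[2L] + 1,
               Q[, 3L] / vs[3L] + 1)
  -ncc(as.vector(fixed), w)
}

#' Register one volume onto a fixed reference
#'
#' Estimates the transform m mapping reference coordinates to moving
#' coordinates such that resampling the moving volume through m matches
#' the fixed volume (normalized cross-correlation metric). The affine
#' stage never decreases NCC relative to identity; the optional demons
#' stage adds a Gaussian-regularized dense displacement.
#'
#' @param fixed,moving 3-D (z, y, x) volumes of identical shape.
#' @param voxel_size (z, y, x) voxel size, um.
#' @param params a [registration_params()].
#' @param init optional [transform3d()] warm start (e.g. the previous
#'   frame's transform).
#' @return A [transform3d()] with attributes `ncc_before` / `ncc_after`;
#'   `converged = FALSE` flags a failed improvement.
#' @export
register_frame <- function(fixed, moving, voxel_size,
                           params = registration_params(), init = NULL) {
  if (!all(dim(fixed) == dim(moving))) abort("fixed and moving must share shape")
  if (sd(fixed) == 0 || sd(moving) == 0) abort("constant image: registration is degenerate")
  vs <- as.numeric(voxel_size)
  d <- dim(fixed)
  center <- (d - 1L) * vs / 2
  ncc0 <- ncc(as.vector(fixed), as.vector(moving))

  theta <- if (params$dof == "rigid") numeric(6L) else numeric(3L)
  if (!is.null(init)) {
    theta[1:3] <- init$b + as.numeric(init$A %*% center) - center
    # rotation warm start omitted: angles are small and re-estimated
  } else {
    sh <- cc_shift(fixed, moving)
    theta[1:3] <- sh * vs
  }

  for (f in params$levels) {
    fx <- downsample_vol(fixed, f)
    mv <- downsample_vol(moving, f)
    dl <- dim(fx)
    vsl <- c(vs[1L] * d[1L] / dl[1L], vs[2L] * (d[2L] / dl[2L]), vs[3L] * (d[3L] / dl[3L]))
    grid <- grid_coords(dl, vsl)
    opt <- optim(theta, warp_ncc, fixed = fx, moving = mv, vs = vsl,
                 grid = grid, center = center, dof = params$dof,
                 method = "Nelder-Mead",
                 control = list(maxit = params$maxit,
                                parscale = c(rep(max(vsl[2L]), 3L),
                                             rep(0.01, length(theta) - 3L))))
    theta <- opt$par
  }
  rt <- rigid_from_theta(theta, center, params$dof)
  tr <- transform3d(A = rt$A, b = rt$b, voxel_size = vs)

  warped <- apply_transform(moving, tr, vs)
  ncc1 <- ncc(as.vector(fixed), as.vector(warped))
  if (ncc1 < ncc0) {
    # never degrade: fall back to identity
    tr <- transform3d(voxel_size = vs, converged = FALSE)
    warped <- moving
    ncc1 <- ncc0
  }

  if (params$nonrigid) {
    tr <- demons_refine(fixed, moving, tr, vs, params)
    warped <- apply_transform(moving, tr, vs)
    ncc2 <- ncc(as.vector(fixed), as.vector(warped))
    if (ncc2 < ncc1) {
      tr$disp <- NULL
      tr$converged <- FALSE
    } else ncc1 <- ncc2
  }
  attr(tr, "ncc_before") <- ncc0
  attr(tr, "ncc_after") <- ncc1
  tr
}

# Thirion demons on top of the affine part; multi-resolution, with the
# displacement accumulated on the reference grid in physical um.
demons_refine <- function(fixed, moving, tr, vs, params) {
  d <- dim(fixed)
  Abase <- tr$A; bbase <- tr$b
  u <- NULL; u_vs <- NULL
  for (f in sort(unique(pmax(params$levels, 1L)), decreasing = TRUE)) {
    fx <- downsample_vol(fixed, f)
    mv <- downsample_vol(moving, f)
    dl <- dim(fx)
    vsl <- c(vs[1L] * d[1L] / dl[1L], vs[2L] * (d[2L] / dl[2L]),
             vs[3L] * (d[3L] / dl[3L]))
    if (is.null(u)) {
      u <- list(dz = array(0, dl), dy = array(0, dl), dx = array(0, dl))
    } else {
      # upsample the accumulated field onto this level's grid
      g <- grid_coords(dl, vsl)
      zi <- g[, 1L] / u_vs[1L] + 1; yi <- g[, 2L] / u_vs[2L] + 1; xi <- g[, 3L] / u_vs[3L] + 1
      u <- list(dz = array(interp3(u$dz, zi, yi, xi), dl),
                dy = array(interp3(u$dy, zi, yi, xi), dl),
                dx = array(interp3(u$dx, zi, yi, xi), dl))
    }
    u_vs <- vsl
    u <- demons_level(fx, mv, Abase, bbase, u, vsl, params)
  }
  transform3d(A = Abase, b = bbase, disp = u, voxel_size = u_vs,
              converged = tr$converged)
}

demons_level <- function(fixed, moving, Abase, bbase, u, vs, params) {
  d <- dim(fixed)
  grid <- grid_coords(d, vs)
  scale_int <- sd(fixed)
  max_step <- 0.8 * min(vs[2:3])
  smooth_sig <- rep(params$sigma_reg, 3L) * c(if (d[1L] > 4L) 1 else 0, 1, 1)
  vox2 <- mean(vs[2:3])^2
  for (it in seq_len(params$demons_iter)) {
    Q <- grid %*% t(Abase) + matrix(bbase, nrow(grid), 3L, byrow = TRUE) +
      cbind(as.vector(u$dz), as.vector(u$dy), as.vector(u$dx))
    w <- interp3(moving, Q[, 1L] / vs[1L] + 1, Q[, 2L] / vs[2L] + 1,
                 Q[, 3L] / vs[3L] + 1)
    dim(w) <- d
    diffim <- fixed - w
    gz <- axis_gradient(w, 1L, vs[1L])
    gy <- axis_gradient(w, 2L, vs[2L])
    gx <- axis_gradient(w, 3L, vs[3L])
    g2 <- gz^2 + gy^2 + gx^2
    denom <- g2 + diffim^2 / vox2 + 1e-9 * max(g2, scale_int^2 / vox2)
    fac <- diffim / pmax(denom, 1e-12)
    dz <- fac * gz; dy <- fac * gy; dx <- fac * gx
    nrm <- sqrt(dz^2 + dy^2 + dx^2)
    cap <- pmin(nrm, max_step) / pmax(nrm, 1e-12)
    # fluid-like smoothing of the update, light diffusion smoothing of the
    # accumulated field (heavy smoothing of the total would erode it)
    diff_sig <- smooth_sig * 0.35
    u$dz <- gauss_smooth(u$dz + gauss_smooth(dz * cap, smooth_sig), diff_sig)
    u$dy <- gauss_smooth(u$dy + gauss_smooth(dy * cap, smooth_sig), diff_sig)
    u$dx <- gauss_smooth(u$dx + gauss_smooth(dx * cap, smooth_sig), diff_sig)
  }
  u
}

#' Register every frame of a movie onto frame 1
#'
#' Registration runs on the reference channel (DNA); the transforms are
#' then applied to detections from any channel. Frame 1 gets the identity
#' transform by construction; each subsequent frame is warm-started from
#' its predecessor.
#'
#' @param movie a [movie5d()].
#' @param reference_channel 1-based channel used for registration.
#' @param params a [registration_params()].
#' @return A `transform_series`: list of [transform3d()] (one per frame)
#'   with a `similarity` tibble (frame, ncc_before, ncc_after).
#' @export
register_sequence <- function(movie, reference_channel = 1L,
                              params = registration_params()) {
  nf <- dim(movie$data)[1L]
  if (reference_channel < 1L || reference_channel > dim(movie$data)[2L]) {
    abort("reference channel does not exist")
  }
  vs <- movie$voxel_size
  fixed <- movie_volume(movie, 1L, reference_channel)
  transforms <- vector("list", nf)
  transforms[[1L]] <- transform3d(voxel_size = vs)
  sim <- tibble(frame = seq_len(nf), ncc_before = NA_real_, ncc_after = NA_real_)
  sim$ncc_before[1L] <- sim$ncc_after[1L] <- 1
  prev <- NULL
  for (t in seq_len(nf)[-1L]) {
    tr <- tryCatch(
      register_frame(fixed, movie_volume(movie, t, reference_channel), vs,
                     params, init = prev),
      error = function(e) abort(sprintf("registration failed at frame %d: %s",
                                        t, conditionMessage(e))))
    transforms[[t]] <- tr
    sim$ncc_before[t] <- attr(tr, "ncc_before")
    sim$ncc_after[t] <- attr(tr, "ncc_after")
    prev <- if (is.null(tr$disp)) tr else transform3d(tr$A, tr$b, voxel_size = vs)
  }
  structure(list(transforms = transforms, similarity = sim, voxel_size = vs),
            class = "transform_series")
}

#' @export
print.transform_series <- function(x, ...) {
  cat(sprintf("<transform_series> %d frames; mean NCC %0.3f -> %0.3f\n",
              length(x$transforms),
              mean(x$similarity$ncc_before, na.rm = TRUE),
              mean(x$similarity$ncc_after, na.rm = TRUE)))
  invisible(x)
}

#' Map detections into registered (frame-1) coordinates
#'
#' @param detections tibble with frame, z_um, y_um, x_um.
#' @param series a [register_sequence()] result.
#' @return The detections tibble with positions replaced by registered
#'   coordinates.
#' @export
register_detections <- function(detections, series) {
  out <- detections
  for (t in unique(detections$frame)) {
    sel <- detections$frame == t
    tr <- series$transforms[[t]]
    if (is_identity_transform(tr)) next
    P <- as.matrix(detections[sel, c("z_um", "y_um", "x_um")])
    M <- t3d_inverse(tr, P)
    out$z_um[sel] <- M[, 1L]; out$y_um[sel] <- M[, 2L]; out$x_um[sel] <- M[, 3L]
  }
  out
}
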