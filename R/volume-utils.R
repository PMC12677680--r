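# Internal 3-D array primitives: separable Gaussian smoothing via FFT,
# finite-difference Laplacian/gradient in physical units, trilinear
# interpolation, local-maximum detection, connected components.
# Volumes are dim = c(nz, ny, nx); 2-D images are promoted to nz = 1.

# Promote a 2-D matrix to a singleton-z volume; returns list(vol, was2d)
promote_vol <- function(vol) {
  if (length(dim(vol)) == 2L) {
    list(vol = array(vol, dim = c(1L, dim(vol))), was2d = TRUE)
  } else if (length(dim(vol)) == 3L) {
    list(vol = vol, was2d = FALSE)
  } else {
    abort("volume must be a 2-D matrix or 3-D array")
  }
}

# Circular 1-D Gaussian kernel of length n centred at index 1, sigma in voxels
gauss_kernel_1d <- function(n, sigma) {
  if (sigma <= 0 || n == 1L) {
    k <- numeric(n); k[1L] <- 1
    return(k)
  }
  d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-d^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing by FFT (circular boundary).
# sigma_vox: per-axis sigma in voxel units, (z, y, x).
gauss_smooth <- function(vol, sigma_vox) {
  d <- dim(vol)
  if (all(sigma_vox <= 0)) return(vol)
  tk <- lapply(seq_along(d), function(a) Re(fft(gauss_kernel_1d(d[a], sigma_vox[a]))))
  transfer <- outer(outer(tk[[1L]], tk[[2L]]), tk[[3L]])
  dim(transfer) <- d
  out <- Re(fft(fft(vol) * transfer, inverse = TRUE)) / prod(d)
  out
}

# Central-difference gradient along one axis, physical spacing h (um).
# Edges use one-sided differences.
axis_gradient <- function(vol, axis, h) {
  d <- dim(vol)
  n <- d[axis]
  g <- array(0, d)
  if (n == 1L) return(g)
  idx <- function(i) switch(axis,
    vol[i, , , drop = FALSE],
    vol[, i, , drop = FALSE],
    vol[, , i, drop = FALSE])
  put <- function(g, i, val) {
    switch(axis,
      g[i, , ] <- val,
      g[, i, ] <- val,
      g[, , i] <- val)
    g
  }
  ctr <- (idx(3:n) - idx(1:(n - 2))) / (2 * h)
  g <- put(g, 2:(n - 1), ctr)
  g <- put(g, 1L, (idx(2L) - idx(1L)) / h)
  g <- put(g, n, (idx(n) - idx(n - 1L)) / h)
  g
}

# Laplacian in physical units; axes of size 1 are skipped.
laplacian3 <- function(vol, voxel_size) {
  d <- dim(vol)
  out <- array(0, d)
  for (a in 1:3) {
    n <- d[a]
    if (n < 3L) next
    h2 <- voxel_size[a]^2
    sl <- function(i) switch(a,
      vol[i, , , drop = FALSE],
      vol[, i, , drop = FALSE],
      vol[, , i, drop = FALSE])
    second <- (sl(3:n) - 2 * sl(2:(n - 1)) + sl(1:(n - 2))) / h2
    switch(a,
      out[2:(n - 1), , ] <- out[2:(n - 1), , , drop = FALSE] + second,
      out[, 2:(n - 1), ] <- out[, 2:(n - 1), , drop = FALSE] + second,
      out[, , 2:(n - 1)] <- out[, , 2:(n - 1), drop = FALSE] + second)
  }
  out
}

# Trilinear interpolation at continuous 1-based voxel coordinates
# (zi, yi, xi), edge-clamped.  All three must be equal-length vectors.
interp3 <- function(vol, zi, yi, xi) {
  d <- dim(vol)
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  zi <- pmin(pmax(zi, 1), nz)
  yi <- pmin(pmax(yi, 1), ny)
  xi <- pmin(pmax(xi, 1), nx)
  z0 <- pmin(floor(zi), max(nz - 1L, 1L)); fz <- zi - z0
  y0 <- pmin(floor(yi), max(ny - 1L, 1L)); fy <- yi - y0
  x0 <- pmin(floor(xi), max(nx - 1L, 1L)); fx <- xi - x0
  z1 <- pmin(z0 + 1L, nz); y1 <- pmin(y0 + 1L, ny); x1 <- pmin(x0 + 1L, nx)
  lin <- function(z, y, x) vol[z + (y - 1) * nz + (x - 1) * nz * ny]
  c000 <- lin(z0, y0, x0); c100 <- lin(z1, y0, x0)
  c010 <- lin(z0, y1, x0); c110 <- lin(z1, y1, x0)
  c001 <- lin(z0, y0, x1); c101 <- lin(z1, y0, x1)
  c011 <- lin(z0, y1, x1); c111 <- lin(z1, y1, x1)
  c00 <- c000 * (1 - fz) + c100 * fz
  c10 <- c010 * (1 - fz) + c110 * fz
  c01 <- c001 * (1 - fz) + c101 * fz
  c11 <- c011 * (1 - fz) + c111 * fz
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fx) + c1 * fx
}

# Logical volume of strict 26-neighbourhood local maxima.
local_maxima3 <- function(vol) {
  d <- dim(vol)
  ismax <- array(TRUE, d)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  for (r in seq_len(nrow(offs))) {
    o <- c(offs$dz[r], offs$dy[r], offs$dx[r])
    if (any(abs(o) >= d)) next
    sh <- array(-Inf, d)
    src <- dst <- vector("list", 3L)
    for (a in 1:3) {
      n <- d[a]
      if (o[a] >= 0) { src[[a]] <- seq_len(n - o[a]); dst[[a]] <- seq_len(n - o[a]) + o[a] }
      else { src[[a]] <- seq_len(n + o[a]) - o[a]; dst[[a]] <- seq_len(n + o[a]) }
    }
    sh[dst[[1L]], dst[[2L]], dst[[3L]]] <- vol[src[[1L]], src[[2L]], src[[3L]]]
    ismax <- ismax & (vol > sh | (vol == sh & (r > 13L)))
  }
  ismax
}

# Shift a logical volume by one voxel along axis/dir, padding FALSE.
shift1 <- function(mask, axis, dir) {
  d <- dim(mask)
  out <- array(FALSE, d)
  n <- d[axis]
  if (n == 1L) return(out)
  s <- seq_len(n - 1L)
  if (axis == 1L) { if (dir > 0) out[s + 1L, , ] <- mask[s, , ] else out[s, , ] <- mask[s + 1L, , ] }
  if (axis == 2L) { if (dir > 0) out[, s + 1L, ] <- mask[, s, ] else out[, s, ] <- mask[, s + 1L, ] }
  if (axis == 3L) { if (dir > 0) out[, , s + 1L] <- mask[, , s] else out[, , s] <- mask[, , s + 1L] }
  out
}

# 6-connected component containing the seed voxel (linear index), by
# iterative frontier dilation; returns logical volume.
flood_component <- function(mask, seed) {
  comp <- array(FALSE, dim(mask))
  comp[seed] <- TRUE
  repeat {
    grown <- comp
    for (a in 1:3) {
      grown <- grown | shift1(comp, a, 1L) | shift1(comp, a, -1L)
    }
    grown <- grown & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# Largest 6-connected foreground component.
largest_component <- function(mask) {
  remaining <- mask
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1L]
    comp <- flood_component(remaining, seed)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
    if (sum(remaining) < best_n) break
  }
  best
}

# Otsu threshold on raw intensities (EBImage::otsu expects [0,1]).
otsu_threshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1L])
  scaled <- (x - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(matrix(scaled, nrow = 1L), range = c(0, 1))
  rng[1L] + thr * diff(rng)
}
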