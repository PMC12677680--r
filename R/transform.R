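#' Rigid/affine + dense-displacement 3-D transform
#'
#' A `transform3d` stores the map `m(x) = A x + b + d(x)` from reference
#' (frame-0) physical coordinates to the coordinates of the same material
#' point in the moving frame; `d` is an optional dense displacement field
#' sampled on the reference voxel grid. Applying the transform to a volume
#' resamples the moving frame onto the reference grid (pull-back, linear
#' interpolation); applying it to points maps moving-frame detections into
#' reference coordinates via the inverse map (no image interpolation).
#'
#' @param A 3x3 linear part (z, y, x order).
#' @param b length-3 translation, um.
#' @param disp optional displacement field: list of three (z, y, x) arrays
#'   `dz`, `dy`, `dx` in um on the reference grid.
#' @param voxel_size (z, y, x) voxel size of the grid `disp` lives on.
#' @param converged logical flag set by the estimator.
#' @return A `transform3d` object.
#' @export
transform3d <- function(A = diag(3), b = c(0, 0, 0), disp = NULL,
                        voxel_size = NULL, converged = TRUE) {
  A <- matrix(as.numeric(A), 3L, 3L)
  if (abs(det(A)) < 1e-12) abort("affine linear part must be invertible")
  if (!is.null(disp)) {
    stopifnot(is.list(disp), all(c("dz", "dy", "dx") %in% names(disp)))
    if (!all(vapply(disp, function(u) all(is.finite(u)), logical(1L)))) {
      abort("displacement field must be finite everywhere")
    }
  }
  structure(list(A = A, b = as.numeric(b), disp = disp,
                 voxel_size = voxel_size, converged = converged),
            class = "transform3d")
}

#' @export
print.transform3d <- function(x, ...) {
  cat("<transform3d> translation (z,y,x) um:", signif(x$b, 4), "\n")
  cat("  |A - I|_max:", signif(max(abs(x$A - diag(3))), 3),
      if (!is.null(x$disp)) sprintf("; dense field, max |d| = %.4g um",
                                    max(abs(c(x$disp$dz, x$disp$dy, x$disp$dx))))
      else "; no dense field", "\n")
  invisible(x)
}

is_identity_transform <- function(t, tol = 1e-9) {
  max(abs(t$A - diag(3))) < tol && max(abs(t$b)) < tol &&
    (is.null(t$disp) || max(abs(c(t$disp$dz, t$disp$dy, t$disp$dx))) < tol)
}

# Sample the displacement field at physical points P (n x 3, z,y,x um).
disp_at <- function(t, P) {
  if (is.null(t$disp)) return(matrix(0, nrow(P), 3L))
  vs <- t$voxel_size
  zi <- P[, 1L] / vs[1L] + 1; yi <- P[, 2L] / vs[2L] + 1; xi <- P[, 3L] / vs[3L] + 1
  cbind(interp3(t$disp$dz, zi, yi, xi),
        interp3(t$disp$dy, zi, yi, xi),
        interp3(t$disp$dx, zi, yi, xi))
}

# Forward map m(x): reference coords -> moving coords. P is n x 3.
t3d_forward <- function(t, P) {
  P %*% t(t$A) + matrix(t$b, nrow(P), 3L, byrow = TRUE) + disp_at(t, P)
}

# Inverse map m^-1(q): moving coords -> reference coords, by fixed-point
# iteration on the (small, smooth) displacement part.
t3d_inverse <- function(t, Q, iter = 4L) {
  Ainv <- solve(t$A)
  bmat <- matrix(t$b, nrow(Q), 3L, byrow = TRUE)
  X <- (Q - bmat) %*% t(Ainv)
  if (is.null(t$disp)) return(X)
  for (i in seq_len(iter)) {
    X <- (Q - bmat - disp_at(t, X)) %*% t(Ainv)
  }
  X
}

# Algebraic inverse of an affine-only transform3d.
invert_affine_transform <- function(t) {
  if (!is.null(t$disp)) abort("only affine transforms can be inverted exactly")
  Ainv <- solve(t$A)
  transform3d(A = Ainv, b = as.numeric(-Ainv %*% t$b), voxel_size = t$voxel_size)
}

#' Apply a transform to a volume or to a point set
#'
#' Volumes are resampled onto the reference grid with linear interpolation;
#' point sets (a tibble/data frame with `z_um`, `y_um`, `x_um`, or an
#' `n x 3` matrix) are mapped exactly from moving-frame to reference-frame
#' coordinates.
#'
#' @param x a 3-D array, matrix of points (n x 3, z/y/x um), or data frame
#'   with columns `z_um`, `y_um`, `x_um`.
#' @param transform a [transform3d()].
#' @param voxel_size (z, y, x) voxel size of the volume, um (volumes only).
#' @return The warped volume or the mapped points (same container as input).
#' @export
apply_transform <- function(x, transform, voxel_size = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    vs <- voxel_size %||% transform$voxel_size
    if (is.null(vs)) abort("voxel_size required to warp a volume")
    d <- dim(x)
    grid <- grid_coords(d, vs)
    Q <- t3d_forward(transform, grid)
    out <- interp3(x, Q[, 1L] / vs[1L] + 1, Q[, 2L] / vs[2L] + 1, Q[, 3L] / vs[3L] + 1)
    dim(out) <- d
    return(out)
  }
  if (is.matrix(x)) {
    return(t3d_inverse(transform, x))
  }
  if (is.data.frame(x)) {
    P <- as.matrix(x[, c("z_um", "y_um", "x_um")])
    M <- t3d_inverse(transform, P)
    x$z_um <- M[, 1L]; x$y_um <- M[, 2L]; x$x_um <- M[, 3L]
    return(x)
  }
  abort("`x` must be a 3-D array, an n x 3 matrix, or a data frame with z_um/y_um/x_um")
}

# Physical coordinates (n_vox x 3) of all voxel centres, z fastest.
grid_coords <- function(d, vs) {
  z <- (seq_len(d[1L]) - 1L) * vs[1L]
  y <- (seq_len(d[2L]) - 1L) * vs[2L]
  x <- (seq_len(d[3L]) - 1L) * vs[3L]
  cbind(rep(z, times = d[2L] * d[3L]),
        rep(rep(y, each = d[1L]), times = d[3L]),
        rep(x, each = d[1L] * d[2L]))
}
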