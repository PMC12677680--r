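# Resolution-gain analysis between two imaging modalities (e.g. confocal
# vs STED) of the same cell: detect foci in both, match them one-to-one
# (Hungarian method), extract 1 um horizontal intensity profiles at each
# detection, average, min-max normalize, and compute the FWHM.

#' Match two detection sets one-to-one
#'
#' Minimum-total-distance assignment (Hungarian method) between the two
#' sets, using whichever of z_um/y_um/x_um both share; pairs farther than
#' `max_dist` are discarded after solving.
#'
#' @param set_a,set_b detection tibbles.
#' @param max_dist gating distance, um (default one confocal FWHM).
#' @return Tibble: index_a, index_b, dist_um.
#' @export
match_detections <- function(set_a, set_b, max_dist = 0.3) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) abort("both detection sets must be non-empty")
  cols <- intersect(intersect(c("z_um", "y_um", "x_um"), names(set_a)), names(set_b))
  A <- as.matrix(set_a[, cols]); B <- as.matrix(set_b[, cols])
  D <- sqrt(outer(rowSums(A^2), rep(1, nrow(B))) +
              outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B))
  D[!is.finite(D) | D < 0] <- 0
  asg <- solve_assignment(D)
  keep <- which(!is.na(asg))
  dist <- D[cbind(keep, asg[keep])]
  ok <- dist <= max_dist
  tibble(index_a = keep[ok], index_b = asg[keep][ok], dist_um = dist[ok])
}

#' Extract horizontal intensity profiles at detections
#'
#' For each detection, samples the image by linear interpolation along a
#' horizontal (x) line of length `length_um` centred at the detection's
#' subpixel position. Detections closer than `length_um / 2` to the
#' lateral border are skipped (count reported in `attr(, "skipped")`).
#'
#' @param image 2-D (y, x) matrix.
#' @param detections tibble with y_um, x_um.
#' @param pixel pixel size, um.
#' @param length_um profile length, um.
#' @return A `profile_set`: matrix (n_foci x n_samples) with attributes
#'   `pixel`, `offsets_um`, `skipped`.
#' @export
extract_profiles <- function(image, detections, pixel, length_um = 1) {
  ny <- nrow(image); nx <- ncol(image)
  ns <- round(length_um / pixel) + 1L
  offs <- seq(-length_um / 2, length_um / 2, length.out = ns)
  vol <- array(image, dim = c(1L, ny, nx))
  keep <- logical(nrow(detections))
  rows <- vector("list", nrow(detections))
  for (i in seq_len(nrow(detections))) {
    yc <- detections$y_um[i]; xc <- detections$x_um[i]
    xs <- xc + offs
    xi <- xs / pixel + 1
    yi <- yc / pixel + 1
    if (min(xi) < 1 || max(xi) > nx || yi < 1 || yi > ny) next
    keep[i] <- TRUE
    rows[[i]] <- interp3(vol, rep(1, ns), rep(yi, ns), xi)
  }
  if (!any(keep)) {
    out <- matrix(numeric(0), 0L, ns)
  } else {
    out <- do.call(rbind, rows[keep])
  }
  attr(out, "pixel") <- pixel
  attr(out, "offsets_um") <- offs
  attr(out, "skipped") <- sum(!keep)
  class(out) <- c("profile_set", class(out))
  out
}

#' Average profiles and normalize to [0, 1]
#'
#' Pointwise mean across all profiles, then min-max normalization.
#'
#' @param pset a [extract_profiles()] result (or numeric matrix).
#' @return Numeric vector in [0, 1] with the `offsets_um` attribute.
#' @export
average_and_normalize <- function(pset) {
  if (nrow(pset) < 1L) abort("no profiles to average")
  avg <- colMeans(unclass(pset))
  rng <- range(avg)
  if (diff(rng) <= 0) abort("constant averaged profile: normalization degenerate")
  out <- (avg - rng[1L]) / diff(rng)
  attr(out, "offsets_um") <- attr(pset, "offsets_um")
  attr(out, "pixel") <- attr(pset, "pixel")
  out
}

#' Full width at half maximum of a profile
#'
#' Normalizes the profile (affine-invariantly) to [0, 1], locates the
#' global maximum, and finds the two half-maximum crossings by linear
#' interpolation between samples.
#'
#' @param profile numeric vector.
#' @param pixel sample spacing, um.
#' @return An `fwhm_result`: list(fwhm, normalized_profile).
#' @export
compute_fwhm <- function(profile, pixel) {
  p <- as.numeric(profile)
  rng <- range(p)
  if (diff(rng) <= 0) abort("flat profile has no width")
  p <- (p - rng[1L]) / diff(rng)
  imax <- which.max(p)
  n <- length(p)
  left <- NA_real_
  if (imax > 1L) {
    for (i in (imax - 1L):1L) {
      if (p[i] <= 0.5) {
        left <- i + (0.5 - p[i]) / (p[i + 1L] - p[i])
        break
      }
    }
  }
  right <- NA_real_
  if (imax < n) {
    for (i in (imax + 1L):n) {
      if (p[i] <= 0.5) {
        right <- i - (0.5 - p[i]) / (p[i - 1L] - p[i])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) {
    abort("no half-maximum crossing on one side (peak at border)")
  }
  structure(list(fwhm = (right - left) * pixel, normalized_profile = p),
            class = "fwhm_result")
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf("<fwhm_result> FWHM = %.4f um\n", x$fwhm))
  invisible(x)
}

#' End-to-end resolution-gain analysis of an image pair
#'
#' Detects foci in both images with the spot-enhancing filter, matches
#' them with the Hungarian method, extracts 1 um horizontal profiles at
#' the matched detections, averages and normalizes per modality, and
#' computes both FWHMs.
#'
#' @param image_a,image_b 2-D (y, x) matrices of the same scene.
#' @param pixel pixel size, um.
#' @param sigma_a,sigma_b lateral LoG detection scale per image, um.
#' @param k_factor detection threshold factor.
#' @param max_dist match gating distance, um.
#' @param length_um profile length, um.
#' @return Tibble: modality (a/b), fwhm_um, n_matched, n_profiles; the
#'   normalized profiles in `attr(, "profiles")`.
#' @export
resolution_gain <- function(image_a, image_b, pixel,
                            sigma_a = 0.12, sigma_b = 0.06,
                            k_factor = 3, max_dist = 0.3, length_um = 1) {
  par_a <- detection_params(sigma = rep(sigma_a, 2L), k_factor = k_factor,
                            min_separation = 2 * sigma_a)
  par_b <- detection_params(sigma = rep(sigma_b, 2L), k_factor = k_factor,
                            min_separation = 2 * sigma_b)
  det_a <- sef_detect(image_a, rep(pixel, 2L), par_a)
  det_b <- sef_detect(image_b, rep(pixel, 2L), par_b)
  if (nrow(det_a) == 0L || nrow(det_b) == 0L) abort("no detections in one of the images")
  mm <- match_detections(det_a, det_b, max_dist = max_dist)
  pa <- extract_profiles(image_a, det_a[mm$index_a, , drop = FALSE], pixel, length_um)
  pb <- extract_profiles(image_b, det_b[mm$index_b, , drop = FALSE], pixel, length_um)
  na_ <- average_and_normalize(pa)
  nb_ <- average_and_normalize(pb)
  fa <- compute_fwhm(na_, pixel)
  fb <- compute_fwhm(nb_, pixel)
  out <- tibble(modality = c("a", "b"), fwhm_um = c(fa$fwhm, fb$fwhm),
                n_matched = nrow(mm), n_profiles = c(nrow(pa), nrow(pb)))
  attr(out, "profiles") <- list(a = na_, b = nb_)
  out
}

#' Plot normalized averaged profiles
#'
#' @param object a numeric profile from [average_and_normalize()], or the
#'   result of [resolution_gain()].
#' @param ... unused.
#' @return A ggplot.
#' @export
plot_profiles <- function(object, ...) {
  if (is_tibble(object) && !is.null(attr(object, "profiles"))) {
    pr <- attr(object, "profiles")
    df <- dplyr::bind_rows(lapply(names(pr), function(nm) {
      tibble(modality = nm, offset_um = attr(pr[[nm]], "offsets_um"),
             intensity = as.numeric(pr[[nm]]))
    }))
    return(ggplot(df, aes(.data$offset_um, .data$intensity,
                          colour = .data$modality)) +
             geom_line() + labs(x = "offset (um)", y = "normalized intensity") +
             theme_minimal())
  }
  df <- tibble(offset_um = attr(object, "offsets_um") %||%
                 seq_along(object), intensity = as.numeric(object))
  ggplot(df, aes(.data$offset_um, .data$intensity)) + geom_line() +
    labs(x = "offset (um)", y = "normalized intensity") + theme_minimal()
}
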