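# Nuclear landscape: nucleus segmentation (Otsu + largest component +
# hole filling), 2-class GMM compaction map, 7-class Potts/ICM compaction
# map (class 1 = interchromatin), trajectory-to-class voting, signal
# fraction mapping, and nuclear morphometry.

#' Segment the nucleus from a DNA-intensity volume
#'
#' Two-level Otsu threshold on the laterally smoothed volume (the first
#' Otsu split can land between the eu- and heterochromatin modes; a
#' second Otsu on the sub-threshold intensities separates background from
#' nucleus), largest 6-connected component, one-voxel lateral erosion to
#' recenter the blur-dilated boundary, per-slice hole filling.
#' Deterministic and scale-invariant in intensity.
#'
#' @param dna_volume 3-D (z, y, x) array.
#' @param voxel_size (z, y, x) voxel size, um.
#' @param smooth_sigma_um lateral smoothing scale before thresholding, um.
#' @return A `nucleus_mask`: list(mask, voxel_size).
#' @export
segment_nucleus <- function(dna_volume, voxel_size, smooth_sigma_um = 0.15) {
  vs <- as.numeric(voxel_size)
  d <- dim(dna_volume)
  sig_vox <- c(0, smooth_sigma_um / vs[2L], smooth_sigma_um / vs[3L])
  sig_vox[d == 1L] <- 0
  sm <- gauss_smooth(dna_volume, sig_vox)
  t1 <- otsu_threshold(as.vector(sm))
  low <- sm[sm <= t1]
  thr <- if (length(unique(low)) > 1L) otsu_threshold(as.vector(low)) else t1
  fg <- sm > thr
  if (!any(fg)) abort("empty foreground: nothing to segment")
  mask <- largest_component(fg)
  # one-voxel lateral erosion compensates the smoothing-induced dilation
  er <- mask
  for (a in 2:3) er <- er & shift1(mask, a, 1L) & shift1(mask, a, -1L)
  if (sum(er) > 0.5 * sum(mask)) mask <- er
  mask <- EBImage::fillHull(array(as.integer(mask), d)) > 0
  dim(mask) <- d
  structure(list(mask = mask, voxel_size = vs), class = "nucleus_mask")
}

new_compaction_map <- function(labels, K, class_means, voxel_size,
                               fallback = FALSE, class_sds = NULL) {
  structure(list(labels = labels, K = as.integer(K),
                 class_means = class_means, class_sds = class_sds,
                 voxel_size = voxel_size, fallback = fallback),
            class = "compaction_map")
}

#' @export
print.compaction_map <- function(x, ...) {
  cat(sprintf("<compaction_map> K = %d classes; means: %s%s\n", x$K,
              paste(signif(x$class_means, 4), collapse = ", "),
              if (x$fallback) " (degenerate fallback)" else ""))
  invisible(x)
}

#' Two-class chromatin compaction map (GMM)
#'
#' Fits a 2-component Gaussian mixture to the inside-mask DNA intensities
#' (EM, k-means-style deterministic subsample initialization, fixed seed)
#' and hard-assigns each voxel by posterior. Class 1 = lower mean
#' (euchromatin-like), class 2 = higher mean (heterochromatin-like).
#' Degenerate fits fall back to an Otsu split with `fallback = TRUE`.
#'
#' @param dna_volume 3-D array.
#' @param mask a [segment_nucleus()] result or logical array.
#' @param seed integer seed (subsample selection).
#' @param max_fit_n intensities subsampled for the EM fit.
#' @return A `compaction_map` with labels 0 (outside), 1, 2.
#' @export
classify_two_class <- function(dna_volume, mask, seed = 1L, max_fit_n = 20000L) {
  m <- if (inherits(mask, "nucleus_mask")) mask$mask else mask
  vs <- if (inherits(mask, "nucleus_mask")) mask$voxel_size else NULL
  vals <- dna_volume[m]
  if (length(unique(vals)) < 2L) abort("need >= 2 distinct intensities inside the mask")
  set.seed(seed)
  fit_vals <- if (length(vals) > max_fit_n) sample(vals, max_fit_n) else vals
  fit <- tryCatch(
    mclust::Mclust(fit_vals, G = 2L, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  labels <- array(0L, dim(dna_volume))
  degenerate <- is.null(fit) ||
    abs(diff(fit$parameters$mean)) <
      1e-6 * max(abs(fit$parameters$mean), 1e-12)
  if (degenerate) {
    thr <- otsu_threshold(vals)
    cl <- ifelse(vals > thr, 2L, 1L)
    labels[m] <- cl
    mus <- c(mean(vals[cl == 1L]), mean(vals[cl == 2L]))
    return(new_compaction_map(labels, 2L, mus, vs, fallback = TRUE))
  }
  ord <- order(fit$parameters$mean)
  pr <- predict(fit, newdata = vals)
  cl <- match(pr$classification, ord)
  labels[m] <- cl
  mus <- fit$parameters$mean[ord]
  sds <- sqrt(fit$parameters$variance$sigmasq)[ord]
  new_compaction_map(labels, 2L, unname(mus), vs, class_sds = unname(sds))
}

#' Seven-class compaction map (Potts-regularized ICM)
#'
#' Seven Gaussian intensity classes initialized at the inside-mask
#' intensity quantiles, refined by iterated conditional modes with a
#' Potts spatial prior of strength `beta` on the 6-neighbourhood; class
#' parameters are re-estimated after each sweep. Classes are relabeled so
#' mean intensity increases with index: class 1 is interchromatin (IC),
#' classes 2-3 low-compaction perichromatin, classes 4-7 the more
#' compacted inactive compartment. `beta = 0` reduces to per-voxel
#' maximum-likelihood Gaussian classification.
#'
#' @param dna_volume 3-D array.
#' @param mask [segment_nucleus()] result or logical array.
#' @param beta Potts prior strength (>= 0).
#' @param K number of classes.
#' @param max_iter ICM sweeps.
#' @param seed integer seed (reserved; the fit is deterministic).
#' @return A `compaction_map` with labels 0 (outside), 1..K and a
#'   `converged` attribute.
#' @export
classify_seven_class <- function(dna_volume, mask, beta = 0.5, K = 7L,
                                 max_iter = 20L, seed = 1L) {
  m <- if (inherits(mask, "nucleus_mask")) mask$mask else mask
  vs <- if (inherits(mask, "nucleus_mask")) mask$voxel_size else NULL
  vals <- dna_volume[m]
  if (length(unique(vals)) < K) abort("fewer distinct intensities than classes")
  d <- dim(dna_volume)
  qs <- quantile(vals, probs = (2 * seq_len(K) - 1) / (2 * K), names = FALSE)
  mus <- qs
  sds <- rep(max(sd(vals) / K, 1e-6), K)

  # initial per-voxel ML assignment
  lab <- array(0L, d)
  lab[m] <- max.col(-outer(vals, mus, function(v, mu) (v - mu)^2), "first")

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # M-step: re-estimate class parameters inside the mask
    lv <- lab[m]
    for (k in seq_len(K)) {
      vk <- vals[lv == k]
      if (length(vk) > 1L) {
        mus[k] <- mean(vk)
        sds[k] <- max(sd(vk), 1e-6)
      }
    }
    # data term: negative log Gaussian density per class
    energy <- array(Inf, dim = c(sum(m), K))
    for (k in seq_len(K)) {
      energy[, k] <- (vals - mus[k])^2 / (2 * sds[k]^2) + log(sds[k])
    }
    if (beta > 0) {
      for (k in seq_len(K)) {
        same <- array(0, d)
        isk <- lab == k
        for (a in 1:3) {
          same <- same + shift1(isk, a, 1L) + shift1(isk, a, -1L)
        }
        energy[, k] <- energy[, k] - beta * same[m]
      }
    }
    new_lv <- max.col(-energy, "first")
    changed <- mean(new_lv != lab[m])
    lab[m] <- new_lv
    if (changed < 1e-3) { converged <- TRUE; break }
  }
  # relabel so class means strictly increase; report the parameters the
  # final assignment was computed with
  lv <- lab[m]
  ord <- order(mus)
  lab[m] <- match(lv, ord)
  out <- new_compaction_map(lab, K, mus[ord], vs, class_sds = sds[ord])
  attr(out, "converged") <- converged
  if (!converged) warn("ICM did not converge within max_iter; returning last state")
  out
}

#' Assign trajectories to compaction classes by majority vote
#'
#' Each track point samples its frame's compaction map at the nearest
#' voxel; the track gets the class holding a strict majority of in-mask
#' points. Exact ties and all-outside tracks are `"unassigned"`. For
#' 2-class maps the labels are `"euchromatin"` / `"heterochromatin"`.
#'
#' @param tracks tibble with track_id, frame, z_um, y_um, x_um.
#' @param cmap a `compaction_map`, or a list of per-frame maps indexed by
#'   frame number.
#' @return Tibble: track_id, class (integer, NA = unassigned), label,
#'   n_inside, n_points.
#' @export
assign_track_class <- function(tracks, cmap) {
  get_map <- function(f) if (inherits(cmap, "compaction_map")) cmap else cmap[[f]]
  res <- lapply(split(tracks, tracks$track_id), function(tr) {
    cls <- integer(0)
    for (i in seq_len(nrow(tr))) {
      cm <- get_map(tr$frame[i])
      vs <- cm$voxel_size
      vox <- round(c(tr$z_um[i], tr$y_um[i], tr$x_um[i]) / vs) + 1L
      d <- dim(cm$labels)
      if (any(vox < 1L) || any(vox > d)) next
      l <- cm$labels[vox[1L], vox[2L], vox[3L]]
      if (l > 0L) cls <- c(cls, l)
    }
    K <- get_map(tr$frame[1L])$K
    n_in <- length(cls)
    if (n_in == 0L) {
      return(tibble(track_id = tr$track_id[1L], class = NA_integer_,
                    n_inside = 0L, n_points = nrow(tr)))
    }
    tab <- tabulate(cls, nbins = K)
    top <- which(tab == max(tab))
    cl <- if (length(top) > 1L || max(tab) * 2L <= n_in) NA_integer_ else top
    tibble(track_id = tr$track_id[1L], class = cl,
           n_inside = n_in, n_points = nrow(tr))
  })
  out <- dplyr::bind_rows(res)
  K <- if (inherits(cmap, "compaction_map")) cmap$K else cmap[[1L]]$K
  out$label <- if (K == 2L) {
    c("euchromatin", "heterochromatin")[out$class]
  } else paste0("class", out$class)
  out$label[is.na(out$class)] <- "unassigned"
  dplyr::select(out, "track_id", "class", "label", "n_inside", "n_points")
}

#' Intensity-weighted signal fractions per compaction class
#'
#' Segments the signal by Otsu threshold over the inside-mask voxels,
#' then reports, for each compaction class, the fraction of segmented
#' signal intensity falling in that class. Fractions sum to 1 (or are all
#' zero, flagged, when the segmentation is empty).
#'
#' @param signal_volume 3-D array, co-registered with the map.
#' @param cmap a `compaction_map`.
#' @return Tibble: class, fraction; attribute `empty` when nothing was
#'   segmented.
#' @export
map_signal_fractions <- function(signal_volume, cmap) {
  inmask <- cmap$labels > 0L
  if (!all(dim(signal_volume) == dim(cmap$labels))) abort("signal and map shapes differ")
  vals <- signal_volume[inmask]
  # constant signal: keep the whole mask rather than an empty segmentation
  thr <- if (diff(range(vals)) > 0) otsu_threshold(vals) else vals[1L] - 1e-9
  seg <- inmask & signal_volume > thr
  out <- tibble(class = seq_len(cmap$K), fraction = 0)
  tot <- sum(signal_volume[seg])
  if (tot <= 0) {
    attr(out, "empty") <- TRUE
    return(out)
  }
  for (k in seq_len(cmap$K)) {
    out$fraction[k] <- sum(signal_volume[seg & cmap$labels == k]) / tot
  }
  out
}

#' Nuclear morphometry
#'
#' Volume (voxel count times voxel volume), sphericity shape factor
#' `pi^(1/3) (6 V)^(2/3) / A` (1 for a perfect sphere) with the surface
#' area A estimated by the coarea formula on a lightly smoothed indicator
#' function, and the sum and standard deviation of the inside-mask DNA
#' intensities.
#'
#' @param mask a [segment_nucleus()] result or logical array.
#' @param dna_volume 3-D intensity array.
#' @param voxel_size (z, y, x) voxel size, um (taken from the mask object
#'   when present).
#' @return One-row tibble: volume_um3, shape_factor, sum_intensity,
#'   std_intensity, surface_um2.
#' @export
nuclear_morphometry <- function(mask, dna_volume, voxel_size = NULL) {
  m <- if (inherits(mask, "nucleus_mask")) mask$mask else mask
  vs <- voxel_size %||% (if (inherits(mask, "nucleus_mask")) mask$voxel_size else NULL)
  if (is.null(vs)) abort("voxel_size required")
  vol <- sum(m) * prod(vs)
  ind <- array(as.numeric(m), dim(m))
  sig_vox <- pmax(1, min(vs) / vs)
  sm <- gauss_smooth(ind, sig_vox)
  gz <- axis_gradient(sm, 1L, vs[1L])
  gy <- axis_gradient(sm, 2L, vs[2L])
  gx <- axis_gradient(sm, 3L, vs[3L])
  area <- sum(sqrt(gz^2 + gy^2 + gx^2)) * prod(vs)
  # coarea estimate can undershoot the area by a fraction of a percent on
  # near-perfect spheres; clip at the isoperimetric bound
  shape <- if (area > 0) min(pi^(1 / 3) * (6 * vol)^(2 / 3) / area, 1) else NA_real_
  vals <- dna_volume[m]
  tibble(volume_um3 = vol, shape_factor = shape,
         sum_intensity = sum(vals), std_intensity = sd(vals),
         surface_um2 = area)
}
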