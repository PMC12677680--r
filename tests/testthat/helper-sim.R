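# Shared fixtures, all generated in code.

# Roomy isotropic nucleus so boundary confinement is negligible.
free_nucleus <- function(r = 10) nucleus_ellipsoid(semiaxes = c(r, r, r))

# All permutations of 1..n (for brute-force assignment oracles).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      out <- c(out, list(c(i, setdiff(seq_len(n), i)[p])))
    }
  }
  out
}

# Independent brute-force radius of gyration for one track matrix (n x 3).
brute_rg <- function(P) {
  ctr <- colMeans(P)
  tot <- 0
  for (i in seq_len(nrow(P))) tot <- tot + sum((P[i, ] - ctr)^2)
  sqrt(tot / nrow(P))
}

# Lateral-only detection-vs-truth matching stats for one frame.
match_stats <- function(det, truth, max_dist) {
  d <- det[, c("y_um", "x_um")]
  g <- truth[, c("y_um", "x_um")]
  mm <- match_detections(d, g, max_dist = max_dist)
  list(recall = nrow(mm) / nrow(g), precision = nrow(mm) / nrow(det),
       rmse = if (nrow(mm)) sqrt(mean(mm$dist_um^2)) else NA_real_)
}

# Small rendered movie with well-separated foci; returns truth + movie.
spot_movie <- function(n_foci = 25, n_frames = 3, D = 14.99e-5,
                       photon_scale = 150, seed = 7, min_separation = 0.4,
                       shape = c(5L, 96L, 96L), ...) {
  cfg <- sim_config(n_foci = n_foci, n_frames = n_frames, image_shape = shape,
                    D = D, loc_noise_sigma = 0, photon_scale = photon_scale,
                    background = 5, read_noise_sd = 2, bleach_rate = 0,
                    seed = seed, ...)
  nuc <- simulate_nucleus(shape = cfg$image_shape, voxel_size = cfg$voxel_size,
                          seed = seed)
  truth <- simulate_trajectories(cfg, nuc, min_separation = min_separation)
  rend <- render_movie(truth, cfg)
  list(cfg = cfg, movie = rend$movie, truth = rend$truth)
}
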