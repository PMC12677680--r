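test_that("config validation rejects unphysical parameters", {
  expect_error(sim_config(alpha = 0), "alpha")
  expect_error(sim_config(alpha = 2.5), "alpha")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(D = -1), "D")
})

test_that("zero-motion, zero-noise trajectories are constant with MSD 0", {
  cfg <- sim_config(n_foci = 20, n_frames = 30, D = 0, loc_noise_sigma = 0,
                    seed = 1)
  tk <- truth_tracks(simulate_trajectories(cfg, free_nucleus()), "observed")
  spread <- tapply(tk$x_um, tk$track_id, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  m <- compute_msd(tk, cfg$dt)
  expect_true(all(m$msd_um2 == 0))
})

test_that("Brownian ensemble MSD matches 6 D k dt + 6 sigma^2 within 3 SE", {
  cfg <- sim_config(n_foci = 1000, n_frames = 101, D = 14.99e-5, alpha = 1,
                    loc_noise_sigma = 0.03, dt = 5, seed = 1)
  tk <- truth_tracks(simulate_trajectories(cfg, free_nucleus()), "observed")
  m <- compute_msd(tk, cfg$dt, max_lag = 50)
  expected <- 6 * cfg$D * m$lag_s + 6 * cfg$loc_noise_sigma^2
  # closed-form spot check at the first lag (5 s): 0.0099 um^2
  expect_equal(m$msd_um2[1], 0.0099, tolerance = 0.05)
  per <- attr(m, "per_track")
  se <- apply(per[, seq_len(nrow(m)), drop = FALSE], 2L,
              function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
  expect_true(all(abs(m$msd_um2 - expected) <= 3 * se))
})

test_that("fBm trajectories have MSD 6 Gamma t^alpha and the right log-log slope", {
  cfg <- sim_config(n_foci = 2000, n_frames = 101, D = 1e-4, alpha = 0.5,
                    loc_noise_sigma = 0, dt = 5, seed = 2)
  tk <- truth_tracks(simulate_trajectories(cfg, free_nucleus()), "true")
  m <- compute_msd(tk, cfg$dt, max_lag = 100)
  for (lag in c(5, 10, 20)) {
    expect_equal(m$msd_um2[m$lag_s == lag], 6e-4 * lag^0.5, tolerance = 0.05)
  }
  slope <- unname(coef(lm(log(m$msd_um2) ~ log(m$lag_s)))[2])
  expect_lt(abs(slope - 0.5), 0.05)
})

test_that("a fixed seed reproduces trajectories and rendered movies exactly", {
  cfg <- sim_config(n_foci = 5, n_frames = 4, image_shape = c(5, 32, 32),
                    seed = 9)
  nuc <- simulate_nucleus(shape = cfg$image_shape, voxel_size = cfg$voxel_size,
                          seed = 9)
  t1 <- simulate_trajectories(cfg, nuc)
  t2 <- simulate_trajectories(cfg, nuc)
  expect_identical(t1$tracks, t2$tracks)
  r1 <- render_movie(t1, cfg)
  r2 <- render_movie(t2, cfg)
  expect_identical(r1$movie$data, r2$movie$data)
})

test_that("nucleus texture is a two-component mixture at the configured fractions", {
  nuc <- simulate_nucleus(shape = c(5, 96, 96), het_fraction = 0.5,
                          mean_eu = 100, mean_het = 300, seed = 4)
  frac_het <- mean(nuc$labels[nuc$mask] == 2L)
  expect_lt(abs(frac_het - 0.5), 0.05)
  # bimodality: class-conditional means are far apart relative to sd
  mu1 <- mean(nuc$dna[nuc$labels == 1L])
  mu2 <- mean(nuc$dna[nuc$labels == 2L])
  expect_gt(mu2 - mu1, 150)
  nuc2 <- simulate_nucleus(shape = c(5, 96, 96), het_fraction = 0.5,
                           mean_eu = 100, mean_het = 300, seed = 4)
  expect_identical(nuc$dna, nuc2$dna)
})

test_that("ellipsoid mask volume matches the closed form", {
  vs <- c(0.1, 0.1, 0.1)
  nuc <- simulate_nucleus(shape = c(45, 85, 85), voxel_size = vs,
                          semiaxes = c(2, 4, 4), seed = 1)
  vol <- sum(nuc$mask) * prod(vs)
  true_vol <- 4 / 3 * pi * 2 * 4 * 4          # 134.04 um^3
  # one voxel-shell tolerance: surface area x voxel edge
  shell <- 4 * pi * (4 * 4 * 2)^(2 / 3) * 0.1  # generous shell bound
  expect_lt(abs(vol - true_vol), 1.5 * shell)
  expect_lt(abs(vol - true_vol) / true_vol, 0.05)
})

test_that("rendering an empty scene gives pure background", {
  cfg <- sim_config(n_foci = 0, n_frames = 2, image_shape = c(3, 16, 16),
                    background = 10, shot_noise = FALSE, read_noise_sd = 0,
                    seed = 1)
  nuc <- simulate_nucleus(shape = cfg$image_shape, voxel_size = cfg$voxel_size,
                          seed = 1)
  rend <- render_movie(simulate_trajectories(cfg, nuc), cfg)
  expect_true(all(rend$movie$data[, 2L, , , ] == 10))
})

test_that("a static focus renders at its voxel in every frame", {
  cfg <- sim_config(n_foci = 1, n_frames = 5, image_shape = c(5, 32, 32),
                    D = 0, loc_noise_sigma = 0, shot_noise = FALSE,
                    read_noise_sd = 0, bleach_rate = 0, background = 0,
                    seed = 2)
  nuc <- simulate_nucleus(shape = cfg$image_shape, voxel_size = cfg$voxel_size,
                          seed = 2)
  truth <- simulate_trajectories(cfg, nuc)
  rend <- render_movie(truth, cfg)
  p <- as.numeric(truth$tracks[1, c("z_um", "y_um", "x_um")])
  want <- round(p / cfg$voxel_size) + 1
  for (t in 1:5) {
    vol <- movie_volume(rend$movie, t, 2L)
    expect_equal(as.integer(arrayInd(which.max(vol), dim(vol))),
                 as.integer(want))
  }
})

test_that("integrated spot intensity matches the Gaussian integral", {
  vs <- c(0.1, 0.05, 0.05)
  vol <- array(0, c(25, 64, 64))
  sig <- c(0.17, 0.085, 0.085)
  vol <- chromodyn:::add_spot(vol, c(1.2, 1.6, 1.6), sig, 50, vs)
  analytic <- 50 * (2 * pi)^1.5 * prod(sig) / prod(vs)
  expect_equal(sum(vol), analytic, tolerance = 0.02)
})

test_that("frame-summed expected signal decays exactly with the bleach rate", {
  cfg <- sim_config(n_foci = 3, n_frames = 10, image_shape = c(9, 48, 48),
                    voxel_size = c(0.1, 0.05, 0.05), D = 0,
                    loc_noise_sigma = 0, shot_noise = FALSE,
                    read_noise_sd = 0, bleach_rate = 0.01, background = 2,
                    seed = 3)
  nuc <- simulate_nucleus(shape = cfg$image_shape, voxel_size = cfg$voxel_size,
                          seed = 3)
  rend <- render_movie(simulate_trajectories(cfg, nuc), cfg)
  s <- vapply(1:10, function(t) {
    sum(rend$movie$data[t, 2L, , , ]) - 2 * prod(cfg$image_shape)
  }, numeric(1))
  expect_equal(s / s[1], exp(-0.01 * (0:9) * cfg$dt), tolerance = 1e-9)
})

test_that("matched PSF pairs are identical when widths agree, reproducible when seeded", {
  pts <- cbind(c(1, 2.5), c(1, 2.5))
  colnames(pts) <- NULL
  pa <- render_psf_pair(pts, 0.3, 0.3, pixel = 0.02, shot_noise = FALSE,
                        seed = 1)
  expect_identical(pa$image_a, pa$image_b)
  pb1 <- render_psf_pair(pts, 0.3, 0.14, pixel = 0.02, seed = 5)
  pb2 <- render_psf_pair(pts, 0.3, 0.14, pixel = 0.02, seed = 5)
  expect_identical(pb1$image_a, pb2$image_a)
  expect_identical(pb1$image_b, pb2$image_b)
})

test_that("a single rendered emitter has the requested profile FWHM", {
  p <- render_psf_pair(cbind(1.5, 1.5), 0.30, 0.14, pixel = 0.02,
                       shape = c(151, 151), shot_noise = FALSE, seed = 1)
  det <- tibble::tibble(y_um = 1.5, x_um = 1.5)
  prof <- extract_profiles(p$image_a, det, pixel = 0.02, length_um = 1)
  fw <- compute_fwhm(as.numeric(prof[1, ]), pixel = 0.02)
  expect_lt(abs(fw$fwhm - 0.30), 0.02)  # within one pixel
  expect_warning(
    render_psf_pair(rbind(c(1, 1), c(1.05, 1)), 0.3, 0.14, pixel = 0.02,
                    shot_noise = FALSE, seed = 1),
    "closer")
})

test_that("trajectories stay inside the nucleus", {
  nuc <- nucleus_ellipsoid(c(0.5, 1, 1), center = c(1, 2, 2))
  cfg <- sim_config(n_foci = 50, n_frames = 200, D = 5e-4,
                    loc_noise_sigma = 0, seed = 6)
  tk <- truth_tracks(simulate_trajectories(cfg, nuc), "true")
  u2 <- ((tk$z_um - 1) / 0.5)^2 + ((tk$y_um - 2) / 1)^2 + ((tk$x_um - 2) / 1)^2
  expect_true(all(u2 <= 1 + 1e-9))
})
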