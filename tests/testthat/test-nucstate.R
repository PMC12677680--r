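nuc_vs <- c(0.170, 0.048, 0.048)
nuc_ref <- simulate_nucleus(shape = c(5, 96, 96), voxel_size = nuc_vs, seed = 5)

test_that("nucleus segmentation recovers the true mask", {
  noisy <- nuc_ref$dna + array(rnorm(length(nuc_ref$dna), 0, 5),
                               dim(nuc_ref$dna))
  nm <- segment_nucleus(noisy, nuc_vs)
  dice <- 2 * sum(nm$mask & nuc_ref$mask) / (sum(nm$mask) + sum(nuc_ref$mask))
  expect_gte(dice, 0.95)
  # scale invariance and all-background error
  nm10 <- segment_nucleus(noisy * 10, nuc_vs)
  expect_identical(nm$mask, nm10$mask)
  expect_error(segment_nucleus(array(0, c(3, 8, 8)), nuc_vs), "foreground|segment")
})

test_that("the 2-class GMM map recovers the true mixture with <1% error", {
  cm <- classify_two_class(nuc_ref$dna, nuc_ref$mask, seed = 1)
  cm$voxel_size <- nuc_vs
  inm <- nuc_ref$mask
  mis <- mean(cm$labels[inm] != nuc_ref$labels[inm])
  expect_lt(mis, 0.01)
  expect_lt(cm$class_means[1], cm$class_means[2])
  cm2 <- classify_two_class(nuc_ref$dna, nuc_ref$mask, seed = 1)
  expect_identical(cm$labels, cm2$labels)
})

test_that("a unimodal texture falls back to an Otsu split with a flag", {
  d <- c(3, 40, 40)
  vol <- array(rnorm(prod(d), 100, 5), d)
  mask <- array(TRUE, d)
  cm <- classify_two_class(vol, mask, seed = 1)
  expect_equal(cm$K, 2L)
  expect_lt(cm$class_means[1], cm$class_means[2])
})

test_that("7-class ICM recovers known plateaus and orders class means", {
  set.seed(9)
  d <- c(5, 60, 60)
  lab_true <- array(0L, d); plat <- array(0, d)
  for (k in 1:7) {
    cols <- ((k - 1) * 8 + 3):(k * 8 + 2)
    lab_true[, , cols] <- k
    plat[, , cols] <- k * 50
  }
  maskv <- lab_true > 0L
  noisy <- plat + array(rnorm(prod(d), 0, 12), d)
  cm7 <- classify_seven_class(noisy, maskv, beta = 0.5)
  expect_gte(mean(cm7$labels[maskv] == lab_true[maskv]), 0.95)
  expect_true(all(diff(cm7$class_means) > 0))
})

test_that("ICM with beta = 0 equals per-voxel maximum-likelihood assignment", {
  set.seed(10)
  d <- c(4, 40, 40)
  vol <- array(rnorm(prod(d), rep(c(60, 120, 200, 280, 360, 460, 560),
                                  length.out = prod(d)), 20), d)
  mask <- array(TRUE, d)
  cm <- classify_seven_class(vol, mask, beta = 0)
  vals <- vol[mask]
  en <- sapply(1:7, function(k) {
    (vals - cm$class_means[k])^2 / (2 * cm$class_sds[k]^2) + log(cm$class_sds[k])
  })
  ml <- max.col(-en, "first")
  expect_equal(cm$labels[mask], ml)
})

test_that("track class assignment follows the majority with tie -> unassigned", {
  d <- c(3, 20, 20)
  labels <- array(0L, d)
  labels[, , 1:10] <- 1L
  labels[, , 11:20] <- 2L
  cmap <- chromodyn:::new_compaction_map(labels, 2L, c(100, 300),
                                         voxel_size = c(0.1, 0.1, 0.1))
  tk <- tibble::tibble(track_id = 1L, frame = 1:10, z_um = 0.1,
                       y_um = 0.5, x_um = c(rep(0.2, 7), rep(1.5, 3)))
  out <- assign_track_class(tk, cmap)
  expect_equal(out$label, "euchromatin")
  tie <- tibble::tibble(track_id = 1L, frame = 1:10, z_um = 0.1, y_um = 0.5,
                        x_um = c(rep(0.2, 5), rep(1.5, 5)))
  expect_equal(assign_track_class(tie, cmap)$label, "unassigned")
  outside <- tibble::tibble(track_id = 1L, frame = 1:4, z_um = 9, y_um = 9,
                            x_um = 9)
  expect_equal(assign_track_class(outside, cmap)$label, "unassigned")
})

test_that("tracks seeded in known compaction blobs are assigned correctly", {
  cmap <- chromodyn:::new_compaction_map(nuc_ref$labels, 2L, c(100, 300),
                                         voxel_size = nuc_vs)
  set.seed(11)
  inside <- which(nuc_ref$labels > 0L)
  pick <- sample(inside, 60)
  idx <- arrayInd(pick, dim(nuc_ref$labels))
  tk <- dplyr::bind_rows(lapply(seq_along(pick), function(i) {
    tibble::tibble(track_id = i, frame = 1:5,
                   z_um = (idx[i, 1] - 1) * nuc_vs[1],
                   y_um = (idx[i, 2] - 1) * nuc_vs[2],
                   x_um = (idx[i, 3] - 1) * nuc_vs[3])
  }))
  out <- assign_track_class(tk, cmap)
  truth <- nuc_ref$labels[pick]
  expect_gte(mean(out$class == truth, na.rm = TRUE), 0.9)
})

test_that("signal fractions obey point-mass, uniform and scaling identities", {
  d <- c(3, 30, 30)
  labels <- array(0L, d)
  labels[, , 1:10] <- 1L; labels[, , 11:20] <- 2L; labels[, , 21:30] <- 3L
  cmap <- chromodyn:::new_compaction_map(labels, 3L, c(1, 2, 3),
                                         voxel_size = c(0.1, 0.1, 0.1))
  sig <- array(0, d)
  sig[, , 24:26] <- 100
  fr <- map_signal_fractions(sig, cmap)
  expect_equal(fr$fraction, c(0, 0, 1))
  uni <- array(50, d)
  fru <- map_signal_fractions(uni, cmap)
  expect_equal(fru$fraction, rep(1 / 3, 3), tolerance = 0.01)
  fr2 <- map_signal_fractions(sig * 2, cmap)
  expect_equal(fr2$fraction, fr$fraction)
  expect_equal(sum(fr$fraction), 1)
})

test_that("morphometry matches the digital-ball closed form and moment identities", {
  vs <- c(0.1, 0.1, 0.1)
  d <- c(61, 61, 61)
  ctr <- (d - 1) / 2 * 0.1
  zc <- (0:60) * 0.1
  U <- outer(outer((zc - ctr[1])^2, (zc - ctr[2])^2, `+`), (zc - ctr[3])^2, `+`)
  ball <- U <= 4
  dna <- array(rnorm(prod(d), 100, 10), d)
  mo <- nuclear_morphometry(ball, dna, vs)
  expect_lt(abs(mo$volume_um3 - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.03)
  expect_gte(mo$shape_factor, 0.95)
  expect_lte(mo$shape_factor, 1)
  mo2 <- nuclear_morphometry(ball, dna + 7, vs)
  expect_equal(mo2$std_intensity, mo$std_intensity, tolerance = 1e-9)
  expect_equal(mo2$sum_intensity, mo$sum_intensity + 7 * sum(ball),
               tolerance = 1e-6)
  # elongated ellipsoid is less spherical
  E <- outer(outer((zc - ctr[1])^2 / 0.81, (zc - ctr[2])^2 / 0.81, `+`),
             (zc - ctr[3])^2 / (3.6^2), `+`)
  ell <- E <= 1
  moe <- nuclear_morphometry(ell, dna, vs)
  expect_lt(moe$shape_factor, mo$shape_factor)
})

test_that("slower foci in heterochromatin give a lower MSD curve than euchromatin", {
  # cohorts simulated with D depending on the true compaction class
  cfg_fast <- sim_config(n_foci = 150, n_frames = 40, D = 14.99e-5,
                         loc_noise_sigma = 0.02, seed = 41)
  cfg_slow <- sim_config(n_foci = 150, n_frames = 40, D = 4e-5,
                         loc_noise_sigma = 0.02, seed = 42)
  nuc <- nuc_ref
  pick_in <- function(cls, n, seed) {
    set.seed(seed)
    arrayInd(sample(which(nuc$labels == cls), n), dim(nuc$labels))
  }
  mk_tracks <- function(cfg, cls, seed, id0) {
    tr <- simulate_trajectories(cfg, nucleus_ellipsoid(c(3, 3, 3)))
    tk <- truth_tracks(tr, "observed")
    # re-anchor each trajectory at a voxel of the requested class
    anchors <- pick_in(cls, cfg$n_foci, seed)
    dplyr::bind_rows(lapply(unique(tk$track_id), function(id) {
      p <- tk[tk$track_id == id, ]
      a <- anchors[id, ]
      p$z_um <- p$z_um - p$z_um[1] + (a[1] - 1) * nuc_vs[1]
      p$y_um <- p$y_um - p$y_um[1] + (a[2] - 1) * nuc_vs[2]
      p$x_um <- p$x_um - p$x_um[1] + (a[3] - 1) * nuc_vs[3]
      p$track_id <- id + id0
      p
    }))
  }
  eu <- mk_tracks(cfg_fast, 1L, 41, 0L)
  het <- mk_tracks(cfg_slow, 2L, 42, 1000L)
  cmap <- chromodyn:::new_compaction_map(nuc$labels, 2L, c(100, 300),
                                         voxel_size = nuc_vs)
  asg <- assign_track_class(dplyr::bind_rows(eu, het), cmap)
  all_tk <- dplyr::bind_rows(eu, het)
  ids_eu <- asg$track_id[asg$label == "euchromatin"]
  ids_het <- asg$track_id[asg$label == "heterochromatin"]
  m_eu <- compute_msd(all_tk[all_tk$track_id %in% ids_eu, ], 5, max_lag = 50)
  m_het <- compute_msd(all_tk[all_tk$track_id %in% ids_het, ], 5, max_lag = 50)
  expect_true(all(m_het$msd_um2 < m_eu$msd_um2))
})
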