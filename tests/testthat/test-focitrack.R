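test_that("a static spot over 100 frames gives exactly one full-length track", {
  det <- tibble::tibble(frame = 1:100, z_um = 1, y_um = 2, x_um = 3)
  tk <- track(det, tracker_params(), dt = 5)
  expect_equal(length(unique(tk$track_id)), 1L)
  expect_equal(nrow(tk), 100L)
})

test_that("two well-separated Brownian spots never swap identity", {
  cfg <- sim_config(n_foci = 2, n_frames = 200, D = 1e-4, loc_noise_sigma = 0,
                    seed = 5)
  nuc <- nucleus_ellipsoid(c(5, 8, 8))
  tt <- truth_tracks(simulate_trajectories(cfg, nuc, min_separation = 5), "true")
  det <- tt[, c("frame", "z_um", "y_um", "x_um")]
  tk <- track(det, tracker_params(gate_radius = 0.5), dt = 5)
  expect_equal(length(unique(tk$track_id)), 2L)
  # each output track coincides with exactly one ground-truth focus
  for (id in unique(tk$track_id)) {
    pts <- tk[tk$track_id == id, ]
    ref <- tt[tt$track_id == tt$track_id[which.min(abs(tt$y_um - pts$y_um[1]))], ]
    joined <- merge(pts, ref, by = "frame")
    expect_lt(max(abs(joined$y_um.x - joined$y_um.y)), 1e-9)
  }
})

test_that("dense simulated detections are relinked with high track overlap", {
  cfg <- sim_config(n_foci = 100, n_frames = 50, D = 14.99e-5,
                    loc_noise_sigma = 0.02, seed = 6)
  nuc <- nucleus_ellipsoid(c(1, 4, 4))
  truth <- simulate_trajectories(cfg, nuc, min_separation = 0.45)
  tt <- truth_tracks(truth, "observed")
  det <- tt[order(tt$frame), c("frame", "z_um", "y_um", "x_um")]
  tk <- track(det, tracker_params(gate_radius = 0.3), dt = 5)
  # Jaccard overlap of frame-to-frame links (position-keyed)
  link_key <- function(d) {
    d <- d[order(d$track_id, d$frame), ]
    keys <- character(0)
    for (id in unique(d$track_id)) {
      p <- d[d$track_id == id, ]
      if (nrow(p) < 2L) next
      a <- p[-nrow(p), ]; b <- p[-1, ]
      ok <- b$frame == a$frame + 1L
      keys <- c(keys, sprintf("%d:%.6f:%.6f>%.6f:%.6f",
                              a$frame[ok], a$y_um[ok], a$x_um[ok],
                              b$y_um[ok], b$x_um[ok]))
    }
    keys
  }
  lt <- link_key(tt)
  lk <- link_key(tk)
  jac <- length(intersect(lt, lk)) / length(union(lt, lk))
  expect_gte(jac, 0.9)
})

test_that("no link exceeds the gate and detections are used at most once", {
  cfg <- sim_config(n_foci = 40, n_frames = 30, D = 2e-4,
                    loc_noise_sigma = 0.02, seed = 9)
  tt <- truth_tracks(simulate_trajectories(cfg, free_nucleus(), 0.5), "observed")
  det <- tt[, c("frame", "z_um", "y_um", "x_um")]
  gate <- 0.35
  tk <- track(det, tracker_params(gate_radius = gate, max_gap = 1L), dt = 5)
  expect_lte(nrow(tk), nrow(det))
  expect_false(any(duplicated(tk[, c("frame", "z_um", "y_um", "x_um")])))
  for (id in unique(tk$track_id)) {
    p <- tk[tk$track_id == id, ]
    if (nrow(p) < 2L) next
    dfr <- diff(p$frame)
    step <- sqrt(diff(p$z_um)^2 + diff(p$y_um)^2 + diff(p$x_um)^2)
    expect_true(all(step[dfr == 1L] <= gate + 1e-9))
  }
})

test_that("duration filtering keeps tracks with at least min_steps points", {
  lens <- c(5, 9, 10, 11, 100)
  det <- dplyr::bind_rows(lapply(seq_along(lens), function(i) {
    tibble::tibble(track_id = i, frame = seq_len(lens[i]),
                   z_um = 0, y_um = i, x_um = 0)
  }))
  expect_equal(length(unique(filter_by_duration(det, 10L)$track_id)), 3L)
  expect_equal(length(unique(filter_by_duration(det, 2L)$track_id)), 5L)
  expect_equal(length(unique(filter_by_duration(det, 100L)$track_id)), 1L)
})

test_that("size split halves the cohort and puts the median in the small group", {
  tk <- tibble::tibble(track_id = rep(1:4, each = 3), frame = rep(1:3, 4),
                       z_um = 0, y_um = 0, x_um = 0,
                       size_um = rep(c(1, 2, 3, 4), each = 3))
  sp <- split_by_size(tk)
  expect_setequal(unique(sp$small$track_id), c(1L, 2L))
  expect_setequal(unique(sp$large$track_id), c(3L, 4L))
  tk5 <- dplyr::bind_rows(tk, tibble::tibble(track_id = 5L, frame = 1:3,
                                             z_um = 0, y_um = 0, x_um = 0,
                                             size_um = 2.5))
  sp5 <- split_by_size(tk5)
  expect_equal(length(unique(sp5$small$track_id)), 3L)
  expect_true(5L %in% sp5$small$track_id)  # median-size track goes small
})

test_that("the size split recovers two true size populations", {
  set.seed(4)
  n <- 40
  true_sizes <- c(rnorm(n / 2, 0.08, 0.008), rnorm(n / 2, 0.16, 0.016))
  tk <- dplyr::bind_rows(lapply(1:n, function(i) {
    tibble::tibble(track_id = i, frame = 1:12, z_um = 0, y_um = 0, x_um = 0,
                   size_um = true_sizes[i] + rnorm(12, 0, 0.01))
  }))
  sp <- split_by_size(tk)
  small_ids <- unique(sp$small$track_id)
  mis <- (sum(small_ids > n / 2) + sum(setdiff(1:n, small_ids) <= n / 2)) / n
  expect_lte(mis, 0.1)
})

test_that("tracking does not bias the fitted diffusion coefficient", {
  cfg <- sim_config(n_foci = 100, n_frames = 100, D = 14.99e-5,
                    loc_noise_sigma = 0.03, seed = 13)
  truth <- simulate_trajectories(cfg, nucleus_ellipsoid(c(2, 5, 5)), 0.5)
  tt <- truth_tracks(truth, "observed")
  d_true <- fit_diffusion(compute_msd(tt, cfg$dt), 50)$D
  det <- tt[order(tt$frame), c("frame", "z_um", "y_um", "x_um")]
  tk <- filter_by_duration(track(det, tracker_params(gate_radius = 0.4),
                                 cfg$dt), 10L)
  d_trk <- fit_diffusion(compute_msd(tk, cfg$dt), 50)$D
  expect_lt(abs(d_trk - d_true) / d_true, 0.1)
})

test_that("empty input tracks to empty output", {
  det <- tibble::tibble(frame = integer(), z_um = numeric(),
                        y_um = numeric(), x_um = numeric())
  expect_equal(nrow(track(det, tracker_params(), 5)), 0L)
})
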