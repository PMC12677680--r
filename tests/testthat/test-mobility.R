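test_that("MSD of static and ballistic tracks matches closed forms", {
  st <- tibble::tibble(track_id = 1L, frame = 1:20, z_um = 1, y_um = 1, x_um = 1)
  m <- compute_msd(st, dt = 5)
  expect_true(all(m$msd_um2 == 0))
  v <- c(0.01, 0.02, -0.01)
  ba <- tibble::tibble(track_id = 1L, frame = 1:20,
                       z_um = v[1] * (1:20) * 5, y_um = v[2] * (1:20) * 5,
                       x_um = v[3] * (1:20) * 5)
  mb <- compute_msd(ba, dt = 5)
  expect_equal(mb$msd_um2, sum(v^2) * mb$lag_s^2, tolerance = 1e-12)
})

test_that("gaps are excluded pairwise from the time average", {
  tk <- tibble::tibble(track_id = 1L, frame = c(1:5, 7:10),
                       z_um = 0, y_um = 0, x_um = (c(1:5, 7:10)) * 0.1)
  m <- compute_msd(tk, dt = 1, max_lag = 3)
  # displacement per frame is exactly 0.1 along x, so MSD(k) = (0.1 k)^2
  expect_equal(m$msd_um2, (0.1 * m$lag_s)^2, tolerance = 1e-12)
  expect_equal(m$n_pairs[1], 7L)  # frame pairs (1..4,+1) and (7..9,+1)
})

test_that("diffusion fits recover exact curves and clip at zero", {
  t_ <- seq(5, 50, by = 5)
  c1 <- tibble::tibble(lag_s = t_, msd_um2 = 6 * 2e-4 * t_)
  f1 <- fit_diffusion(c1, 50)
  expect_equal(f1$D, 2e-4, tolerance = 1e-12)
  expect_equal(f1$b, 0, tolerance = 1e-12)
  expect_lt(f1$residual_rms, 1e-15)
  c2 <- tibble::tibble(lag_s = t_, msd_um2 = 6 * 1e-4 * t_ + 0.0024)
  f2 <- fit_diffusion(c2, 50)
  expect_equal(f2$D, 1e-4, tolerance = 1e-9)
  expect_equal(f2$b, 0.0024, tolerance = 1e-9)
  c3 <- tibble::tibble(lag_s = t_, msd_um2 = 0.01 - 1e-5 * t_)
  f3 <- fit_diffusion(c3, 50)
  expect_equal(f3$D, 0)
  expect_true(f3$clipped)
  expect_error(fit_diffusion(c1[1:2, ], 50), "3 lags")
})

test_that("anomalous fits recover exact power laws and the Brownian limit", {
  t_ <- seq(5, 200, by = 5)
  a1 <- fit_anomalous(tibble::tibble(lag_s = t_, msd_um2 = 6 * 1e-4 * t_^0.6))
  expect_equal(a1$alpha, 0.6, tolerance = 1e-6)
  expect_equal(a1$Gamma, 1e-4, tolerance = 1e-6)
  a2 <- fit_anomalous(tibble::tibble(lag_s = t_, msd_um2 = 6 * 5e-5 * t_))
  expect_equal(a2$alpha, 1, tolerance = 1e-6)
})

test_that("motion classification uses a strict 0.9 boundary", {
  expect_equal(classify_motion(0.5), "subdiffusive")
  expect_equal(classify_motion(0.9), "normal-or-super")
  expect_equal(classify_motion(1.0), "normal-or-super")
})

test_that("radius of gyration matches identities and a brute-force oracle", {
  st <- tibble::tibble(track_id = 1L, frame = 1:10, z_um = 2, y_um = 2, x_um = 2)
  expect_equal(radius_of_gyration(st, 5)$rg_um, 0)
  two <- tibble::tibble(track_id = 1L, frame = 1:2,
                        z_um = c(0, 0), y_um = c(0, 0.3), x_um = c(0, 0.4))
  expect_equal(radius_of_gyration(two, 5)$rg_um, 0.25)  # d/2 with d = 0.5
  cfg <- sim_config(n_foci = 2000, n_frames = 20, D = 1e-4,
                    loc_noise_sigma = 0.02, seed = 17)
  tk <- truth_tracks(simulate_trajectories(cfg, free_nucleus()), "observed")
  rg <- radius_of_gyration(tk, cfg$dt, duration = 500)
  brute <- vapply(split(tk, tk$track_id), function(p) {
    brute_rg(cbind(p$z_um, p$y_um, p$x_um))
  }, numeric(1))
  expect_equal(rg$rg_um, unname(brute[as.character(rg$track_id)]),
               tolerance = 1e-12)
})

test_that("rg uses only points within the requested duration window", {
  tk <- tibble::tibble(track_id = 1L, frame = 1:200, z_um = 0, y_um = 0,
                       x_um = c(rep(0, 101), rep(10, 99)))
  rg <- radius_of_gyration(tk, dt = 5, duration = 500)
  expect_equal(rg$rg_um, 0)           # the jump at frame 102 is outside 500 s
  expect_equal(rg$n_points, 101L)
})

test_that("the localization bias b is recovered across noise levels", {
  for (sig in c(0.01, 0.02, 0.03)) {
    cfg <- sim_config(n_foci = 1000, n_frames = 40, D = 1e-4,
                      loc_noise_sigma = sig, seed = round(1000 * sig))
    tk <- truth_tracks(simulate_trajectories(cfg, free_nucleus()), "observed")
    f <- fit_diffusion(compute_msd(tk, cfg$dt, max_lag = 50), 50)
    expect_lt(abs(f$b - 6 * sig^2) / (6 * sig^2), 0.2)
  }
})

test_that("confined motion shows an MSD plateau and a sub-diffusive exponent", {
  cfg <- sim_config(n_foci = 400, n_frames = 150, D = 1e-3,
                    loc_noise_sigma = 0, seed = 19)
  sphere <- nucleus_ellipsoid(c(0.5, 0.5, 0.5), center = c(1, 1, 1))
  tk <- truth_tracks(simulate_trajectories(cfg, sphere), "true")
  m <- compute_msd(tk, cfg$dt)
  a <- fit_anomalous(m)
  expect_lt(a$alpha, 0.9)
  n <- nrow(m)
  late <- mean(m$msd_um2[(n - 9):n])
  mid <- mean(m$msd_um2[floor(n / 2) + (-4:5)])
  expect_lt(late / mid, 1.15)  # plateau: late lags no longer grow
})

test_that("higher simulated D gives higher fitted D and larger rg", {
  fit_one <- function(D, seed) {
    cfg <- sim_config(n_foci = 500, n_frames = 101, D = D,
                      loc_noise_sigma = 0.03, seed = seed)
    tk <- truth_tracks(simulate_trajectories(cfg, free_nucleus()), "observed")
    list(D = fit_diffusion(compute_msd(tk, cfg$dt, max_lag = 50), 50)$D,
         rg = mean(radius_of_gyration(tk, cfg$dt, 500)$rg_um))
  }
  hi <- fit_one(14.99e-5, 23)
  lo <- fit_one(8.38e-5, 24)
  expect_gt(hi$D, lo$D)
  expect_gt(hi$rg, lo$rg)
})

test_that("tidiers and plots expose the fitted parameters", {
  t_ <- seq(5, 50, by = 5)
  f <- fit_diffusion(tibble::tibble(lag_s = t_, msd_um2 = 6e-4 * t_ + 1e-3), 50)
  td <- generics::tidy(f)
  expect_equal(td$term, c("D", "b"))
  gl <- generics::glance(f)
  expect_true(all(c("D", "b", "residual_rms") %in% names(gl)))
  a <- fit_anomalous(tibble::tibble(lag_s = seq(5, 100, 5),
                                    msd_um2 = 6e-4 * seq(5, 100, 5)^0.7))
  expect_equal(generics::tidy(a)$term, c("Gamma", "alpha"))
  cfg <- sim_config(n_foci = 20, n_frames = 20, seed = 3)
  m <- compute_msd(truth_tracks(simulate_trajectories(cfg, free_nucleus()),
                                "observed"), 5)
  p <- ggplot2::autoplot(m, fit = f)
  expect_s3_class(p, "ggplot")
})

test_that("bootstrap CIs bracket the point estimate", {
  cfg <- sim_config(n_foci = 100, n_frames = 40, D = 1e-4,
                    loc_noise_sigma = 0.02, seed = 29)
  tk <- truth_tracks(simulate_trajectories(cfg, free_nucleus()), "observed")
  ci <- bootstrap_diffusion(tk, cfg$dt, n_boot = 30, seed = 1)
  expect_true(ci$D_lo <= ci$D && ci$D <= ci$D_hi)
  expect_lt(ci$D_lo, ci$D_hi)
})
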