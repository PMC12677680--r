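# MSD analysis: per-trajectory time-averaged mean-square displacement,
# ensemble averaging with equal weight per trajectory, short-range
# diffusion fit MSD = 6 D t + b over the first 50 s, anomalous fit
# MSD = 6 Gamma t^alpha over the whole curve, and radius of gyration.

#' Compute the ensemble-averaged MSD curve
#'
#' Per trajectory, the time-averaged 3-D MSD at lag `k * dt` is the mean
#' of `|r(t + k dt) - r(t)|^2` over all valid pairs (gaps excluded
#' pairwise). The ensemble curve is the unweighted mean of the
#' per-trajectory curves at each lag; only trajectories covering a lag
#' contribute to it.
#'
#' @param tracks tibble with track_id, frame, z_um, y_um, x_um.
#' @param dt frame interval, seconds.
#' @param max_lag maximum lag in seconds (default: half the longest
#'   trajectory duration).
#' @return An `msd_curve`: tibble with lag_s, msd_um2, n_tracks, n_pairs;
#'   per-trajectory curves in `attr(, "per_track")`.
#' @export
compute_msd <- function(tracks, dt, max_lag = NULL) {
  if (dt <= 0) abort("dt must be > 0")
  if (nrow(tracks) == 0L) abort("no trajectories supplied")
  ids <- unique(tracks$track_id)
  span <- max(tracks$frame) - min(tracks$frame)
  max_k <- if (is.null(max_lag)) max(floor(span / 2), 1L) else max(floor(max_lag / dt), 1L)

  per <- matrix(NA_real_, length(ids), max_k)
  npair <- matrix(0L, length(ids), max_k)
  f0 <- min(tracks$frame)
  zi <- tracks$z_um; yi <- tracks$y_um; xi <- tracks$x_um
  fr <- tracks$frame - f0 + 1L
  id_idx <- match(tracks$track_id, ids)
  nfr <- max(fr)
  for (i in seq_along(ids)) {
    sel <- id_idx == i
    P <- matrix(NA_real_, nfr, 3L)
    P[fr[sel], ] <- cbind(zi[sel], yi[sel], xi[sel])
    have <- !is.na(P[, 1L])
    idxs <- which(have)
    if (length(idxs) < 2L) next
    lo <- min(idxs); hi <- max(idxs)
    for (k in seq_len(min(max_k, hi - lo))) {
      a <- lo:(hi - k)
      d2 <- rowSums((P[a + k, , drop = FALSE] - P[a, , drop = FALSE])^2)
      ok <- !is.na(d2)
      if (any(ok)) {
        per[i, k] <- mean(d2[ok])
        npair[i, k] <- sum(ok)
      }
    }
  }
  msd <- colMeans(per, na.rm = TRUE)
  ntr <- colSums(!is.na(per))
  np <- colSums(npair)
  keep <- ntr > 0L
  out <- tibble(lag_s = (seq_len(max_k) * dt)[keep], msd_um2 = msd[keep],
                n_tracks = ntr[keep], n_pairs = np[keep])
  attr(out, "per_track") <- per
  attr(out, "track_ids") <- ids
  attr(out, "dt") <- dt
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit the short-range diffusion model 6 D t + b
#'
#' Ordinary least squares of the ensemble MSD against lag over lags up to
#' `fit_window` (inclusive; 10 lags at dt = 5 s and the default 50 s
#' window), with D and b constrained non-negative. The bias b absorbs the
#' localization-error floor (about `6 * sigma_loc^2` for isotropic noise).
#'
#' @param curve an [compute_msd()] result, or any tibble with lag_s and
#'   msd_um2.
#' @param fit_window largest lag used, seconds.
#' @return A `diffusion_fit` object: D (um^2/s), b (um^2), fit_window,
#'   residual_rms, n_lags, clipped flag. [tidy()] and [glance()] methods
#'   are provided.
#' @export
fit_diffusion <- function(curve, fit_window = 50) {
  sel <- curve$lag_s <= fit_window + 1e-9
  t_ <- curve$lag_s[sel]; y <- curve$msd_um2[sel]
  if (length(t_) < 3L) abort("need >= 3 lags inside the fit window")
  fit <- lm(y ~ t_)
  D <- unname(coef(fit)[2L]) / 6
  b <- unname(coef(fit)[1L])
  clipped <- FALSE
  if (b < 0) {
    clipped <- TRUE
    b <- 0
    D <- max(sum(t_ * y) / (6 * sum(t_^2)), 0)
  }
  if (D < 0) {
    clipped <- TRUE
    D <- 0
    b <- max(mean(y), 0)
  }
  res <- y - (6 * D * t_ + b)
  structure(list(D = D, b = b, fit_window = fit_window,
                 residual_rms = sqrt(mean(res^2)), n_lags = length(t_),
                 clipped = clipped),
            class = "diffusion_fit")
}

#' Fit the anomalous diffusion model 6 Gamma t^alpha
#'
#' Nonlinear least squares in linear space over the whole curve,
#' initialized from the log-log linear regression; alpha is bounded to
#' (0, 2]. Non-positive MSD values are dropped with a warning. A fitted
#' alpha below 0.9 indicates sub-diffusion ([classify_motion()]).
#'
#' @param curve an [compute_msd()] result.
#' @return An `anomalous_fit` object: Gamma (um^2/s^alpha), alpha,
#'   residual_rms, n_lags.
#' @export
fit_anomalous <- function(curve) {
  t_ <- curve$lag_s; y <- curve$msd_um2
  pos <- y > 0
  if (!all(pos)) {
    warn(sprintf("dropping %d non-positive MSD values", sum(!pos)))
    t_ <- t_[pos]; y <- y[pos]
  }
  if (length(t_) < 5L) abort("need >= 5 positive lags for the anomalous fit")
  ll <- lm(log(y) ~ log(t_))
  a0 <- min(max(unname(coef(ll)[2L]), 0.05), 2)
  g0 <- exp(unname(coef(ll)[1L])) / 6
  df <- data.frame(t_ = t_, y = y)
  fit <- minpack.lm::nlsLM(y ~ 6 * Gamma * t_^alpha, data = df,
                           start = list(Gamma = g0, alpha = a0),
                           lower = c(Gamma = 1e-12, alpha = 1e-6),
                           upper = c(Gamma = Inf, alpha = 2),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  res <- y - 6 * est[["Gamma"]] * t_^est[["alpha"]]
  structure(list(Gamma = est[["Gamma"]], alpha = est[["alpha"]],
                 residual_rms = sqrt(mean(res^2)), n_lags = length(t_)),
            class = "anomalous_fit")
}

#' Classify motion from the anomalous exponent
#'
#' Sub-diffusive when alpha < 0.9 (strict); the boundary itself is not
#' sub-diffusive.
#'
#' @param fit an `anomalous_fit`, or a numeric alpha.
#' @return `"subdiffusive"` or `"normal-or-super"`.
#' @export
classify_motion <- function(fit) {
  alpha <- if (inherits(fit, "anomalous_fit")) fit$alpha else as.numeric(fit)
  if (alpha < 0.9) "subdiffusive" else "normal-or-super"
}

#' Radius of gyration per trajectory
#'
#' `rg = sqrt(mean |r_i - mean(r)|^2)` in 3-D over the points within
#' `duration` seconds of each trajectory's first frame (500 s default).
#' Trajectories with fewer than two points in the window are excluded.
#'
#' @param tracks tibble with track_id, frame, z_um, y_um, x_um.
#' @param dt frame interval, seconds.
#' @param duration window length from the trajectory start, seconds.
#' @return Tibble: track_id, rg_um, n_points, duration_used_s.
#' @export
radius_of_gyration <- function(tracks, dt, duration = 500) {
  if (dt <= 0) abort("dt must be > 0")
  res <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter((.data$frame - min(.data$frame)) * dt <= duration + 1e-9) |>
    dplyr::summarise(
      rg_um = sqrt(mean((.data$z_um - mean(.data$z_um))^2 +
                          (.data$y_um - mean(.data$y_um))^2 +
                          (.data$x_um - mean(.data$x_um))^2)),
      n_points = dplyr::n(),
      duration_used_s = (max(.data$frame) - min(.data$frame)) * dt,
      .groups = "drop")
  dplyr::filter(res, .data$n_points >= 2L)
}

# ---- broom-style methods ---------------------------------------------------

#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(term = c("D", "b"), estimate = c(x$D, x$b),
         unit = c("um^2/s", "um^2"))
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D = x$D, b = x$b, fit_window_s = x$fit_window,
         residual_rms = x$residual_rms, n_lags = x$n_lags,
         clipped = x$clipped)
}

#' @export
tidy.anomalous_fit <- function(x, ...) {
  tibble(term = c("Gamma", "alpha"), estimate = c(x$Gamma, x$alpha),
         unit = c("um^2/s^alpha", ""))
}

#' @export
glance.anomalous_fit <- function(x, ...) {
  tibble(Gamma = x$Gamma, alpha = x$alpha, motion = classify_motion(x),
         residual_rms = x$residual_rms, n_lags = x$n_lags)
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> MSD = 6 D t + b: D = %.4g um^2/s, b = %.4g um^2 (window %g s, rms %.3g)\n",
              x$D, x$b, x$fit_window, x$residual_rms))
  invisible(x)
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat(sprintf("<anomalous_fit> MSD = 6 G t^a: Gamma = %.4g, alpha = %.3f (%s)\n",
              x$Gamma, x$alpha, classify_motion(x)))
  invisible(x)
}

#' Plot an MSD curve
#'
#' @param object an `msd_curve`.
#' @param fit optional `diffusion_fit` or `anomalous_fit` overlay.
#' @param log_axes draw on log-log axes?
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.msd_curve <- function(object, fit = NULL, log_axes = FALSE, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$lag_s, y = .data$msd_um2)) +
    geom_point(size = 1) +
    labs(x = "lag time (s)", y = expression(MSD ~ (mu * m^2))) +
    theme_minimal()
  if (!is.null(fit)) {
    tgrid <- seq(min(object$lag_s), max(object$lag_s), length.out = 200L)
    yhat <- if (inherits(fit, "diffusion_fit")) 6 * fit$D * tgrid + fit$b
    else 6 * fit$Gamma * tgrid^fit$alpha
    p <- p + geom_line(data = tibble(lag_s = tgrid, msd_um2 = yhat),
                       colour = "firebrick")
  }
  if (log_axes) p <- p + scale_x_log10() + scale_y_log10()
  p
}

#' Bootstrap confidence interval for D over trajectories
#'
#' Resamples trajectories with replacement, recomputes the ensemble MSD
#' and the diffusion fit, and reports quantile intervals. The spread is a
#' bootstrap-over-trajectories uncertainty, not a between-cell one.
#'
#' @param tracks tibble of track points.
#' @param dt frame interval, seconds.
#' @param n_boot number of resamples.
#' @param fit_window fit window, seconds.
#' @param level confidence level.
#' @param seed integer seed.
#' @return Tibble: D, D_lo, D_hi, b, n_boot.
#' @export
bootstrap_diffusion <- function(tracks, dt, n_boot = 100L, fit_window = 50,
                                level = 0.95, seed = 1L) {
  set.seed(seed)
  ids <- unique(tracks$track_id)
  base <- fit_diffusion(compute_msd(tracks, dt, max_lag = fit_window), fit_window)
  Ds <- vapply(seq_len(n_boot), function(i) {
    pick <- sample(ids, length(ids), replace = TRUE)
    res <- dplyr::bind_rows(lapply(seq_along(pick), function(j) {
      tr <- tracks[tracks$track_id == pick[j], , drop = FALSE]
      tr$track_id <- j
      tr
    }))
    fit_diffusion(compute_msd(res, dt, max_lag = fit_window), fit_window)$D
  }, numeric(1L))
  qs <- quantile(Ds, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble(D = base$D, D_lo = qs[1L], D_hi = qs[2L], b = base$b, n_boot = n_boot)
}
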