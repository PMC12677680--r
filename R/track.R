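# Trajectory linking: constant-position (random-walk) Kalman prediction
# per live track, gated cost matrix against the frame's detections,
# globally optimal assignment, gap tolerance, and duration filtering.

#' Tracker parameters
#'
#' @param gate_radius maximum allowed link distance between a track's
#'   predicted position and a detection, um.
#' @param max_gap number of consecutive frames a track may survive
#'   without a detection before termination.
#' @param process_noise random-walk motion-model intensity, um^2/s (per
#'   axis position variance grows by `process_noise * dt` per frame).
#' @param measurement_noise detection localization variance, um^2.
#' @param min_steps minimum number of time steps for [filter_by_duration()].
#' @return A `tracker_params` list.
#' @export
tracker_params <- function(gate_radius = 0.5, max_gap = 1L,
                           process_noise = 1e-3, measurement_noise = 1e-3,
                           min_steps = 10L) {
  if (gate_radius <= 0) abort("gate_radius must be > 0")
  if (max_gap < 0) abort("max_gap must be >= 0")
  if (min_steps < 2L) abort("min_steps must be >= 2")
  structure(list(gate_radius = gate_radius, max_gap = as.integer(max_gap),
                 process_noise = process_noise,
                 measurement_noise = measurement_noise,
                 min_steps = as.integer(min_steps)),
            class = "tracker_params")
}

#' Link detections into trajectories
#'
#' Per frame: Kalman-predict every live track under a constant-position
#' random-walk model, build the gated squared-distance cost matrix between
#' predictions and detections, solve the assignment globally (Hungarian
#' method), update matched tracks, age unmatched tracks up to `max_gap`
#' frames, and open new tracks from unmatched detections. Every detection
#' is used at most once per frame; ties are broken by detection order.
#'
#' @param detections tibble with columns frame, z_um, y_um, x_um and
#'   optionally intensity, size_um (as from [detect_movie()]).
#' @param params a [tracker_params()].
#' @param dt frame interval, seconds.
#' @return Tibble of track points: track_id, frame, z_um, y_um, x_um
#'   (+ size_um/intensity when present), ordered by track then frame.
#' @export
track <- function(detections, params = tracker_params(), dt = 5) {
  if (dt <= 0) abort("dt must be > 0")
  cols_extra <- intersect(c("intensity", "size_um", "response"), names(detections))
  if (nrow(detections) == 0L) {
    return(tibble(track_id = integer(), frame = integer(), z_um = numeric(),
                  y_um = numeric(), x_um = numeric()))
  }
  detections <- dplyr::arrange(detections, .data$frame)
  frames <- sort(unique(detections$frame))

  live <- list()      # each: id, pos (3), P (scalar variance), miss, rows
  done <- list()
  next_id <- 1L
  out_rows <- vector("list", 0L)
  q <- params$process_noise * dt
  R <- params$measurement_noise
  gate2 <- params$gate_radius^2
  BIG <- 1e12

  prev_frame <- frames[1L] - 1L
  for (f in frames) {
    gapn <- f - prev_frame    # >= 1; propagate over skipped frames
    det_f <- detections[detections$frame == f, , drop = FALSE]
    Z <- as.matrix(det_f[, c("z_um", "y_um", "x_um")])
    nd <- nrow(det_f)
    nt <- length(live)
    # predict
    for (k in seq_len(nt)) live[[k]]$P <- live[[k]]$P + q * gapn

    assigned_det <- rep(FALSE, nd)
    if (nt > 0L && nd > 0L) {
      pred <- t(vapply(live, function(tr) tr$pos, numeric(3L)))
      cost <- matrix(BIG, nt, nd)
      for (k in seq_len(nt)) {
        d2 <- colSums((t(Z) - pred[k, ])^2)
        ok <- d2 <= gate2
        cost[k, ok] <- d2[ok]
      }
      asg <- solve_assignment(cost)
      for (k in seq_len(nt)) {
        j <- asg[k]
        if (!is.na(j) && cost[k, j] < BIG) {
          # Kalman update (scalar, identical per axis)
          K <- live[[k]]$P / (live[[k]]$P + R)
          live[[k]]$pos <- live[[k]]$pos + K * (Z[j, ] - live[[k]]$pos)
          live[[k]]$P <- (1 - K) * live[[k]]$P
          live[[k]]$miss <- 0L
          live[[k]]$rows <- c(live[[k]]$rows, list(cbind(det_f[j, , drop = FALSE],
                                                         .tid = live[[k]]$id)))
          assigned_det[j] <- TRUE
        } else {
          live[[k]]$miss <- live[[k]]$miss + 1L
        }
      }
    } else if (nt > 0L) {
      for (k in seq_len(nt)) live[[k]]$miss <- live[[k]]$miss + 1L
    }
    # retire tracks that exceeded the gap allowance
    keep <- vapply(live, function(tr) tr$miss <= params$max_gap, logical(1L))
    done <- c(done, live[!keep])
    live <- live[keep]
    # start new tracks from unmatched detections (in detection order)
    for (j in which(!assigned_det)) {
      live[[length(live) + 1L]] <- list(id = next_id, pos = Z[j, ],
                                        P = R, miss = 0L,
                                        rows = list(cbind(det_f[j, , drop = FALSE],
                                                          .tid = next_id)))
      next_id <- next_id + 1L
    }
    prev_frame <- f
  }
  done <- c(done, live)
  if (!length(done)) {
    return(tibble(track_id = integer(), frame = integer(), z_um = numeric(),
                  y_um = numeric(), x_um = numeric()))
  }
  pts <- dplyr::bind_rows(lapply(done, function(tr) dplyr::bind_rows(tr$rows)))
  pts <- dplyr::rename(pts, track_id = ".tid")
  pts <- dplyr::arrange(pts, .data$track_id, .data$frame)
  dplyr::select(pts, "track_id", "frame", "z_um", "y_um", "x_um",
                dplyr::any_of(cols_extra))
}

#' Keep trajectories with a minimum duration
#'
#' Retains tracks spanning at least `min_steps` time steps (number of
#' observed points), matching the rule that only trajectories with a
#' minimum duration of about 50 s (10 steps of 5 s) enter the MSD fits;
#' the 100-step (500 s) preset serves the radius-of-gyration analysis.
#'
#' @param tracks tibble with track_id and frame columns.
#' @param min_steps inclusive minimum number of points per track.
#' @return Filtered tibble, original order preserved.
#' @export
filter_by_duration <- function(tracks, min_steps = 10L) {
  if (min_steps < 2L) abort("min_steps must be >= 2")
  dplyr::filter(dplyr::group_by(tracks, .data$track_id),
                dplyr::n() >= min_steps) |> dplyr::ungroup()
}

#' Split trajectories into small and large by median focus size
#'
#' Per-trajectory size is the median of its detections' size estimates;
#' the split point is the median of those medians, chosen so the two
#' groups differ in count by at most one. Trajectories at the split value
#' go to the small group; ties beyond that break by track id.
#'
#' @param tracks tibble with track_id and size_um columns.
#' @return List with `small` and `large` tibbles of track points, plus a
#'   `sizes` tibble (track_id, size_um, group).
#' @export
split_by_size <- function(tracks) {
  if (!"size_um" %in% names(tracks)) abort("tracks need a size_um column")
  med <- dplyr::summarise(dplyr::group_by(tracks, .data$track_id),
                          size_um = median(.data$size_um, na.rm = TRUE),
                          .groups = "drop")
  if (nrow(med) < 2L) abort("need >= 2 trajectories to split")
  if (length(unique(med$size_um)) == 1L) {
    warn("all trajectory sizes identical: deterministic split by track id")
  }
  med <- dplyr::arrange(med, .data$size_um, .data$track_id)
  n_small <- ceiling(nrow(med) / 2)
  med$group <- rep(c("small", "large"), c(n_small, nrow(med) - n_small))
  small_ids <- med$track_id[med$group == "small"]
  list(small = dplyr::filter(tracks, .data$track_id %in% small_ids),
       large = dplyr::filter(tracks, !.data$track_id %in% small_ids),
       sizes = dplyr::arrange(med, .data$track_id))
}
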