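# Minimum-cost one-to-one assignment (Hungarian method), shortest
# augmenting path formulation with potentials, O(n^2 m). Used both for
# frame-to-frame track linking and for cross-modality focus matching.

#' Solve a minimum-cost assignment problem
#'
#' Finds the one-to-one row-to-column matching of minimum total cost.
#' With more rows than columns (or vice versa) the smaller side is fully
#' matched. Costs must be finite; use a large finite cost to discourage a
#' pairing and filter afterwards.
#'
#' @param cost numeric cost matrix.
#' @return Integer vector of length `nrow(cost)`: assigned column for each
#'   row (`NA` for unmatched rows).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) abort("assignment costs must be finite")
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  transposed <- FALSE
  if (nr > nc) { cost <- t(cost); transposed <- TRUE }
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n); v <- numeric(m)
  p <- integer(m)       # p[j] = row assigned to column j (0 = none)
  way <- integer(m)
  for (i in seq_len(n)) {
    j0 <- 0L            # virtual column holding row i
    minv <- rep(Inf, m)
    used0 <- FALSE      # whether the virtual column is used (always becomes TRUE)
    used <- logical(m)
    i_in_col0 <- i
    repeat {
      if (j0 == 0L) { used0 <- TRUE; i0 <- i_in_col0 } else { used[j0] <- TRUE; i0 <- p[j0] }
      cur <- cost[i0, ] - u[i0] - v
      upd <- !used & cur < minv
      if (any(upd)) { minv[upd] <- cur[upd]; way[upd] <- j0 }
      free <- which(!used)
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      # update potentials over the alternating tree
      u[i_in_col0] <- u[i_in_col0] + delta
      if (any(used)) {
        ju <- which(used)
        u[p[ju]] <- u[p[ju]] + delta
        v[ju] <- v[ju] - delta
      }
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      if (j1 == 0L) { p[j0] <- i; break }
      p[j0] <- p[j1]
      j0 <- j1
    }
  }
  row_of <- p
  assign_rows <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (row_of[j] > 0L) assign_rows[row_of[j]] <- j
  if (!transposed) return(assign_rows)
  # transposed: assign_rows maps original columns -> original rows
  out <- rep(NA_integer_, nc)
  # cost was transposed: rows of t(cost) = original columns
  res <- rep(NA_integer_, max(nr, 1L))
  for (jcol in seq_len(n)) {
    r <- assign_rows[jcol]
    if (!is.na(r)) res[r] <- jcol
  }
  res[seq_len(nr)]
}
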