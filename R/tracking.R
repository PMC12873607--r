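# Frame-to-frame linking of localizations into trajectories: per frame-pair
# globally optimal one-to-one assignment on squared displacement with a hard
# gating radius, plus gap closing over up to max_gaps skipped frames.

# Hungarian algorithm (Jonker-Volgonant style shortest augmenting paths,
# O(n^3)) for a square cost matrix; returns, for each row, the assigned
# column. No LSAP solver ships with the environment's packages, so this is
# implemented here and unit-tested against brute-force enumeration.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer())
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

# Maximum-cardinality minimum-cost matching between two point sets under a
# gating radius: the gated cost matrix is padded to square with a large
# constant, so minimizing total cost first maximizes the number of
# admissible links, then minimizes their summed squared displacement.
# Returns an integer vector over rows of `a`: index into `b` or NA.
match_points <- function(ax, ay, bx, by, r_max) {
  na <- length(ax); nb <- length(bx)
  if (na == 0L || nb == 0L) return(rep(NA_integer_, na))
  d2 <- outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2
  BIG <- max(r_max^2 * 4, 1) * (na + nb) * 1e6
  d2[d2 > r_max^2] <- BIG
  n <- max(na, nb)
  cost <- matrix(BIG, n, n)
  cost[seq_len(na), seq_len(nb)] <- d2
  asg <- hungarian_assign(cost)
  out <- rep(NA_integer_, na)
  for (i in seq_len(na)) {
    j <- asg[i]
    if (j <= nb && d2[i, j] < BIG) out[i] <- j
  }
  out
}

#' Link localizations into trajectories
#'
#' Builds trajectories by optimal one-to-one assignment per frame pair
#' (minimum summed squared displacement, Hungarian algorithm) with a hard
#' gating radius `r_max(k) = sqrt(4 * d_max_expected * k * frame_interval)
#' * safety_factor` for links spanning `k` frames. Gap closing is greedy
#' over the span: at each frame, 1-frame links are made first, then
#' detections still unassigned may be claimed by tracks that ended 2, then
#' 3, ... frames earlier (up to `max_gaps` skipped frames). Unlinked
#' detections start new trajectories.
#'
#' @param locs Localization data.frame (`frame`, `x_um`, `y_um`, optional
#'   extra columns carried through), sorted by frame.
#' @param cfg A [linking_config()].
#' @return Trajectory data.frame: the input columns plus `trajectory_id`
#'   (assigned in order of track creation).
#' @export
link_localizations <- function(locs, cfg) {
  stopifnot(inherits(cfg, "linking_config"))
  req <- c("frame", "x_um", "y_um")
  miss <- setdiff(req, names(locs))
  if (length(miss)) stopf("localization table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!nrow(locs)) {
    out <- locs
    out$trajectory_id <- integer()
    return(out)
  }
  if (is.unsorted(locs$frame)) stopf("localizations must be sorted by frame")

  frames <- sort(unique(locs$frame))
  by_frame <- split(seq_len(nrow(locs)), locs$frame)
  traj_of <- rep(NA_integer_, nrow(locs))
  # active track registry: last row index per track
  track_last <- integer(0)
  next_id <- 1L
  max_span <- cfg$max_gaps + 1L
  r_of_k <- function(k) sqrt(4 * cfg$d_max_expected * k * cfg$frame_interval) *
    cfg$safety_factor

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- by_frame[[as.character(f)]]
    unassigned <- rows
    if (length(track_last)) {
      for (k in seq_len(max_span)) {
        if (!length(unassigned)) break
        ends <- which(locs$frame[track_last] == f - k)
        if (!length(ends)) next
        erows <- track_last[ends]
        m <- match_points(locs$x_um[erows], locs$y_um[erows],
                          locs$x_um[unassigned], locs$y_um[unassigned],
                          r_of_k(k))
        linked <- which(!is.na(m))
        for (ii in linked) {
          row_new <- unassigned[m[ii]]
          traj_of[row_new] <- traj_of[erows[ii]]
          track_last[ends[ii]] <- row_new
        }
        if (length(linked)) unassigned <- unassigned[-m[linked]]
      }
    }
    for (r in unassigned) {
      traj_of[r] <- next_id
      track_last <- c(track_last, r)
      next_id <- next_id + 1L
    }
    # drop tracks too old to ever be extended
    keep <- locs$frame[track_last] >= f - max_span + 1L
    track_last <- track_last[keep]
  }
  out <- locs
  out$trajectory_id <- traj_of
  out <- out[order(out$trajectory_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics of a trajectory set
#'
#' @param trajs Trajectory data.frame (`trajectory_id`, `frame`), or an
#'   `spt_dataset`.
#' @param n_timepoints Number of time gaps for the per-gap jump counts.
#' @return A list: `n_trajectories`, `n_localizations`, `median_length`,
#'   `mean_length`, `length_table` (track length distribution) and
#'   `jumps_per_gap` (valid gap-free jumps available at each time gap,
#'   uncapped).
#' @export
trajectory_stats <- function(trajs, n_timepoints = 7L) {
  if (inherits(trajs, "spt_dataset")) trajs <- trajs$trajectories
  if (!nrow(trajs)) {
    return(list(n_trajectories = 0L, n_localizations = 0L,
                median_length = 0, mean_length = 0,
                length_table = table(integer()),
                jumps_per_gap = setNames(integer(n_timepoints),
                                         paste0("k", seq_len(n_timepoints)))))
  }
  DT <- data.table::as.data.table(trajs[, c("trajectory_id", "frame")])
  data.table::setorder(DT, trajectory_id, frame)
  lens <- DT[, .N, by = "trajectory_id"]$N
  jumps <- integer(n_timepoints)
  for (k in seq_len(n_timepoints)) {
    f2 <- DT[, data.table::shift(frame, k, type = "lead"), by = "trajectory_id"]$V1
    jumps[k] <- sum(!is.na(f2) & (f2 - DT$frame) == k)
  }
  list(n_trajectories = length(lens),
       n_localizations = nrow(DT),
       median_length = median(lens),
       mean_length = mean(lens),
       length_table = table(lens),
       jumps_per_gap = setNames(jumps, paste0("k", seq_len(n_timepoints))))
}
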