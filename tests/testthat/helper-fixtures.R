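# Shared fixtures and independent oracles used across the suite.

default_model <- function(...) ground_truth_model(...)

default_acq <- function(...) acquisition_config(...)

# Closed-form per-bin mass of the 2D jump-length (Rayleigh) distribution
# with per-axis variance 2 * v: independent oracle for model_jump_pdf.
rayleigh_bin_mass <- function(breaks, v) {
  exp(-breaks[-length(breaks)]^2 / (4 * v)) - exp(-breaks[-1]^2 / (4 * v))
}

# Brute-force minimum-cost assignment by permutation enumeration.
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf; best_p <- NULL
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) { best <- s; best_p <- p }
  }
  list(cost = best, assignment = best_p)
}

# Exhaustive enumeration of admissible jumps for one trajectory: all pairs
# of observations k frames apart with every intermediate frame present,
# first `cap` by start frame. Oracle for compile_jump_histograms.
enumerate_jumps <- function(frames, x, y, k, cap = 4L) {
  out <- numeric(0)
  starts <- sort(frames)
  for (f in starts) {
    i <- match(f, frames); j <- match(f + k, frames)
    if (is.na(j)) next
    if (!all((f + seq_len(k - 1)) %in% frames) && k > 1) next
    out <- c(out, sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2))
    if (length(out) >= cap) break
  }
  out
}

# Simulated localizations on a sparse jittered grid, optionally with frames
# removed from chosen particles, for tracking tests. Nearest-neighbor
# spacing is >= sep_factor times the 1-frame gating radius.
sparse_grid_locs <- function(n_cols = 10, n_rows = 4, n_frames = 12,
                             cfg = linking_config(), sep_factor = 5,
                             jitter_sd_frac = 1 / 8, seed = 1,
                             drop = list()) {
  r1 <- sqrt(4 * cfg$d_max_expected * cfg$frame_interval) * cfg$safety_factor
  n <- n_cols * n_rows
  gx <- rep(seq_len(n_cols) - 1, n_rows) * sep_factor * r1
  gy <- rep(seq_len(n_rows) - 1, each = n_cols) * sep_factor * r1
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_frames), function(f)
      data.frame(tid = seq_len(n), frame = f - 1L,
                 x_um = gx + rnorm(n, 0, r1 * jitter_sd_frac),
                 y_um = gy + rnorm(n, 0, r1 * jitter_sd_frac))))
  })
  for (d in drop) rows <- rows[!(rows$tid == d$tid & rows$frame %in% d$frames), ]
  rows[order(rows$frame, rows$tid), ]
}

# Ground-truth purity of a linking result against the tid column of
# sparse_grid_locs output: every output trajectory must contain exactly one
# true particle and every true segment must map to one trajectory.
linking_matches_truth <- function(truth_rows, linked) {
  key <- paste(linked$frame, signif(linked$x_um, 12))
  tkey <- paste(truth_rows$frame, signif(truth_rows$x_um, 12))
  tid <- truth_rows$tid[match(key, tkey)]
  pure <- all(vapply(split(tid, linked$trajectory_id),
                     function(v) length(unique(v)) == 1L, logical(1)))
  list(pure = pure, n_tracks = length(unique(linked$trajectory_id)))
}

# One simulated cell fitted end to end; returns the fitted bound fraction.
fit_cell_F_bound <- function(model, acq, cfg, n_traj, seed) {
  d <- simulate_trajectories(model, acq, n_traj, seed = seed)
  h <- compile_jump_histograms(d$trajectories, cfg)
  fit_kinetic_model(h, cfg)$fractions[["bound"]]
}
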