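# Ground-truth trajectory simulation and movie rendering, plus a Monte-Carlo
# oracle for axial (defocalization) survival.

# Brownian-bridge probability that a 1D path from z1 to z2 over a step with
# variance s2 = 2*D*dt crossed either absorbing plane at +/- h, given both
# endpoints inside. Single-barrier bridge formula per plane; double-crossing
# terms are negligible when sqrt(s2) << 2h, which holds for the sub-steps
# used here.
bridge_cross_prob <- function(z1, z2, h, s2) {
  p <- exp(-2 * (h - z1) * (h - z2) / s2) + exp(-2 * (h + z1) * (h + z2) / s2)
  pmin(p, 1)
}

#' Simulate single-molecule trajectories
#'
#' Samples molecules from a static state mixture (or a Markov-switching
#' variant), propagates 3D Brownian motion at the frame interval, censors
#' the observed record when the molecule leaves the axial detection slice
#' or photobleaches, and adds isotropic Gaussian localization error to the
#' observed x, y positions. Only x and y are reported; z is simulated solely
#' to reproduce defocalization bias.
#'
#' @param model A [ground_truth_model()].
#' @param acq An [acquisition_config()].
#' @param n_trajectories Number of molecules to simulate.
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @param cell_id Cell label stored with every row.
#' @param n_frames Optional movie length; when given, trajectory start
#'   frames are staggered uniformly over the movie and clipped to it,
#'   otherwise all trajectories start at frame 0.
#' @return An object of class `spt_dataset`: a list with `trajectories`
#'   (data.frame: `trajectory_id`, `frame`, `x_um`, `y_um`, `cell_id`,
#'   `true_state`, plus noise-free `x_true_um`, `y_true_um` used for
#'   rendering), `ground_truth`, `acq`, and `seed`.
#' @export
#' @examples
#' d <- simulate_trajectories(ground_truth_model(), acquisition_config(),
#'                            n_trajectories = 50, seed = 1)
#' head(d$trajectories)
simulate_trajectories <- function(model, acq, n_trajectories, seed,
                                  cell_id = "cell_1", n_frames = NULL) {
  stopifnot(inherits(model, "ground_truth_model"), inherits(acq, "acquisition_config"))
  if (!is_count(n_trajectories)) stopf("n_trajectories must be a non-negative integer")
  n <- as.integer(n_trajectories)
  empty <- data.frame(trajectory_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      cell_id = character(), true_state = character(),
                      x_true_um = numeric(), y_true_um = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(trajectories = empty, ground_truth = model,
                          acq = acq, seed = seed), class = "spt_dataset"))
  }
  dt <- acq$frame_interval
  h <- acq$dz / 2
  states <- c("bound", "free1", "free2")

  with_seed(seed, {
    st <- sample.int(3L, n, replace = TRUE, prob = model$state_fractions)
    # photobleaching-limited length in frames (support >= 1, geometric mean)
    p_bleach <- 1 / model$track_length_mean
    len_bleach <- rgeom(n, p_bleach) + 1L
    max_len <- max(len_bleach)
    start <- if (is.null(n_frames)) rep(0L, n) else
      sample.int(as.integer(n_frames), n, replace = TRUE) - 1L

    fov_um <- acq$fov_px * acq$pixel_size
    X <- matrix(NA_real_, n, max_len)
    Y <- matrix(NA_real_, n, max_len)
    S <- matrix(NA_integer_, n, max_len)
    X[, 1] <- runif(n, 0, fov_um[1])
    Y[, 1] <- runif(n, 0, fov_um[2])
    S[, 1] <- st
    z <- if (is.finite(h)) runif(n, -h, h) else numeric(n)
    exit_len <- rep.int(max_len, n)  # observed frames permitted by axial exit
    alive <- rep.int(TRUE, n)

    # Markov switching (optional stress-test mode): first-order transition
    # probabilities rate * dt per frame.
    P_switch <- NULL
    if (!is.null(model$switching_rates)) {
      P_switch <- model$switching_rates * dt
      diag(P_switch) <- 0
      diag(P_switch) <- pmax(0, 1 - rowSums(P_switch))
      P_switch <- P_switch / rowSums(P_switch)
    }

    n_sub <- acq$n_substeps
    dt_sub <- dt / n_sub
    if (max_len > 1L) for (f in 2:max_len) {
      if (!is.null(P_switch)) {
        u <- runif(n)
        cum <- t(apply(P_switch, 1, cumsum))
        prev <- S[, f - 1L]
        nxt <- 1L + (u > cum[prev, 1]) + (u > cum[prev, 2])
        S[, f] <- as.integer(nxt)
      } else {
        S[, f] <- st
      }
      D <- model$diffusion_coeffs[S[, f]]
      sd_xy <- sqrt(2 * D * dt)
      X[, f] <- X[, f - 1L] + rnorm(n) * sd_xy
      Y[, f] <- Y[, f - 1L] + rnorm(n) * sd_xy
      if (is.finite(h)) {
        s2_sub <- 2 * D * dt_sub
        sd_sub <- sqrt(s2_sub)
        for (s in seq_len(n_sub)) {
          z_new <- z + rnorm(n) * sd_sub
          crossed <- abs(z_new) >= h
          inside <- !crossed & s2_sub > 0
          pb <- numeric(n)
          pb[inside] <- bridge_cross_prob(z[inside], z_new[inside], h, s2_sub[inside])
          crossed <- crossed | (runif(n) < pb)
          newly <- alive & crossed
          if (any(newly)) {
            exit_len[newly] <- f - 1L  # exited during frame f: last good frame f-1
            alive[newly] <- FALSE
          }
          z <- z_new
        }
      }
    }

    len_obs <- pmin(len_bleach, exit_len)
    if (!is.null(n_frames)) len_obs <- pmin(len_obs, as.integer(n_frames) - start)
    keep <- len_obs >= 1L
    idx_traj <- rep(seq_len(n)[keep], len_obs[keep])
    idx_col <- sequence(len_obs[keep])
    ij <- cbind(idx_traj, idx_col)
    m <- length(idx_traj)
    out <- data.frame(
      trajectory_id = idx_traj,
      frame = start[idx_traj] + idx_col - 1L,
      x_um = X[ij] + rnorm(m, 0, model$sigma_loc),
      y_um = Y[ij] + rnorm(m, 0, model$sigma_loc),
      cell_id = rep.int(cell_id, m),
      true_state = states[S[ij]],
      x_true_um = X[ij],
      y_true_um = Y[ij],
      stringsAsFactors = FALSE
    )
  })
  structure(list(trajectories = out, ground_truth = model, acq = acq, seed = seed),
            class = "spt_dataset")
}

#' Render a movie from simulated trajectories
#'
#' Draws every in-focus molecule as a pixel-integrated 2D Gaussian of width
#' `psf_sigma` and integrated intensity `photon_budget` on a constant
#' background, then applies Poisson shot noise. Noise-free ground-truth
#' positions are used, so localization error in the rendered data arises
#' from photon statistics alone.
#'
#' @param dataset An `spt_dataset` from [simulate_trajectories()], or a
#'   trajectory data.frame carrying `x_true_um`/`y_true_um` (falls back to
#'   `x_um`/`y_um`).
#' @param acq An [acquisition_config()].
#' @param seed Integer seed for the shot noise.
#' @param n_frames Number of frames; defaults to `max(frame) + 1`.
#' @return A numeric array `[ny, nx, n_frames]` of photon counts, class
#'   `spt_movie`.
#' @export
render_movie <- function(dataset, acq, seed, n_frames = NULL) {
  stopifnot(inherits(acq, "acquisition_config"))
  trajs <- if (inherits(dataset, "spt_dataset")) dataset$trajectories else dataset
  xs <- if ("x_true_um" %in% names(trajs)) trajs$x_true_um else trajs$x_um
  ys <- if ("y_true_um" %in% names(trajs)) trajs$y_true_um else trajs$y_um
  nx <- acq$fov_px[1]; ny <- acq$fov_px[2]
  px <- acq$pixel_size
  if (is.null(n_frames))
    n_frames <- if (nrow(trajs)) max(trajs$frame) + 1L else 1L
  fov_um <- c(nx, ny) * px
  outside <- xs < 0 | xs > fov_um[1] | ys < 0 | ys > fov_um[2]
  if (any(outside))
    warnf("%d spot positions outside the field of view were clipped", sum(outside))

  sig <- acq$psf_sigma
  half <- ceiling(4 * sig)
  stack <- array(acq$background, dim = c(ny, nx, n_frames))
  if (nrow(trajs)) {
    xp <- xs / px  # pixel-edge units: pixel j spans [j-1, j]
    yp <- ys / px
    for (r in seq_len(nrow(trajs))) {
      f <- trajs$frame[r] + 1L
      if (f < 1L || f > n_frames) next
      jc <- floor(xp[r]) + 1L
      ic <- floor(yp[r]) + 1L
      js <- max(1L, jc - half):min(nx, jc + half)
      is <- max(1L, ic - half):min(ny, ic + half)
      if (!length(js) || !length(is)) next
      colmass <- pnorm((js - xp[r]) / sig) - pnorm((js - 1 - xp[r]) / sig)
      rowmass <- pnorm((is - yp[r]) / sig) - pnorm((is - 1 - yp[r]) / sig)
      stack[is, js, f] <- stack[is, js, f] +
        acq$photon_budget * (rowmass %o% colmass)
    }
  }
  with_seed(seed, {
    stack[] <- rpois(length(stack), stack)
  })
  class(stack) <- c("spt_movie", class(stack))
  stack
}

#' Monte-Carlo axial survival probability
#'
#' Brute-force estimate of the probability that a molecule with diffusion
#' coefficient `D`, started uniformly inside an axial slice of thickness
#' `dz`, never crosses either slice boundary during `[0, t]`. Walkers are
#' propagated over `n_substeps` intermediate times; between checkpoints the
#' exact Brownian-bridge crossing probability is applied, so the estimator
#' targets the continuous never-cross probability rather than its
#' discretely monitored (upward-biased) counterpart. Set `bridge = FALSE`
#' for plain discrete monitoring.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param t Time, s.
#' @param dz Slice thickness, um.
#' @param n_walkers Number of walkers.
#' @param n_substeps Number of intermediate checkpoints.
#' @param seed Integer seed.
#' @param bridge Apply Brownian-bridge crossing corrections (default TRUE).
#' @return A list with `p` (survival probability), `se` (binomial standard
#'   error), `n_walkers`.
#' @export
#' @examples
#' mc_axial_survival(D = 1, t = 0.01, dz = 0.7,
#'                   n_walkers = 1e4, n_substeps = 50, seed = 1)$p
mc_axial_survival <- function(D, t, dz, n_walkers, n_substeps, seed, bridge = TRUE) {
  if (!is_number(D) || D < 0) stopf("D must be >= 0")
  if (!is_number(t) || t <= 0) stopf("t must be > 0")
  if (!(is_number(dz) || identical(dz, Inf)) || dz <= 0) stopf("dz must be > 0")
  if (!is_count(n_walkers) || n_walkers < 1) stopf("n_walkers must be a positive integer")
  if (!is_count(n_substeps) || n_substeps < 1) stopf("n_substeps must be a positive integer")
  n <- as.integer(n_walkers)
  if (D == 0 || !is.finite(dz)) {
    return(list(p = 1, se = 0, n_walkers = n))
  }
  h <- dz / 2
  dt <- t / n_substeps
  s2 <- 2 * D * dt
  sdv <- sqrt(s2)
  surv <- with_seed(seed, {
    z <- runif(n, -h, h)
    for (s in seq_len(n_substeps)) {
      if (!length(z)) break
      z_new <- z + rnorm(length(z)) * sdv
      ok <- abs(z_new) < h
      if (bridge) {
        pb <- bridge_cross_prob(z, z_new, h, s2)
        ok <- ok & (runif(length(z)) >= pb)
      }
      z <- z_new[ok]
    }
    length(z)
  })
  p <- surv / n
  list(p = p, se = sqrt(p * (1 - p) / n), n_walkers = n)
}
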