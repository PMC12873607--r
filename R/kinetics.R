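# Jump-length histogram compilation and two-/three-state kinetic model
# fitting with localization error and axial defocalization correction.
#
# Model: for a state with diffusion coefficient D observed over a time gap
# tau with per-axis localization error sigma, the 2D jump length r is
# Rayleigh with per-axis variance 2*(D*tau + sigma^2):
#   p(r) = r / (2*(D*tau + sigma^2)) * exp(-r^2 / (4*(D*tau + sigma^2)))
# The per-bin mass has the closed form
#   exp(-a^2/(4v)) - exp(-b^2/(4v)),  v = D*tau + sigma^2
# for a bin [a, b). Mixture weights are corrected for defocalization (fast
# molecules leaving the axial detection slice between frames) and the
# mixture is renormalized over the histogram range at each time gap, to
# match the per-gap-normalized empirical densities.

# Survival eigenseries for an absorbing slab, averaged over a uniform start:
#   S(x) = sum_{n odd} 8/(n^2 pi^2) exp(-n^2 pi^2 x),  x = D*t/dz^2.
# Truncated when terms fall below 1e-10; a short-time expansion
# S ~= 1 - 4*sqrt(x/pi) replaces the series where it would need >6000 terms.
axial_survival_x <- function(x) {
  out <- numeric(length(x))        # x = Inf stays 0: nothing survives
  out[x <= 0] <- 1
  small <- x > 0 & x < 1e-7
  out[small] <- 1 - 4 * sqrt(x[small] / pi)
  main <- is.finite(x) & x >= 1e-7
  if (any(main)) {
    xm <- x[main]
    # largest odd n with 8/(n^2 pi^2) exp(-n^2 pi^2 x_min) > 1e-10
    nmax <- ceiling(sqrt(24 / (pi^2 * min(xm))))
    ns <- seq(1, max(3, nmax), by = 2)
    terms <- exp(-outer(xm, ns^2 * pi^2))
    out[main] <- pmin(as.numeric(terms %*% (8 / (pi^2 * ns^2))), 1)
  }
  out
}

#' Axial (defocalization) survival probability
#'
#' Probability that a molecule with diffusion coefficient `D`, started
#' uniformly inside an axial detection slice of thickness `dz`, has not
#' crossed either slice boundary by time `t`. Computed from the
#' absorbing-boundary eigenfunction series averaged over the start depth,
#' truncated when terms fall below 1e-10. This is the correction factor by
#' which fast-diffusing states are under-represented in jump histograms.
#'
#' @param D Diffusion coefficient, um^2/s (vectorized).
#' @param t Time, s (vectorized).
#' @param dz Slice thickness, um; `Inf` gives 1.
#' @return Survival probability in `[0, 1]`; exactly 1 for `D = 0`.
#' @export
#' @examples
#' axial_survival_probability(2.0, 0.01, 0.7)
axial_survival_probability <- function(D, t, dz) {
  if (any(D < 0)) stopf("D must be >= 0")
  if (any(t <= 0)) stopf("t must be > 0")
  if (any(dz <= 0)) stopf("dz must be > 0")
  if (all(!is.finite(dz))) return(rep(1, max(length(D), length(t))))
  x <- D * t / dz^2
  x[!is.finite(dz) | D == 0] <- 0
  axial_survival_x(x)
}

#' Compile jump-length histograms
#'
#' Collects 2D displacements between observations `k` frames apart for
#' `k = 1..n_timepoints`, using at most `jumps_per_trajectory` jumps per
#' trajectory per gap (the first ones by start frame). Displacements that
#' span recorded gaps (missing intermediate frames) are excluded, so every
#' jump at gap `k` covers exactly `k` contiguous frame intervals.
#'
#' @param trajs Trajectory data.frame (`trajectory_id`, `frame`, `x_um`,
#'   `y_um`) or an `spt_dataset`.
#' @param cfg A [fit_config()] supplying `frame_interval`, `n_timepoints`,
#'   `bin_width`, `r_max` and `jumps_per_trajectory`.
#' @return An object of class `jump_histogram`: bin geometry, per-gap
#'   counts and normalized densities (`sum(density) * bin_width = 1`),
#'   per-gap jump totals, the per-frame track-survival estimate `q_hat`
#'   used by the age-averaged defocalization correction, and bookkeeping.
#' @export
compile_jump_histograms <- function(trajs, cfg) {
  stopifnot(inherits(cfg, "fit_config"))
  if (inherits(trajs, "spt_dataset")) trajs <- trajs$trajectories
  req <- c("trajectory_id", "frame", "x_um", "y_um")
  miss <- setdiff(req, names(trajs))
  if (length(miss)) stopf("trajectory table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  K <- cfg$n_timepoints
  breaks <- seq(0, cfg$r_max, by = cfg$bin_width)
  if (abs(breaks[length(breaks)] - cfg$r_max) > 1e-12)
    breaks <- c(breaks, cfg$r_max)
  nbin <- length(breaks) - 1L
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- matrix(0L, nbin, K)
  n_jumps <- integer(K)
  n_traj <- 0L
  q_hat <- 0
  if (nrow(trajs)) {
    DT <- data.table::as.data.table(trajs[, req])
    data.table::setorder(DT, trajectory_id, frame)
    lens <- DT[, .N, by = "trajectory_id"]$N
    n_traj <- length(lens)
    q_hat <- max(0, 1 - 1 / mean(lens))
    for (k in seq_len(K)) {
      x2 <- DT[, data.table::shift(x_um, k, type = "lead"), by = "trajectory_id"]$V1
      y2 <- DT[, data.table::shift(y_um, k, type = "lead"), by = "trajectory_id"]$V1
      f2 <- DT[, data.table::shift(frame, k, type = "lead"), by = "trajectory_id"]$V1
      valid <- !is.na(f2) & (f2 - DT$frame) == k
      DT[, v_ := valid]
      vrank <- DT[, cumsum(v_), by = "trajectory_id"]$V1
      use <- valid & vrank <= cfg$jumps_per_trajectory
      r <- sqrt((x2[use] - DT$x_um[use])^2 + (y2[use] - DT$y_um[use])^2)
      r <- r[r < cfg$r_max]
      n_jumps[k] <- length(r)
      if (length(r))
        counts[, k] <- tabulate(findInterval(r, breaks, left.open = FALSE,
                                             rightmost.closed = FALSE), nbin)
    }
  }
  density <- counts
  storage.mode(density) <- "double"
  for (k in seq_len(K)) {
    density[, k] <- if (n_jumps[k] > 0)
      counts[, k] / (n_jumps[k] * cfg$bin_width) else NA_real_
  }
  structure(list(
    breaks = breaks, centers = centers, bin_width = cfg$bin_width,
    counts = counts, density = density, n_jumps = n_jumps,
    dt_gaps = seq_len(K) * cfg$frame_interval,
    frame_interval = cfg$frame_interval,
    jumps_per_trajectory = cfg$jumps_per_trajectory,
    q_hat = q_hat, n_trajectories = n_traj
  ), class = "jump_histogram")
}

# Defocalization weight of one state at every time gap. mode "age" averages
# the never-cross survival over the admissible jump start ages j = 0 ..
# cap-1 (a jump over gap tau starting at track age j requires in-slice
# survival over j*frame_dt + tau), weighted by the per-frame
# photobleaching survival q.
defocal_weights <- function(D, dt_gaps, frame_dt, dz, mode, cap, q) {
  K <- length(dt_gaps)
  if (mode == "none" || !is.finite(dz) || D == 0) return(rep(1, K))
  if (mode == "single") return(axial_survival_probability(D, dt_gaps, dz))
  ages <- 0:(cap - 1L)
  w <- q^ages
  tt <- as.numeric(outer(ages * frame_dt, dt_gaps, `+`))  # cap x K
  S <- matrix(axial_survival_probability(D, tt, dz), nrow = cap)
  as.numeric(crossprod(S, w)) / sum(w)
}

# Per-gap model bin masses for a candidate parameter set; returns an
# nbin x K matrix whose columns each sum to 1 over the histogram range.
model_bin_mass <- function(breaks, F, D, sigma, dt_gaps, cfg, q) {
  K <- length(dt_gaps)
  nbin <- length(breaks) - 1L
  W <- vapply(seq_along(D), function(s) {
    F[s] * defocal_weights(D[s], dt_gaps, cfg$frame_interval, cfg$dz,
                           cfg$defocalization, cfg$jumps_per_trajectory, q)
  }, numeric(K))
  W <- matrix(W, nrow = K)             # K x n_states
  out <- matrix(0, nbin, K)
  for (k in seq_len(K)) {
    v <- D * dt_gaps[k] + sigma^2
    cdf <- function(r) 1 - exp(-r^2 / (4 * v))  # length n_states per r
    mass <- vapply(seq_along(D), function(s) {
      exp(-breaks[-length(breaks)]^2 / (4 * v[s])) - exp(-breaks[-1]^2 / (4 * v[s]))
    }, numeric(nbin))                  # nbin x n_states
    tot <- cdf(breaks[length(breaks)])
    num <- mass %*% W[k, ]
    den <- sum(W[k, ] * tot)
    out[, k] <- num / den
  }
  out
}

#' Model jump-length density at one time gap
#'
#' Evaluates the (two- or three-state) mixture density over histogram bins
#' at a single time gap, including the localization-error inflation of the
#' jump variance and the defocalization re-weighting of the free states,
#' renormalized so that `sum(density) * bin_width = 1` over the histogram
#' range.
#'
#' @param bin_centers Uniformly spaced bin centers, um.
#' @param fit List with `F` (state fractions), `D` (diffusion
#'   coefficients, um^2/s) and `sigma` (localization error, um), ordered
#'   slowest state first.
#' @param dt_gap Time gap, s.
#' @param cfg A [fit_config()] (supplies `dz`, the defocalization mode and
#'   the jump cap).
#' @param q Per-frame track survival used by the age-averaged correction
#'   (default 1: no photobleaching weighting).
#' @return Density per bin (1/um).
#' @export
#' @examples
#' cfg <- fit_config(dz = Inf)
#' ctr <- seq(0.005, 1.195, by = 0.01)
#' d <- model_jump_pdf(ctr, list(F = c(0, 0, 1), D = c(0.001, 0.1, 1),
#'                               sigma = 0), dt_gap = 0.01, cfg = cfg)
#' sum(d) * 0.01
model_jump_pdf <- function(bin_centers, fit, dt_gap, cfg, q = 1) {
  stopifnot(inherits(cfg, "fit_config"))
  if (any(fit$D < 0)) stopf("negative diffusion coefficients are not allowed")
  if (fit$sigma < 0) stopf("sigma must be >= 0")
  if (length(fit$F) != length(fit$D)) stopf("F and D must have equal length")
  bw <- diff(bin_centers)
  if (length(bw) && diff(range(bw)) > 1e-9) stopf("bin_centers must be uniform")
  bw <- if (length(bw)) bw[1] else cfg$bin_width
  breaks <- c(bin_centers - bw / 2, bin_centers[length(bin_centers)] + bw / 2)
  mass <- model_bin_mass(breaks, fit$F, fit$D, fit$sigma, dt_gap, cfg, q)
  as.numeric(mass[, 1] / bw)
}

# Map optimizer parameters to (F, D, sigma). Fractions use stick-breaking
# (p1 = F_bound, p2 = F_free1 / (1 - F_bound)) so they sum to 1 by
# construction for any p1, p2 in [0, 1].
par_to_fit <- function(par, cfg) {
  ns <- cfg$n_states
  if (ns == 3L) {
    F <- c(par[1], (1 - par[1]) * par[2], (1 - par[1]) * (1 - par[2]))
    D <- par[3:5]
    sigma <- if (cfg$sigma_mode == "fit") par[6] else cfg$sigma_fixed
  } else {
    F <- c(par[1], 1 - par[1])
    D <- par[2:3]
    sigma <- if (cfg$sigma_mode == "fit") par[4] else cfg$sigma_fixed
  }
  list(F = F, D = D, sigma = sigma)
}

fit_par_bounds <- function(cfg) {
  lo <- vapply(cfg$d_bounds, `[`, numeric(1), 1L)
  hi <- vapply(cfg$d_bounds, `[`, numeric(1), 2L)
  nfrac <- cfg$n_states - 1L
  lower <- c(rep(0, nfrac), lo)
  upper <- c(rep(1, nfrac), hi)
  if (cfg$sigma_mode == "fit") {
    lower <- c(lower, cfg$sigma_bounds[1])
    upper <- c(upper, cfg$sigma_bounds[2])
  }
  list(lower = lower, upper = upper)
}

#' Fit the jump-length kinetic model
#'
#' Bounded least squares of the mixture model against the per-gap
#' normalized jump histograms, simultaneously over all non-empty time gaps,
#' with seeded random restarts. Fractions are parameterized to sum to 1 by
#' construction and every diffusion coefficient is constrained to its
#' configured interval.
#'
#' @param hist A [compile_jump_histograms()] result.
#' @param cfg A [fit_config()].
#' @return An object of class `kinetic_fit`: state fractions (`F_bound`,
#'   `F_free1`, `F_free2` for 3 states; `F_bound`, `F_free` for 2),
#'   diffusion coefficients, `sigma`, `residual` (sum of squared density
#'   errors), `n_jumps_used`, `converged`, plus the fitted per-gap model
#'   densities and a config echo.
#' @export
fit_kinetic_model <- function(hist, cfg) {
  stopifnot(inherits(hist, "jump_histogram"), inherits(cfg, "fit_config"))
  use_k <- which(hist$n_jumps > 0)
  if (!length(use_k)) stopf("no time gap has any jumps; nothing to fit")
  total <- sum(hist$n_jumps[use_k])
  if (total < cfg$min_jumps)
    stopf("only %d jumps available; at least %d required for a stable fit",
          total, cfg$min_jumps)
  K_all <- length(hist$dt_gaps)
  emp <- hist$density[, use_k, drop = FALSE]
  emp_cdf <- apply(hist$counts[, use_k, drop = FALSE], 2,
                   function(cc) cumsum(cc) / sum(cc))
  bw <- hist$bin_width
  q <- hist$q_hat

  resid_fn <- function(par) {
    f <- par_to_fit(par, cfg)
    mass <- model_bin_mass(hist$breaks, f$F, f$D, f$sigma,
                           hist$dt_gaps, cfg, q)[, use_k, drop = FALSE]
    if (cfg$objective == "pdf") as.numeric(mass / bw - emp)
    else as.numeric(apply(mass, 2, cumsum) - emp_cdf)
  }

  b <- fit_par_bounds(cfg)
  npar <- length(b$lower)
  nfrac <- cfg$n_states - 1L
  d_lo <- vapply(cfg$d_bounds, `[`, numeric(1), 1L)
  d_hi <- vapply(cfg$d_bounds, `[`, numeric(1), 2L)
  d_mid <- sqrt(d_lo * d_hi)
  sig0 <- if (cfg$sigma_mode == "fit")
    min(max(0.035, b$lower[npar]), b$upper[npar]) else NULL
  start1 <- c(rep(0.4, nfrac), d_mid, sig0)
  # mostly-free start: the regime typical of freely scanning nuclear factors
  # (guards against the local optimum where the fast state collapses)
  d_fast <- pmin(pmax(if (cfg$n_states == 3L) c(0.003, 0.3, 2.5)
                      else c(0.003, 2.5), d_lo), d_hi)
  start2 <- c(if (cfg$n_states == 3L) c(0.1, 0.25) else 0.1, d_fast, sig0)
  starts <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_restarts), function(i) {
      if (i == 1L) start1
      else if (i == 2L) start2
      else b$lower + runif(npar) * (b$upper - b$lower)
    })
  })

  best <- NULL
  best_ssr <- Inf
  converged <- FALSE
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = b$lower, upper = b$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    ssr <- res$deviance
    if (res$info %in% 1:4) converged <- TRUE
    if (is.finite(ssr) && ssr < best_ssr) {
      best_ssr <- ssr
      best <- res
    }
  }
  if (is.null(best)) stopf("all optimizer restarts failed")
  f <- par_to_fit(best$par, cfg)
  fitted_mass <- model_bin_mass(hist$breaks, f$F, f$D, f$sigma,
                                hist$dt_gaps, cfg, q)
  fr_names <- if (cfg$n_states == 3L) c("bound", "free1", "free2")
              else c("bound", "free")
  structure(list(
    fractions = setNames(f$F, fr_names),
    D = setNames(f$D, fr_names),
    sigma = f$sigma,
    residual = best_ssr,
    n_jumps_used = total,
    converged = converged,
    n_states = cfg$n_states,
    fitted_density = fitted_mass / bw,
    gaps_used = use_k,
    q_hat = q,
    cfg = cfg
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%d-state jump-length kinetic fit (%d jumps)\n",
              x$n_states, x$n_jumps_used))
  cat("  fractions:", paste(sprintf("%s=%.3f", names(x$fractions), x$fractions),
                            collapse = "  "), "\n")
  cat("  D [um^2/s]:", paste(sprintf("%s=%.4g", names(x$D), x$D),
                             collapse = "  "), "\n")
  cat(sprintf("  sigma = %.4f um, residual = %.4g, converged = %s\n",
              x$sigma, x$residual, x$converged))
  invisible(x)
}

# Multinomial log-likelihood of the observed bin counts under the fitted
# per-gap bin masses; the basis of the model-selection criterion. (A BIC on
# the raw least-squares objective is miscalibrated here because bin
# residuals within a gap are correlated through the shared normalization.)
hist_log_lik <- function(hist, fit) {
  ll <- 0
  for (k in fit$gaps_used) {
    mass <- pmax(fit$fitted_density[, k] * hist$bin_width, 1e-300)
    ll <- ll + sum(hist$counts[, k] * log(mass))
  }
  ll
}

# BIC comparison: lower is better; ties go to fewer parameters.
ic_for_fit <- function(log_lik, n_jumps, n_par) {
  -2 * log_lik + n_par * log(n_jumps)
}

#' Choose between the two- and three-state models
#'
#' Fits both models by bounded least squares and compares them with a
#' Bayesian information criterion on the multinomial likelihood of the
#' binned jump counts (`-2 logLik + k log(n_jumps)`); ties go to the model
#' with fewer parameters.
#'
#' @param hist A [compile_jump_histograms()] result.
#' @param cfg2 A two-state [fit_config()].
#' @param cfg3 A three-state [fit_config()].
#' @return A list with `selected` (`"two_state"` or `"three_state"`), per-
#'   model residuals and criterion values, and both fits.
#' @export
select_model <- function(hist, cfg2, cfg3) {
  if (cfg2$n_states != 2L || cfg3$n_states != 3L)
    stopf("cfg2 must be two-state and cfg3 three-state")
  fit2 <- fit_kinetic_model(hist, cfg2)
  fit3 <- fit_kinetic_model(hist, cfg3)
  n_jumps <- sum(hist$n_jumps)
  k2 <- 3L + (cfg2$sigma_mode == "fit")
  k3 <- 5L + (cfg3$sigma_mode == "fit")
  ic2 <- ic_for_fit(hist_log_lik(hist, fit2), n_jumps, k2)
  ic3 <- ic_for_fit(hist_log_lik(hist, fit3), n_jumps, k3)
  selected <- if (ic3 < ic2) "three_state" else "two_state"
  list(selected = selected, ic = c(two_state = ic2, three_state = ic3),
       residual = c(two_state = fit2$residual, three_state = fit3$residual),
       fit2 = fit2, fit3 = fit3)
}
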