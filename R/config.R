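# Configuration objects for every pipeline stage. Plain validated lists with
# S3 classes; defaults reproduce the acquisition and fitting settings of the
# fast-tracking experiment the package emulates (10 ms frames, 0.16 um
# pixels, 0.7 um detection slice, 7 time points, 4 jumps per trajectory,
# three-state diffusion bounds).

#' Ground-truth model for trajectory simulation
#'
#' Describes the static three-state mixture that the kinetic fit assumes:
#' each molecule is chromatin-bound, slow-diffusing or fast-diffusing for
#' the lifetime of its trajectory (optional Markov switching is available as
#' a stress-test mode).
#'
#' @param state_fractions Numeric length 3, fractions of molecules in the
#'   (bound, free1, free2) states. Must sum to 1.
#' @param diffusion_coeffs Numeric length 3, diffusion coefficients in
#'   um^2/s for (bound, free1, free2). Must satisfy
#'   `D_bound < D_free1 < D_free2`.
#' @param sigma_loc Localization error (per-axis standard deviation), um.
#' @param track_length_mean Mean photobleaching-limited track length,
#'   frames; lengths are geometric with this mean.
#' @param density Particles per um^2 for movie rendering.
#' @param switching_rates Optional 3x3 matrix of state-switching rates
#'   (1/s); `NULL` (default) keeps the state fixed per trajectory.
#' @return An object of class `ground_truth_model`.
#' @export
#' @examples
#' ground_truth_model()
ground_truth_model <- function(state_fractions = c(bound = 0.10, free1 = 0.18, free2 = 0.72),
                               diffusion_coeffs = c(bound = 0.005, free1 = 0.35, free2 = 2.3),
                               sigma_loc = 0.035,
                               track_length_mean = 6,
                               density = 0.1,
                               switching_rates = NULL) {
  if (length(state_fractions) != 3L || any(!is.finite(state_fractions)) ||
      any(state_fractions < 0))
    stopf("state_fractions must be 3 non-negative finite numbers")
  if (abs(sum(state_fractions) - 1) > 1e-9)
    stopf("state_fractions must sum to 1 (got %.12f)", sum(state_fractions))
  if (length(diffusion_coeffs) != 3L || any(diffusion_coeffs < 0))
    stopf("diffusion_coeffs must be 3 non-negative numbers")
  if (!(diffusion_coeffs[1] < diffusion_coeffs[2] &&
        diffusion_coeffs[2] < diffusion_coeffs[3]))
    stopf("diffusion_coeffs must be ordered D_bound < D_free1 < D_free2")
  if (!is_number(sigma_loc) || sigma_loc < 0) stopf("sigma_loc must be >= 0")
  if (!is_number(track_length_mean) || track_length_mean < 1)
    stopf("track_length_mean must be >= 1 frame")
  if (!is_number(density) || density < 0) stopf("density must be >= 0")
  if (!is.null(switching_rates)) {
    if (!is.matrix(switching_rates) || any(dim(switching_rates) != 3L) ||
        any(switching_rates[!diag(3)] < 0))
      stopf("switching_rates must be a 3x3 matrix with non-negative off-diagonal rates")
  }
  structure(list(
    state_fractions = setNames(as.numeric(state_fractions), c("bound", "free1", "free2")),
    diffusion_coeffs = setNames(as.numeric(diffusion_coeffs), c("bound", "free1", "free2")),
    sigma_loc = sigma_loc,
    track_length_mean = track_length_mean,
    density = density,
    switching_rates = switching_rates
  ), class = "ground_truth_model")
}

#' Acquisition configuration
#'
#' Camera and optics parameters of the fast-tracking acquisition.
#'
#' @param frame_interval Frame interval, s (10 ms stroboscopic tracking).
#' @param exposure Exposure time, s.
#' @param pixel_size Pixel size, um.
#' @param psf_sigma Gaussian PSF standard deviation, pixels.
#' @param dz Axial detection slice thickness, um.
#' @param fov_px Field of view, pixels, as `c(nx, ny)`.
#' @param photon_budget Integrated photons per molecule per frame
#'   (movie rendering).
#' @param background Background level, photons per pixel (movie rendering).
#' @param n_substeps Axial sub-steps per frame used for slice-exit
#'   detection during simulation (Brownian-bridge crossing checks make the
#'   censoring effectively continuous; see the methods vignette).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_interval = 0.010,
                               exposure = 0.010,
                               pixel_size = 0.16,
                               psf_sigma = 1.35,
                               dz = 0.700,
                               fov_px = c(256L, 128L),
                               photon_budget = 500,
                               background = 100,
                               n_substeps = 5L) {
  if (!is_number(frame_interval) || frame_interval <= 0) stopf("frame_interval must be > 0")
  if (!is_number(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")
  if (!(is_number(dz) || identical(dz, Inf)) || dz <= 0) stopf("dz must be > 0")
  if (!is_number(psf_sigma) || psf_sigma <= 0) stopf("psf_sigma must be > 0")
  if (length(fov_px) != 2L || any(fov_px < 1)) stopf("fov_px must be c(nx, ny) >= 1")
  if (!is_number(photon_budget) || photon_budget < 0) stopf("photon_budget must be >= 0")
  if (!is_number(background) || background < 0) stopf("background must be >= 0")
  if (!is_count(n_substeps) || n_substeps < 1) stopf("n_substeps must be a positive integer")
  structure(list(
    frame_interval = frame_interval, exposure = exposure,
    pixel_size = pixel_size, psf_sigma = psf_sigma, dz = dz,
    fov_px = as.integer(fov_px), photon_budget = photon_budget,
    background = background, n_substeps = as.integer(n_substeps)
  ), class = "acquisition_config")
}

#' Spot-detection configuration
#'
#' @param log_error_threshold Base-10 exponent of the per-pixel false
#'   positive rate of the detection test (default -5; -6 for the sparser
#'   visualization setting). Must be negative.
#' @param psf_sigma Gaussian PSF standard deviation, pixels (matched
#'   filter width).
#' @param min_separation Minimum separation between detections, pixels;
#'   closer maxima are merged to the brighter one.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(log_error_threshold = -5,
                             psf_sigma = 1.35,
                             min_separation = 4) {
  if (!is_number(log_error_threshold) || log_error_threshold >= 0)
    stopf("log_error_threshold must be < 0")
  if (!is_number(psf_sigma) || psf_sigma <= 0) stopf("psf_sigma must be > 0")
  if (!is_number(min_separation) || min_separation < 0) stopf("min_separation must be >= 0")
  structure(list(
    log_error_threshold = log_error_threshold,
    psf_sigma = psf_sigma,
    min_separation = min_separation
  ), class = "detection_config")
}

#' Trajectory-linking configuration
#'
#' @param d_max_expected Maximum expected diffusion coefficient, um^2/s;
#'   sets the gating radius `r_max(k) = sqrt(4 * d_max_expected * k *
#'   frame_interval) * safety_factor` for links spanning `k` frames.
#' @param max_gaps Maximum number of consecutive missed frames a trajectory
#'   may bridge.
#' @param frame_interval Frame interval, s.
#' @param safety_factor Multiplier on the gating radius.
#' @return An object of class `linking_config`.
#' @export
linking_config <- function(d_max_expected = 5,
                           max_gaps = 2L,
                           frame_interval = 0.010,
                           safety_factor = 1.0) {
  if (!is_number(d_max_expected) || d_max_expected <= 0) stopf("d_max_expected must be > 0")
  if (!is_count(max_gaps)) stopf("max_gaps must be a non-negative integer")
  if (!is_number(frame_interval) || frame_interval <= 0) stopf("frame_interval must be > 0")
  if (!is_number(safety_factor) || safety_factor <= 0) stopf("safety_factor must be > 0")
  structure(list(
    d_max_expected = d_max_expected, max_gaps = as.integer(max_gaps),
    frame_interval = frame_interval, safety_factor = safety_factor
  ), class = "linking_config")
}

#' Kinetic-model fit configuration
#'
#' Histogram compilation and fitting settings for the jump-length-mixture
#' model. Default diffusion-coefficient bounds follow the two- and
#' three-state conventions of the jump-distribution framework:
#' two-state `D_free` in `[0.5, 10]`, `D_bound` in `[1e-4, 0.5]`;
#' three-state `D_free1` in `[0.05, 1]`, `D_free2` in `[1, 10]`,
#' `D_bound` in `[1e-4, 0.05]` (um^2/s).
#'
#' @param n_states 2 or 3.
#' @param d_bounds Named list of length-2 numeric intervals for each
#'   diffusion coefficient; `NULL` installs the defaults for `n_states`.
#' @param sigma_mode `"fit"` (localization error fitted within
#'   `sigma_bounds`) or `"fixed"` (held at `sigma_fixed`).
#' @param sigma_bounds Interval for fitted sigma, um.
#' @param sigma_fixed Fixed sigma, um, when `sigma_mode = "fixed"`.
#' @param dz Axial detection slice thickness for the defocalization
#'   correction, um; `Inf` disables the correction geometrically.
#' @param defocalization `"age"` (default; survival averaged over admissible
#'   jump ages, see the methods vignette), `"single"` (survival over the
#'   single gap time only) or `"none"`.
#' @param objective `"pdf"` (default) or `"cdf"` fitting.
#' @param frame_interval Frame interval, s.
#' @param n_timepoints Number of time gaps (multiples of the frame
#'   interval) entering the fit.
#' @param bin_width Histogram bin width, um.
#' @param r_max Histogram upper range, um.
#' @param jumps_per_trajectory Cap on jumps per trajectory per time gap
#'   (the first ones by start frame).
#' @param min_jumps Minimum total jumps required before fitting.
#' @param n_restarts Number of seeded random restarts of the bounded
#'   least-squares optimizer.
#' @param seed Seed for the restart draws.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_states = 3L,
                       d_bounds = NULL,
                       sigma_mode = c("fit", "fixed"),
                       sigma_bounds = c(0.01, 0.075),
                       sigma_fixed = 0.035,
                       dz = 0.700,
                       defocalization = c("age", "single", "none"),
                       objective = c("pdf", "cdf"),
                       frame_interval = 0.010,
                       n_timepoints = 7L,
                       bin_width = 0.01,
                       r_max = 1.2,
                       jumps_per_trajectory = 4L,
                       min_jumps = 500L,
                       n_restarts = 10L,
                       seed = 0L) {
  sigma_mode <- match.arg(sigma_mode)
  defocalization <- match.arg(defocalization)
  objective <- match.arg(objective)
  if (!n_states %in% c(2L, 3L)) stopf("n_states must be 2 or 3")
  if (is.null(d_bounds)) {
    d_bounds <- if (n_states == 3L)
      list(bound = c(0.0001, 0.05), free1 = c(0.05, 1), free2 = c(1, 10))
    else
      list(bound = c(0.0001, 0.5), free = c(0.5, 10))
  }
  if (length(d_bounds) != n_states) stopf("d_bounds must have one interval per state")
  lo <- vapply(d_bounds, `[`, numeric(1), 1L)
  hi <- vapply(d_bounds, `[`, numeric(1), 2L)
  if (any(lo >= hi)) stopf("each d_bounds interval must be increasing")
  if (any(hi[-length(hi)] > lo[-1]))
    stopf("d_bounds intervals must be ordered and non-overlapping")
  if (!(is_number(dz) || identical(dz, Inf)) || dz <= 0) stopf("dz must be > 0")
  if (sigma_bounds[1] < 0 || sigma_bounds[1] >= sigma_bounds[2])
    stopf("sigma_bounds must be an increasing non-negative interval")
  if (!is_number(frame_interval) || frame_interval <= 0) stopf("frame_interval must be > 0")
  if (!is_count(n_timepoints) || n_timepoints < 1) stopf("n_timepoints must be >= 1")
  if (!is_number(bin_width) || bin_width <= 0) stopf("bin_width must be > 0")
  if (!is_number(r_max) || r_max <= bin_width) stopf("r_max must exceed bin_width")
  if (!is_count(jumps_per_trajectory) || jumps_per_trajectory < 1)
    stopf("jumps_per_trajectory must be >= 1")
  if (!is_count(n_restarts) || n_restarts < 1) stopf("n_restarts must be >= 1")
  structure(list(
    n_states = as.integer(n_states), d_bounds = d_bounds,
    sigma_mode = sigma_mode, sigma_bounds = as.numeric(sigma_bounds),
    sigma_fixed = sigma_fixed, dz = dz, defocalization = defocalization,
    objective = objective, frame_interval = frame_interval,
    n_timepoints = as.integer(n_timepoints), bin_width = bin_width,
    r_max = r_max, jumps_per_trajectory = as.integer(jumps_per_trajectory),
    min_jumps = as.integer(min_jumps), n_restarts = as.integer(n_restarts),
    seed = as.integer(seed)
  ), class = "fit_config")
}

#' Pipeline configuration
#'
#' Bundles the stage configurations, statistics options and seeds used by
#' [run_pipeline()].
#'
#' @param model [ground_truth_model()] (used when the pipeline simulates).
#' @param acq [acquisition_config()].
#' @param detection [detection_config()].
#' @param linking [linking_config()].
#' @param fit [fit_config()].
#' @param min_trajectories Per-cell minimum-data filter for
#'   [summarize_cells()].
#' @param test_mode `"student"` or `"welch"` for group comparisons.
#' @param seed Master seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(model = ground_truth_model(),
                            acq = acquisition_config(),
                            detection = detection_config(),
                            linking = linking_config(frame_interval = acq$frame_interval),
                            fit = fit_config(frame_interval = acq$frame_interval, dz = acq$dz),
                            min_trajectories = 500L,
                            test_mode = c("student", "welch"),
                            seed = 1L) {
  stopifnot(inherits(model, "ground_truth_model"),
            inherits(acq, "acquisition_config"),
            inherits(detection, "detection_config"),
            inherits(linking, "linking_config"),
            inherits(fit, "fit_config"))
  test_mode <- match.arg(test_mode)
  if (!is_count(min_trajectories)) stopf("min_trajectories must be a non-negative integer")
  structure(list(
    model = model, acq = acq, detection = detection, linking = linking,
    fit = fit, min_trajectories = as.integer(min_trajectories),
    test_mode = test_mode, seed = as.integer(seed)
  ), class = "pipeline_config")
}
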