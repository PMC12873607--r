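# Auxiliary quantifications used alongside the tracking analysis:
# size-scaling regression of diffusion coefficients, molecule counting
# against a fluorescence standard, and chromatin-fractionation ratios.

#' Size-scaling regression of diffusion coefficients
#'
#' Ordinary least squares of diffusion coefficient against the inverse
#' cubic root of molecular weight, `D ~ MW^(-1/3)` — the Stokes-Einstein
#' expectation for globular particles, where the hydrodynamic radius scales
#' as the cube root of mass.
#'
#' @param molecular_weight Molecular weights, kDa (> 0).
#' @param diffusion_coefficient Diffusion coefficients, um^2/s (> 0).
#' @param labels Optional protein labels.
#' @return A list: `slope`, `intercept`, `residuals`, `predictor`
#'   (`MW^(-1/3)` values), `fitted`, `r_squared`, and the underlying `lm`
#'   fit.
#' @export
#' @examples
#' stokes_einstein_fit(c(100, 200, 400), c(3.0, 2.4, 1.9))
stokes_einstein_fit <- function(molecular_weight, diffusion_coefficient,
                                labels = NULL) {
  mw <- as.numeric(molecular_weight)
  D <- as.numeric(diffusion_coefficient)
  if (length(mw) != length(D)) stopf("inputs must have equal length")
  if (length(mw) < 2L) stopf("at least 2 points are required")
  if (any(mw <= 0) || any(D <= 0)) stopf("weights and diffusion coefficients must be > 0")
  x <- mw^(-1 / 3)
  if (length(unique(x)) < 2L)
    stopf("degenerate design: all molecular weights identical")
  fit <- lm(D ~ x)
  ss_tot <- sum((D - mean(D))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       residuals = unname(fit$residuals), predictor = x,
       fitted = unname(fit$fitted.values),
       r_squared = r2,
       labels = labels, lm = fit)
}

#' Count molecules against a fluorescence standard
#'
#' Converts background-corrected fluorescence to absolute molecule numbers
#' using a cell line carrying a known number of the same tag:
#' `count = (sample - background) / (standard - background) * standard_count`.
#' The standard's absolute count comes from independent calibration and
#' must be supplied by the user.
#'
#' @param sample_signal Sample fluorescence (vectorized).
#' @param background_signal Background (untagged) fluorescence.
#' @param standard_signal Fluorescence of the calibration standard.
#' @param standard_count Absolute molecule count of the standard.
#' @return Molecules per cell; negative numerators are clipped to 0 with a
#'   warning.
#' @export
#' @examples
#' molecule_count(2100, 100, 1100, 80000)  # 160000
molecule_count <- function(sample_signal, background_signal,
                           standard_signal, standard_count) {
  if (!is_number(standard_signal) || !is_number(background_signal))
    stopf("background_signal and standard_signal must be single numbers")
  if (standard_signal <= background_signal)
    stopf("standard_signal must exceed background_signal")
  if (!is_number(standard_count) || standard_count <= 0)
    stopf("standard_count must be > 0")
  num <- sample_signal - background_signal
  if (any(num < 0)) {
    warnf("%d sample signal(s) below background were clipped to 0", sum(num < 0))
    num <- pmax(num, 0)
  }
  num / (standard_signal - background_signal) * standard_count
}

#' Chromatin / nucleoplasm fractionation ratio
#'
#' Ratio of loading-normalized target intensities in the chromatin and
#' nucleoplasmic fractions. Each argument is a list with `target` and
#' `normalizer` intensities; vectors are treated as paired replicates and
#' the ratio is summarized by its mean and standard error.
#'
#' @param chromatin,nucleoplasm Lists with numeric `target` and
#'   `normalizer` (normalizers > 0).
#' @return A list: `ratio` (mean over replicates), `se` (standard error of
#'   the mean, `NA` for a single replicate), `replicates` (per-replicate
#'   ratios).
#' @export
#' @examples
#' fractionation_ratio(list(target = c(2.0, 2.2), normalizer = c(1, 1)),
#'                     list(target = c(1.0, 1.1), normalizer = c(1, 1)))
fractionation_ratio <- function(chromatin, nucleoplasm) {
  for (m in list(chromatin, nucleoplasm)) {
    if (!is.list(m) || is.null(m$target) || is.null(m$normalizer))
      stopf("each measurement must be a list with target and normalizer")
    if (any(m$normalizer <= 0)) stopf("normalizer intensities must be > 0")
  }
  nc <- chromatin$target / chromatin$normalizer
  nn <- nucleoplasm$target / nucleoplasm$normalizer
  if (length(nc) != length(nn)) stopf("replicate sets must have equal length")
  if (any(nn == 0)) stopf("nucleoplasmic normalized intensity is 0; ratio undefined")
  reps <- nc / nn
  list(ratio = mean(reps),
       se = if (length(reps) > 1L) sd(reps) / sqrt(length(reps)) else NA_real_,
       replicates = reps)
}
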