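# Jump histograms, defocalization correction, mixture density, fitting and
# model selection.

cfg3 <- fit_config()
acq <- acquisition_config()

test_that("single jump lands in its bin, nothing elsewhere", {
  tr <- data.frame(trajectory_id = 1L, frame = 0:1,
                   x_um = c(1, 1.055), y_um = c(2, 2))
  h <- compile_jump_histograms(tr, cfg3)
  i <- findInterval(0.055, h$breaks)
  expect_identical(h$counts[i, 1], 1L)
  expect_identical(sum(h$counts), 1L)
  expect_true(h$breaks[i] <= 0.055 && 0.055 < h$breaks[i + 1])
})

test_that("a 20-point gapless track contributes exactly 4 jumps per gap", {
  set.seed(31)
  tr <- data.frame(trajectory_id = 1L, frame = 0:19,
                   x_um = cumsum(rnorm(20, 0, 0.02)),
                   y_um = cumsum(rnorm(20, 0, 0.02)))
  h <- compile_jump_histograms(tr, cfg3)
  expect_identical(unname(h$n_jumps), rep(4L, 7L))
})

test_that("jumps spanning recorded gaps match exhaustive enumeration", {
  frames <- c(0L, 1L, 2L, 4L)
  x <- c(0.10, 0.16, 0.13, 0.40)
  y <- c(0.20, 0.22, 0.30, 0.28)
  tr <- data.frame(trajectory_id = 1L, frame = frames, x_um = x, y_um = y)
  h <- compile_jump_histograms(tr, cfg3)
  for (k in 1:7) {
    oracle <- enumerate_jumps(frames, x, y, k, cap = cfg3$jumps_per_trajectory)
    expect_identical(h$n_jumps[k], length(oracle))
    if (length(oracle)) {
      expected <- tabulate(findInterval(oracle, h$breaks), length(h$centers))
      expect_identical(h$counts[, k], as.integer(expected))
    }
  }
  # the frame-2 -> frame-4 pair spans a recorded gap and must be excluded
  expect_identical(h$n_jumps[2], 1L)  # only (0 -> 2)
})

test_that("axial survival: immobile and wide-slab limits", {
  expect_identical(axial_survival_probability(0, 0.01, 0.7), 1)
  # wide slab: survival -> 1; the leading loss is the boundary layer
  # 4*sqrt(D*t/pi)/dz, so a 1e-6 approach to 1 needs dz >> diffusion length
  expect_lt(abs(axial_survival_probability(1, 0.01, 1e6) - 1), 1e-6)
  x <- 1 * 0.01 / 100^2
  expect_equal(axial_survival_probability(1, 0.01, 100),
               1 - 4 * sqrt(x / pi), tolerance = 1e-6)
  expect_identical(axial_survival_probability(3, 0.07, Inf), 1)
})

test_that("axial survival series agrees with the Monte-Carlo oracle", {
  for (D in c(0.1, 2.0)) {
    mc <- mc_axial_survival(D, 0.01, 0.7, n_walkers = 2e5,
                            n_substeps = 100, seed = 32)
    expect_lt(abs(axial_survival_probability(D, 0.01, 0.7) - mc$p),
              0.005)
  }
})

test_that("single free state with sigma = 0 peaks at the Rayleigh mode bin", {
  cfg_inf <- fit_config(dz = Inf)
  ctr <- seq(0.005, 1.195, by = 0.01)
  d <- model_jump_pdf(ctr, list(F = c(0, 0, 1), D = c(0.001, 0.1, 1), sigma = 0),
                      dt_gap = 0.01, cfg = cfg_inf)
  mode_bin <- ctr[which.max(d)]
  expect_true(0.14 < mode_bin && mode_bin < 0.15)  # sqrt(2 D dt) = 0.1414
})

test_that("mixture density normalizes to 1 for random bounded parameters", {
  set.seed(33)
  ctr <- seq(0.005, 1.195, by = 0.01)
  for (i in 1:20) {
    p1 <- runif(1); p2 <- runif(1)
    fit <- list(F = c(p1, (1 - p1) * p2, (1 - p1) * (1 - p2)),
                D = c(runif(1, 1e-4, 0.05), runif(1, 0.05, 1), runif(1, 1, 10)),
                sigma = runif(1, 0.01, 0.075))
    for (k in c(1, 4, 7)) {
      d <- model_jump_pdf(ctr, fit, dt_gap = k * 0.01, cfg = cfg3, q = 0.8)
      expect_lt(abs(sum(d) * 0.01 - 1), 1e-3)
    }
  }
})

test_that("bound-state mass below 0.1 um matches the Rayleigh closed form", {
  ctr <- seq(0.005, 1.195, by = 0.01)
  d <- model_jump_pdf(ctr, list(F = c(1, 0, 0), D = c(0.001, 0.1, 1),
                                sigma = 0.035),
                      dt_gap = 0.01, cfg = fit_config(dz = Inf))
  mass_below <- sum(d[ctr < 0.1]) * 0.01
  v <- 0.001 * 0.01 + 0.035^2
  closed_form <- (1 - exp(-0.1^2 / (4 * v))) / (1 - exp(-1.2^2 / (4 * v)))
  expect_equal(mass_below, closed_form, tolerance = 1e-6)
  expect_gt(mass_below, 0.85)
})

test_that("negative parameters are rejected by the density", {
  ctr <- seq(0.005, 0.995, by = 0.01)
  expect_error(model_jump_pdf(ctr, list(F = c(1, 0, 0), D = c(-1, 0.1, 1),
                                        sigma = 0.03), 0.01, cfg3), "negative")
  expect_error(model_jump_pdf(ctr, list(F = c(1, 0, 0), D = c(0.01, 0.1, 1),
                                        sigma = -0.1), 0.01, cfg3), "sigma")
})

test_that("a pure bound-state simulation is fitted as nearly all bound", {
  m <- ground_truth_model(state_fractions = c(1, 0, 0),
                          diffusion_coeffs = c(0.002, 0.35, 2.3))
  d <- simulate_trajectories(m, acq, 2500, seed = 34)
  h <- compile_jump_histograms(d$trajectories, cfg3)
  fit <- fit_kinetic_model(h, cfg3)
  expect_gte(fit$fractions[["bound"]], 0.95)
})

test_that("three-state simulation parameters are recovered within tolerance", {
  d <- simulate_trajectories(default_model(), acq, 6000, seed = 35)
  h <- compile_jump_histograms(d$trajectories, cfg3)
  fit <- fit_kinetic_model(h, cfg3)
  expect_true(fit$converged)
  expect_lt(abs(fit$fractions[["bound"]] - 0.10), 0.03)
  # the free1/free2 split fluctuates more than F_bound at this data volume
  # (measured seed-to-seed sd ~0.016); 0.06 is a ~3.5-sigma band
  expect_lt(abs(fit$fractions[["free1"]] - 0.18), 0.06)
  expect_lt(abs(fit$fractions[["free2"]] - 0.72), 0.06)
  expect_lt(abs(fit$D[["free2"]] - 2.3) / 2.3, 0.10)
  # all parameters inside their configured intervals
  for (s in names(fit$D)) {
    iv <- cfg3$d_bounds[[s]]
    expect_true(iv[1] <= fit$D[[s]] && fit$D[[s]] <= iv[2])
  }
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-6)
})

test_that("fit is invariant to global rescaling of histogram counts", {
  d <- simulate_trajectories(default_model(), acq, 1500, seed = 36)
  h <- compile_jump_histograms(d$trajectories, cfg3)
  h10 <- h
  h10$counts <- h$counts * 10L
  h10$n_jumps <- h$n_jumps * 10L
  f1 <- fit_kinetic_model(h, cfg3)
  f2 <- fit_kinetic_model(h10, cfg3)
  expect_equal(f1$fractions, f2$fractions, tolerance = 1e-8)
  expect_equal(f1$D, f2$D, tolerance = 1e-8)
})

test_that("disabling the defocalization correction inflates the bound fraction", {
  d <- simulate_trajectories(default_model(), acq, 5000, seed = 37)
  h <- compile_jump_histograms(d$trajectories, cfg3)
  corrected <- fit_kinetic_model(h, cfg3)
  uncorrected <- fit_kinetic_model(h, fit_config(defocalization = "none"))
  expect_gt(uncorrected$fractions[["bound"]], corrected$fractions[["bound"]])
})

test_that("too few jumps refuse the fit with a diagnostic", {
  tr <- data.frame(trajectory_id = 1L, frame = 0:5,
                   x_um = seq(0, 0.1, length.out = 6), y_um = 0)
  h <- compile_jump_histograms(tr, cfg3)
  expect_error(fit_kinetic_model(h, cfg3), "at least")
})

test_that("model selection prefers the generating model; ties go to 2 states", {
  cfg2 <- fit_config(n_states = 2L)
  d3 <- simulate_trajectories(default_model(), acq, 3000, seed = 38)
  sel3 <- select_model(compile_jump_histograms(d3$trajectories, cfg3), cfg2, cfg3)
  expect_identical(sel3$selected, "three_state")
  expect_lt(sel3$residual[["three_state"]], sel3$residual[["two_state"]])

  m2 <- ground_truth_model(state_fractions = c(0.3, 0, 0.7),
                           diffusion_coeffs = c(0.005, 0.3, 2.3))
  d2 <- simulate_trajectories(m2, acq, 3000, seed = 39)
  sel2 <- select_model(compile_jump_histograms(d2$trajectories, cfg3), cfg2, cfg3)
  expect_identical(sel2$selected, "two_state")

  # identical likelihoods: the information criterion must pick fewer parameters
  expect_gt(sptkin:::ic_for_fit(-500, 1e4, 6), sptkin:::ic_for_fit(-500, 1e4, 4))
})
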