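# Trajectory simulator and Monte-Carlo axial-survival oracle.

test_that("degenerate inputs: empty set and frozen particles", {
  m <- default_model()
  acq <- default_acq()
  d0 <- simulate_trajectories(m, acq, 0, seed = 1)
  expect_s3_class(d0, "spt_dataset")
  expect_identical(nrow(d0$trajectories), 0L)

  frozen <- ground_truth_model(diffusion_coeffs = c(0, 1e-12, 2e-12),
                               sigma_loc = 0)
  df <- simulate_trajectories(frozen, acq, 25, seed = 2)$trajectories
  per <- split(df, df$trajectory_id)
  expect_true(all(vapply(per, function(tr)
    diff(range(tr$x_um)) < 1e-5 && diff(range(tr$y_um)) < 1e-5, logical(1))))
})

test_that("invalid inputs are rejected with messages", {
  expect_error(ground_truth_model(state_fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(ground_truth_model(diffusion_coeffs = c(1, 0.5, 2)), "ordered")
  expect_error(simulate_trajectories(default_model(), default_acq(), -3, seed = 1),
               "non-negative")
  expect_error(mc_axial_survival(1, 0.01, 0.7, n_walkers = 0,
                                 n_substeps = 10, seed = 1), "positive")
})

test_that("frame-to-frame MSD matches 4*D*dt for free 2D Brownian motion", {
  m <- ground_truth_model(state_fractions = c(0, 0, 1),
                          diffusion_coeffs = c(0.001, 0.01, 1), sigma_loc = 0)
  acq <- default_acq(dz = Inf)
  tr <- simulate_trajectories(m, acq, 25000, seed = 3)$trajectories
  same <- diff(tr$trajectory_id) == 0 & diff(tr$frame) == 1
  r2 <- (diff(tr$x_um)^2 + diff(tr$y_um)^2)[same]
  expect_gt(length(r2), 1e5)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 4 * 1 * acq$frame_interval), 3 * se)
})

test_that("identical seeds give bit-identical tables; different seeds differ", {
  m <- default_model(); acq <- default_acq()
  a <- simulate_trajectories(m, acq, 200, seed = 7)$trajectories
  b <- simulate_trajectories(m, acq, 200, seed = 7)$trajectories
  c <- simulate_trajectories(m, acq, 200, seed = 8)$trajectories
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("empirical state fractions converge to the model fractions", {
  m <- default_model(); acq <- default_acq()
  tr <- simulate_trajectories(m, acq, 6000, seed = 4)$trajectories
  first <- tr[!duplicated(tr$trajectory_id), ]
  n <- nrow(first)
  emp <- table(factor(first$true_state, c("bound", "free1", "free2"))) / n
  f <- m$state_fractions
  for (s in names(f))
    expect_lt(abs(emp[[s]] - f[[s]]), 4 * sqrt(f[[s]] * (1 - f[[s]]) / n))
})

test_that("axial censoring shortens fast-state tracks relative to bound ones", {
  m <- default_model(); acq <- default_acq()   # dz = 0.7 um
  tr <- simulate_trajectories(m, acq, 4000, seed = 5)$trajectories
  len <- tapply(tr$frame, tr$trajectory_id, length)
  st <- tapply(tr$true_state, tr$trajectory_id, `[`, 1)
  expect_lt(mean(len[st == "free2"]), mean(len[st == "bound"]))
})

test_that("Markov switching mode changes states within trajectories", {
  rates <- matrix(10, 3, 3); diag(rates) <- 0  # fast switching, 10/s
  m <- ground_truth_model(switching_rates = rates)
  tr <- simulate_trajectories(m, default_acq(dz = Inf), 300, seed = 6)$trajectories
  n_states_per_track <- tapply(tr$true_state, tr$trajectory_id,
                               function(s) length(unique(s)))
  expect_gt(mean(n_states_per_track > 1), 0.2)
})

test_that("mc_axial_survival limits: immobile, wide slab, monotonicity", {
  expect_equal(mc_axial_survival(0, 0.01, 0.7, 100, 10, seed = 1)$p, 1)
  # wide slab: survival close to 1, up to the exact boundary-layer loss
  # 4*sqrt(D*t/pi)/dz = 2.26e-3 at dz = 100
  wide <- mc_axial_survival(1, 0.01, 100, n_walkers = 20000,
                            n_substeps = 20, seed = 2)
  loss <- 4 * sqrt(1 * 0.01 / pi) / 100
  expect_lt(abs(wide$p - (1 - loss)), 4 * max(wide$se, 1e-4))
  expect_gt(wide$p, 0.995)
  ps_D <- vapply(c(0.1, 1, 5), function(D)
    mc_axial_survival(D, 0.02, 0.7, 30000, 50, seed = 3)$p, numeric(1))
  expect_true(all(diff(ps_D) < 0))
  ps_t <- vapply(c(0.01, 0.03, 0.07), function(t)
    mc_axial_survival(1, t, 0.7, 30000, 50, seed = 4)$p, numeric(1))
  expect_true(all(diff(ps_t) < 0))
})
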