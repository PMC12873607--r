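# I/O round-tripping and the end-to-end pipeline driver.

test_that("trajectory CSV write/read round-trips and validates", {
  d <- simulate_trajectories(default_model(), default_acq(), 3, seed = 51)
  tab <- d$trajectories
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_table(tab, path)
  back <- read_trajectory_table(path)
  expect_equal(back, tab, tolerance = 1e-12)

  bad <- tab[, setdiff(names(tab), "x_um")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(bad, path2)
  expect_error(read_trajectory_table(path2), "x_um")

  dup <- data.frame(trajectory_id = 1L, frame = c(3L, 3L),
                    x_um = c(0, 1), y_um = c(0, 1), cell_id = "c")
  expect_error(write_trajectory_table(dup, tempfile()), "non-increasing")
})

test_that("movie TIFF round-trips within quantization error", {
  acq <- default_acq(fov_px = c(32L, 24L))
  d <- simulate_trajectories(default_model(), acq, 5, seed = 52)
  mov <- render_movie(d, acq, seed = 53, n_frames = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mov, path)
  back <- read_movie_tiff(path)
  expect_identical(dim(back), dim(mov))
  expect_lt(max(abs(back - unclass(mov))), 1)  # 16-bit quantization
})

test_that("pipeline runs are deterministic and recover the bound fraction", {
  acq <- default_acq()
  cfg <- pipeline_config(acq = acq,
                         fit = fit_config(n_restarts = 4L),
                         min_trajectories = 100L)
  tr1 <- simulate_trajectories(default_model(), acq, 4000, seed = 54,
                               cell_id = "cellA")$trajectories
  res1 <- run_pipeline(cfg, list(trajectories = tr1))
  res2 <- run_pipeline(cfg, list(trajectories = tr1))
  expect_equal(res1$summary, res2$summary, tolerance = 1e-12)
  expect_lt(abs(res1$summary$F_bound - 0.10), 0.03)
  expect_identical(res1$provenance$config_md5, res2$provenance$config_md5)
  expect_true(nzchar(res1$provenance$package_version))
})

test_that("empty trajectory input aborts with the minimum-data diagnostic", {
  cfg <- pipeline_config()
  empty <- data.frame(trajectory_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(), cell_id = character())
  expect_error(run_pipeline(cfg, list(trajectories = empty)), "minimum-data")
  few <- simulate_trajectories(default_model(), default_acq(), 10, seed = 55)
  expect_error(run_pipeline(cfg, list(trajectories = few$trajectories)),
               "at least")
})

test_that("two-condition pipelines report group comparisons", {
  acq <- default_acq()
  cfg <- pipeline_config(acq = acq, fit = fit_config(n_restarts = 3L),
                         min_trajectories = 100L)
  mA <- default_model()
  mB <- ground_truth_model(state_fractions = c(0.20, 0.18, 0.62))
  tr <- do.call(rbind, c(
    lapply(1:3, function(i) simulate_trajectories(mA, acq, 1200, seed = 60 + i,
                                                  cell_id = paste0("A", i))$trajectories),
    lapply(1:3, function(i) simulate_trajectories(mB, acq, 1200, seed = 70 + i,
                                                  cell_id = paste0("B", i))$trajectories)))
  conds <- setNames(rep(c("ctrl", "drug"), each = 3),
                    c(paste0("A", 1:3), paste0("B", 1:3)))
  res <- run_pipeline(cfg, list(trajectories = tr), conditions = conds)
  expect_identical(nrow(res$summary), 6L)
  expect_s3_class(res$comparisons$F_bound, "group_comparison")
  # the simulated contrast is two-fold; the sign must match
  drug_mean <- mean(res$summary$F_bound[res$summary$condition == "drug"])
  ctrl_mean <- mean(res$summary$F_bound[res$summary$condition == "ctrl"])
  expect_gt(drug_mean, ctrl_mean)
})

test_that("movie-tail subsampling keeps every 2nd frame of the tail", {
  acq <- default_acq()
  mov <- array(0, dim = c(4, 4, 1000))  # 10 s at 10 ms
  sub <- subsample_movie_tail(mov, acq, tail_seconds = 4.5, keep_every = 2L)
  frames <- attr(sub, "frames")
  expect_identical(frames[1], 550L)
  expect_true(all(diff(frames) == 2L))
  expect_identical(dim(sub)[3], length(frames))
})
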