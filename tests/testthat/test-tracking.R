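# Linking: Hungarian assignment vs brute force, gap semantics, gating.

test_that("Hungarian assignment matches brute-force enumeration", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    cm <- matrix(runif(n * n), n)
    a <- sptkin:::hungarian_assign(cm)
    expect_identical(sort(a), seq_len(n))  # a permutation
    expect_equal(sum(cm[cbind(seq_len(n), a)]),
                 brute_assignment(cm)$cost, tolerance = 1e-12)
  }
})

test_that("empty and unsorted inputs are handled per contract", {
  cfg <- linking_config()
  empty <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric())
  expect_identical(nrow(link_localizations(empty, cfg)), 0L)
  bad <- data.frame(frame = c(2L, 0L), x_um = c(0, 0), y_um = c(0, 0))
  expect_error(link_localizations(bad, cfg), "sorted")
})

test_that("a lone particle yields one trajectory spanning all frames", {
  cfg <- linking_config()
  locs <- data.frame(frame = 0:9, x_um = 0.01 * (0:9), y_um = 1)
  out <- link_localizations(locs, cfg)
  expect_identical(length(unique(out$trajectory_id)), 1L)
  expect_identical(out$frame, 0:9)
})

test_that("2-frame gaps are closed; 3-frame gaps fragment the track", {
  cfg <- linking_config()  # max_gaps = 2
  mk <- function(frames) data.frame(frame = frames, x_um = 0.01 * frames, y_um = 0.5)
  closed <- link_localizations(mk(c(0:2, 5:7)), cfg)      # frames 3,4 missing
  expect_identical(length(unique(closed$trajectory_id)), 1L)
  split_ <- link_localizations(mk(c(0:2, 6:8)), cfg)      # frames 3,4,5 missing
  expect_identical(length(unique(split_$trajectory_id)), 2L)
})

test_that("no output jump exceeds the gating radius for its frame span", {
  cfg <- linking_config()
  set.seed(22)
  locs <- data.frame(frame = rep(0:19, each = 15),
                     x_um = runif(300, 0, 5), y_um = runif(300, 0, 5))
  out <- link_localizations(locs, cfg)
  per <- split(out, out$trajectory_id)
  for (tr in per) {
    if (nrow(tr) < 2) next
    k <- diff(tr$frame)
    r <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    rmax <- sqrt(4 * cfg$d_max_expected * k * cfg$frame_interval) * cfg$safety_factor
    expect_true(all(r <= rmax + 1e-12))
    expect_true(all(k <= cfg$max_gaps + 1))
  }
})

test_that("sparse well-separated data is linked exactly, including gaps", {
  cfg <- linking_config()
  truth <- sparse_grid_locs(seed = 23,
                            drop = list(list(tid = 1, frames = 5:6),    # closable
                                        list(tid = 2, frames = 4:6)))   # fragments
  out <- link_localizations(truth[, c("frame", "x_um", "y_um")], cfg)
  chk <- linking_matches_truth(truth, out)
  expect_true(chk$pure)
  expect_identical(chk$n_tracks, 41L)  # 40 particles + 1 extra fragment
})

test_that("trajectory_stats counts jumps and lengths correctly", {
  s0 <- trajectory_stats(data.frame(trajectory_id = integer(), frame = integer()))
  expect_identical(s0$n_trajectories, 0L)
  expect_true(all(s0$jumps_per_gap == 0))

  one <- data.frame(trajectory_id = 1L, frame = 0:4,
                    x_um = 0, y_um = 0)
  s1 <- trajectory_stats(one)
  expect_identical(unname(s1$jumps_per_gap[1:4]), c(4L, 3L, 2L, 1L))
  expect_identical(s1$median_length, 5L)

  # identity oracle: low density, perfect detection -> simulator count
  d <- simulate_trajectories(default_model(), default_acq(), 150, seed = 24)
  expect_identical(trajectory_stats(d)$n_trajectories,
                   length(unique(d$trajectories$trajectory_id)))
})
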