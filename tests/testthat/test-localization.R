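# Spot detection and subpixel refinement, validated by injection/recovery
# against the movie renderer.

det <- detection_config()
acq <- acquisition_config(fov_px = c(64L, 64L))

# render one or more spots at given um positions into a single frame
render_frame <- function(x_um, y_um, acq, seed = 1, photons = NULL) {
  tr <- data.frame(trajectory_id = seq_along(x_um), frame = 0L,
                   x_um = x_um, y_um = y_um, cell_id = "c",
                   true_state = "free2", x_true_um = x_um, y_true_um = y_um)
  a <- acq
  if (!is.null(photons)) a$photon_budget <- photons
  render_movie(tr, a, seed = seed, n_frames = 1L)[, , 1]
}

test_that("constant background yields no detections; non-2D input rejected", {
  frame <- matrix(100, 64, 64)
  expect_identical(nrow(detect_spots(frame, det)), 0L)
  expect_error(detect_spots(array(1, c(4, 4, 2)), det), "2D")
})

test_that("rendered spots are detected at their true positions", {
  x <- c(3.2, 3.2 + 10 * acq$pixel_size)  # two spots 10 px apart
  y <- c(5.0, 5.0)
  fr1 <- render_frame(x[1], y[1], acq, seed = 11)  # peak SNR ~ 10 at 500 photons
  d1 <- detect_spots(fr1, det)
  expect_identical(nrow(d1), 1L)
  expect_lt(abs(d1$col - x[1] / acq$pixel_size - 0.5), 1)
  expect_lt(abs(d1$row - y[1] / acq$pixel_size - 0.5), 1)

  fr2 <- render_frame(x, y, acq, seed = 12)
  expect_identical(nrow(detect_spots(fr2, det)), 2L)
})

test_that("detection count is monotone non-increasing in |log_error_threshold|", {
  set.seed(13)
  xs <- runif(12, 2, 8); ys <- runif(12, 2, 8)
  fr <- render_frame(xs, ys, acq, seed = 13, photons = 200)
  counts <- vapply(c(-3, -5, -7, -9), function(le)
    nrow(detect_spots(fr, detection_config(log_error_threshold = le))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("noiseless symmetric spot refines exactly to the pixel center", {
  # spot at the center of pixel (21, 33): x = 32.5 px, y = 20.5 px
  sig <- det$psf_sigma
  px <- seq_len(64)
  cm <- pnorm((px - 32.5) / sig) - pnorm((px - 1 - 32.5) / sig)
  rm_ <- pnorm((px - 20.5) / sig) - pnorm((px - 1 - 20.5) / sig)
  fr <- 500 * (rm_ %o% cm)
  loc <- refine_subpixel(fr, c(21L, 33L), det, acq$pixel_size)
  expect_true(loc$ok)
  expect_equal(loc$x_um / acq$pixel_size, 32.5, tolerance = 1e-6)
  expect_equal(loc$y_um / acq$pixel_size, 20.5, tolerance = 1e-6)
})

test_that("noiseless off-center spot refines within 0.02 px", {
  sig <- det$psf_sigma
  px <- seq_len(64)
  cm <- pnorm((px - 20.30) / sig) - pnorm((px - 1 - 20.30) / sig)
  rm_ <- pnorm((px - 31.70) / sig) - pnorm((px - 1 - 31.70) / sig)
  fr <- 40 + 700 * (rm_ %o% cm)  # row = y = 31.70, col = x = 20.30
  loc <- refine_subpixel(fr, c(32L, 21L), det, pixel_size = 1)
  expect_true(loc$ok)
  expect_lt(abs(loc$x_um - 20.30), 0.02)
  expect_lt(abs(loc$y_um - 31.70), 0.02)
})

test_that("flat window and edge-truncated window are discarded", {
  fr <- matrix(50, 32, 32)
  expect_false(refine_subpixel(fr, c(16L, 16L), det, 0.16)$ok)
  expect_false(refine_subpixel(fr, c(2L, 16L), det, 0.16)$ok)
})

test_that("a binary mask suppresses detections outside it", {
  fr <- render_frame(c(2.0, 8.0), c(5.0, 5.0), acq, seed = 14)
  mask <- matrix(FALSE, 64, 64)
  mask[, seq_len(32)] <- TRUE  # keep only the left half (x < 32 px)
  d <- detect_spots(fr, det, mask = mask)
  expect_identical(nrow(d), 1L)
  expect_lt(d$col, 32)
})
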