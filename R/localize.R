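# Spot detection (matched filter + amplitude test against the local
# background-noise null) and subpixel refinement (bounded least-squares fit
# of a pixel-integrated 2D Gaussian with fixed PSF width).

#' Detect diffraction-limited spots in one frame
#'
#' Convolves the frame with a unit-sum Gaussian matched filter of width
#' `psf_sigma`, estimates the background level and noise of the filtered
#' image robustly (median / MAD), and keeps local maxima whose filtered
#' amplitude exceeds the background by `z * noise`, where
#' `z = qnorm(1 - 10^log_error_threshold)` — i.e. a per-pixel false
#' positive rate of `10^log_error_threshold`. Maxima closer than
#' `min_separation` pixels are merged to the brighter one.
#'
#' @param frame Numeric matrix (photon counts), rows = y, cols = x.
#' @param cfg A [detection_config()].
#' @param mask Optional logical matrix; detections outside the mask are
#'   discarded (e.g. a nucleus mask).
#' @return A data.frame of candidate pixel positions: `row`, `col`
#'   (1-based) and `response` (filtered amplitude above background).
#' @export
detect_spots <- function(frame, cfg, mask = NULL) {
  stopifnot(inherits(cfg, "detection_config"))
  if (!is.matrix(frame) || !is.numeric(frame) || any(!is.finite(frame)))
    stopf("frame must be a finite-valued 2D numeric matrix")
  sig <- cfg$psf_sigma
  half <- ceiling(3 * sig)
  ax <- (-half):half
  k1 <- exp(-ax^2 / (2 * sig^2))
  kern <- (k1 %o% k1) / sum(k1)^2
  filt <- EBImage::filter2(frame, kern, boundary = "replicate")
  bg <- median(filt)
  noise <- mad(filt)
  z <- qnorm(10^cfg$log_error_threshold, lower.tail = FALSE)
  thr <- bg + z * noise
  if (noise == 0) thr <- bg + .Machine$double.eps^0.5 # flat frame: nothing passes

  nr <- nrow(frame); nc <- ncol(frame)
  # strict local maximum over the 8-neighborhood (ties broken toward the
  # top-left by using >= for later neighbors in scan order)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- filt
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  ismax <- ctr > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(nr + 1L + di), (2 + dj):(nc + 1L + dj)]
    ismax <- ismax & if (di < 0 || (di == 0 && dj < 0)) ctr > nb else ctr >= nb
  }
  # maxima within half a kernel of the border are artifacts of boundary
  # padding and could not be refined anyway
  ismax[c(seq_len(min(half, nr)), nr - seq_len(min(half, nr)) + 1L), ] <- FALSE
  ismax[, c(seq_len(min(half, nc)), nc - seq_len(min(half, nc)) + 1L)] <- FALSE
  idx <- which(ismax, arr.ind = TRUE)
  if (!is.null(mask)) {
    keep <- mask[idx]
    idx <- idx[keep, , drop = FALSE]
  }
  if (!nrow(idx))
    return(data.frame(row = integer(), col = integer(), response = numeric()))
  resp <- ctr[idx] - bg
  ord <- order(-resp, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  resp <- resp[ord]
  keep <- rep(TRUE, nrow(idx))
  if (cfg$min_separation > 0 && nrow(idx) > 1L) {
    for (i in 2:nrow(idx)) {
      earlier <- which(keep[seq_len(i - 1L)])
      d2 <- (idx[earlier, 1] - idx[i, 1])^2 + (idx[earlier, 2] - idx[i, 2])^2
      if (any(d2 < cfg$min_separation^2)) keep[i] <- FALSE
    }
  }
  data.frame(row = as.integer(idx[keep, 1]), col = as.integer(idx[keep, 2]),
             response = resp[keep])
}

# Pixel-integrated 2D Gaussian model over a window; photons N, background
# B per pixel, center (x0, y0) in pixel-edge units.
gauss_window_model <- function(rows, cols, x0, y0, N, B, sigma) {
  colmass <- pnorm((cols - x0) / sigma) - pnorm((cols - 1 - x0) / sigma)
  rowmass <- pnorm((rows - y0) / sigma) - pnorm((rows - 1 - y0) / sigma)
  B + N * (rowmass %o% colmass)
}

#' Refine a spot position to subpixel precision
#'
#' Least-squares fit of a pixel-integrated 2D Gaussian (free: center,
#' integrated photons, background; fixed width `psf_sigma`) over a square
#' window around the candidate pixel. Candidates whose window is truncated
#' by the image edge, or whose fitted amplitude is not positive, are
#' discarded with `ok = FALSE`.
#'
#' @param frame Numeric matrix of photon counts.
#' @param candidate Integer vector `c(row, col)` (1-based) or a one-row
#'   data.frame from [detect_spots()].
#' @param cfg A [detection_config()].
#' @param pixel_size Pixel size, um.
#' @param window_half Half-width of the fit window, pixels (default
#'   `max(3, ceiling(2.5 * psf_sigma))`, at least a 7x7 window).
#' @return A one-row data.frame: `x_um`, `y_um`, `intensity` (photons above
#'   background), `background`, `precision_um` (CRLB-style estimate), `ok`.
#'   `ok = FALSE` rows carry `NA` coordinates.
#' @export
refine_subpixel <- function(frame, candidate, cfg, pixel_size,
                            window_half = NULL) {
  stopifnot(inherits(cfg, "detection_config"))
  if (is.data.frame(candidate)) candidate <- c(candidate$row[1], candidate$col[1])
  ci <- as.integer(candidate[1]); cj <- as.integer(candidate[2])
  sig <- cfg$psf_sigma
  if (is.null(window_half)) window_half <- max(3L, as.integer(ceiling(2.5 * sig)))
  failed <- data.frame(x_um = NA_real_, y_um = NA_real_, intensity = NA_real_,
                       background = NA_real_, precision_um = NA_real_, ok = FALSE)
  rows <- (ci - window_half):(ci + window_half)
  cols <- (cj - window_half):(cj + window_half)
  if (min(rows) < 1L || min(cols) < 1L ||
      max(rows) > nrow(frame) || max(cols) > ncol(frame))
    return(failed)  # window truncated by image edge: discard
  win <- frame[rows, cols]
  B0 <- median(c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)]))
  A0 <- max(win[window_half + 1L, window_half + 1L] - B0, 0)
  N0 <- max(A0 * 2 * pi * sig^2, 1)
  wsub <- pmax(win - B0, 0)
  tot <- sum(wsub)
  x0 <- if (tot > 0) sum(t(wsub) * (cols - 0.5)) / tot else cj - 0.5
  y0 <- if (tot > 0) sum(wsub * (rows - 0.5)) / tot else ci - 0.5

  resid_fn <- function(par) {
    as.numeric(win - gauss_window_model(rows, cols, par[1], par[2],
                                        par[3], par[4], sig))
  }
  lower <- c(min(cols) - 1, min(rows) - 1, 0, 0)
  upper <- c(max(cols), max(rows), Inf, Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(x0, y0, N0, max(B0, 0)),
                       lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  p <- fit$par
  if (p[3] <= 1e-3) return(failed)  # degenerate (flat) window: no photons
  # background-corrected precision estimate (per-axis, Mortensen-style)
  sa2 <- sig^2 + 1 / 12
  prec_px2 <- sa2 / p[3] * (16 / 9 + 8 * pi * sa2 * max(p[4], 0) / p[3])
  data.frame(x_um = p[1] * pixel_size, y_um = p[2] * pixel_size,
             intensity = p[3], background = p[4],
             precision_um = sqrt(prec_px2) * pixel_size, ok = TRUE)
}

#' Localize all spots in a movie
#'
#' Runs [detect_spots()] and [refine_subpixel()] on every frame of an image
#' stack and returns the localization table.
#'
#' @param movie Array `[ny, nx, n_frames]` (e.g. from [render_movie()] or
#'   [read_movie_tiff()]).
#' @param cfg A [detection_config()].
#' @param acq An [acquisition_config()] (pixel size).
#' @param mask Optional logical matrix applied to every frame.
#' @param cell_id Cell label stored with every localization.
#' @return A data.frame with `frame` (0-based), `x_um`, `y_um`,
#'   `intensity`, `precision_um`, `cell_id`. Candidates whose refinement
#'   failed are dropped.
#' @export
localize_movie <- function(movie, cfg, acq, mask = NULL, cell_id = "cell_1") {
  stopifnot(inherits(acq, "acquisition_config"))
  if (length(dim(movie)) == 2L) movie <- array(movie, dim = c(dim(movie), 1L))
  n_frames <- dim(movie)[3]
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    fr <- movie[, , f]
    cand <- detect_spots(fr, cfg, mask = mask)
    if (!nrow(cand)) next
    locs <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      refine_subpixel(fr, c(cand$row[i], cand$col[i]), cfg, acq$pixel_size)
    }))
    locs <- locs[locs$ok, , drop = FALSE]
    if (!nrow(locs)) next
    out[[f]] <- data.frame(frame = f - 1L, x_um = locs$x_um, y_um = locs$y_um,
                           intensity = locs$intensity,
                           precision_um = locs$precision_um,
                           cell_id = cell_id, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), precision_um = numeric(),
                      cell_id = character(), stringsAsFactors = FALSE)
  res
}
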