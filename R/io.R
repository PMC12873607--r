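# I/O round-tripping for trajectory tables, movies and configurations.
# Units are fixed by convention: coordinates in um, frames 0-based.

trajectory_required_cols <- c("trajectory_id", "frame", "x_um", "y_um", "cell_id")

validate_trajectory_table <- function(df) {
  miss <- setdiff(trajectory_required_cols, names(df))
  if (length(miss))
    stopf("trajectory table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!nrow(df)) return(invisible(df))
  DT <- data.table::as.data.table(df)
  bad <- as.data.frame(DT[, list(bad = any(diff(frame) <= 0), first_row = .I[1]),
                          by = c("cell_id", "trajectory_id")])
  bad <- bad[bad$bad, , drop = FALSE]
  if (nrow(bad))
    stopf("non-increasing frames within trajectory id(s): %s (first at input row %s)",
          paste(utils::head(bad$trajectory_id, 5), collapse = ", "),
          paste(utils::head(bad$first_row, 5), collapse = ", "))
  invisible(df)
}

#' Read a trajectory table
#'
#' Reads a trajectory CSV (columns `trajectory_id`, `frame`, `x_um`,
#' `y_um`, `cell_id`, optionally `true_state` for simulated data) and
#' validates that frames are strictly increasing within each trajectory.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_trajectory_table <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  validate_trajectory_table(df)
  df
}

#' Write a trajectory table
#'
#' @param trajs Trajectory data.frame (or an `spt_dataset`).
#' @param path Output CSV path.
#' @return `path`, invisibly. `write` then `read` is the identity on valid
#'   tables.
#' @export
write_trajectory_table <- function(trajs, path) {
  if (inherits(trajs, "spt_dataset")) trajs <- trajs$trajectories
  validate_trajectory_table(trajs)
  data.table::fwrite(trajs, path)
  invisible(path)
}

# full-well scaling for 16-bit TIFF storage of photon counts
.tiff_scale <- 65535

#' Write a movie as multi-page 16-bit TIFF
#'
#' @param movie Array `[ny, nx, n_frames]` of photon counts.
#' @param path Output path.
#' @param max_count Count value mapped to the 16-bit ceiling.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, max_count = .tiff_scale) {
  if (length(dim(movie)) == 2L) movie <- array(movie, dim = c(dim(movie), 1L))
  pages <- lapply(seq_len(dim(movie)[3]), function(f)
    pmin(pmax(movie[, , f] / max_count, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF path.
#' @param max_count Count value the 16-bit ceiling maps back to.
#' @return Array `[ny, nx, n_frames]` of photon counts.
#' @export
read_movie_tiff <- function(path, max_count = .tiff_scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * max_count
  arr
}

#' Write a pipeline or fit result as JSON
#'
#' @param x A list (e.g. fit results with config echo).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
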