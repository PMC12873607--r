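# End-to-end driver: simulate (or ingest) -> localize -> track -> fit ->
# summarize -> compare, with provenance recorded alongside every result.

#' Run the full tracking-analysis pipeline
#'
#' Executes the analysis stages in order. Input is either a movie (image
#' stack per cell) or trajectory tables (localization and tracking are then
#' skipped). Per-cell jump histograms are compiled and fitted, cells are
#' summarized with the minimum-data filter, and if the cells span exactly
#' two conditions, two-tailed t tests compare `F_bound`, `D_free1` and
#' `D_free2` between them. Any stage refusal (e.g. too few jumps) aborts
#' with that stage's diagnostic.
#'
#' @param cfg A [pipeline_config()].
#' @param input A list with either `trajectories` (a single trajectory
#'   data.frame covering one or more cells, split by `cell_id`) or `movies`
#'   (named list of arrays, one per cell).
#' @param conditions Optional named character vector mapping `cell_id` to
#'   condition label.
#' @return A list of class `spt_pipeline_result`: `fits` (per-cell
#'   `kinetic_fit`s), `summary` (per-cell table), `comparisons` (list of
#'   `group_comparison` per parameter, when two conditions are present) and
#'   `provenance` (config echo, seed, package version, config hash).
#' @export
run_pipeline <- function(cfg, input, conditions = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(input$trajectories) && is.null(input$movies))
    stopf("input must carry either trajectories or movies")

  if (!is.null(input$movies)) {
    cells <- names(input$movies)
    if (is.null(cells)) cells <- paste0("cell_", seq_along(input$movies))
    trajs <- do.call(rbind, lapply(seq_along(input$movies), function(i) {
      locs <- localize_movie(input$movies[[i]], cfg$detection, cfg$acq,
                             cell_id = cells[i])
      link_localizations(locs, cfg$linking)
    }))
  } else {
    trajs <- input$trajectories
    validate_trajectory_table(trajs)
  }
  if (is.null(trajs) || !nrow(trajs))
    stopf("fit stage refused: no trajectories available (minimum-data check)")

  by_cell <- split(trajs, trajs$cell_id)
  fits <- lapply(names(by_cell), function(cid) {
    tr <- by_cell[[cid]]
    hist <- compile_jump_histograms(tr, cfg$fit)
    fit <- fit_kinetic_model(hist, cfg$fit)
    list(cell_id = cid,
         condition = if (!is.null(conditions)) unname(conditions[cid]) else NA_character_,
         n_trajectories = length(unique(tr$trajectory_id)),
         fit = fit)
  })
  names(fits) <- names(by_cell)
  summary <- summarize_cells(fits, min_trajectories = cfg$min_trajectories)

  comparisons <- NULL
  conds <- unique(stats::na.omit(summary$condition))
  if (length(conds) == 2L && all(table(summary$condition) >= 2)) {
    comparisons <- lapply(c("F_bound", "D_free1", "D_free2"), function(par) {
      a <- summary[[par]][summary$condition == conds[1]]
      b <- summary[[par]][summary$condition == conds[2]]
      if (all(is.finite(a)) && all(is.finite(b)))
        compare_groups(a, b, mode = cfg$test_mode, labels = conds)
      else NULL
    })
    names(comparisons) <- c("F_bound", "D_free1", "D_free2")
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  structure(list(
    fits = fits, summary = summary, comparisons = comparisons,
    provenance = list(config = cfg, seed = cfg$seed,
                      package_version = as.character(packageVersion("sptkin")),
                      config_md5 = hash)
  ), class = "spt_pipeline_result")
}

#' Keep the late, subsampled part of a movie for visualization
#'
#' Retains every `keep_every`-th frame of the final `tail_seconds` of a
#' movie — the convention used to draw a readable subset of trajectories
#' (e.g. the last 4.5 s at roughly half the frame rate). Intended for
#' plotting only, never for fitting.
#'
#' @param movie Array `[ny, nx, n_frames]`.
#' @param acq An [acquisition_config()].
#' @param tail_seconds Length of the retained tail, s.
#' @param keep_every Frame subsampling factor.
#' @return The subsampled array, with attribute `frames` giving the
#'   retained original 0-based frame indices.
#' @export
subsample_movie_tail <- function(movie, acq, tail_seconds = 4.5, keep_every = 2L) {
  n <- dim(movie)[3]
  n_tail <- min(n, as.integer(floor(tail_seconds / acq$frame_interval + 1e-9)))
  frames <- seq.int(n - n_tail + 1L, n, by = keep_every)
  out <- movie[, , frames, drop = FALSE]
  attr(out, "frames") <- frames - 1L
  out
}
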