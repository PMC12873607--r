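# Per-cell aggregation of kinetic fits, two-sample comparisons, and
# bimodality assessment of per-cell parameter distributions.
#
# mclustBIC must be importFrom'd: Mclust() resolves it in the caller's
# environment.
#' @importFrom mclust Mclust mclustBIC
NULL

#' Summarize per-cell kinetic fits
#'
#' Applies the minimum-data filter and maps the surviving fits 1:1 to a
#' per-cell summary table of the quantities plotted and tested per
#' condition (state fractions, diffusion coefficients, data volumes).
#'
#' @param fits A list of per-cell records; each element is a list with
#'   `cell_id`, `fit` (a `kinetic_fit`), `n_trajectories`, and optionally
#'   `condition` and `replicate`.
#' @param min_trajectories Cells with fewer trajectories are excluded (and
#'   reported in the `excluded` attribute).
#' @return A data.frame with one row per passing cell: `cell_id`,
#'   `condition`, `replicate`, `n_trajectories`, `n_jumps`, `F_bound`,
#'   `F_free1`, `F_free2`, `D_bound`, `D_free1`, `D_free2`, `sigma`
#'   (two-state fits fill the `free2` columns with `NA`). Attribute
#'   `excluded` lists filtered cell ids.
#' @export
summarize_cells <- function(fits, min_trajectories = 500L) {
  ids <- vapply(fits, function(f) as.character(f$cell_id), character(1))
  if (anyDuplicated(ids)) stopf("duplicate cell_id: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ntr <- vapply(fits, function(f) as.numeric(f$n_trajectories), numeric(1))
  pass <- ntr >= min_trajectories
  if (any(!pass))
    message(sprintf("summarize_cells: excluded %d cell(s) below %d trajectories: %s",
                    sum(!pass), min_trajectories,
                    paste(ids[!pass], collapse = ", ")))
  rows <- lapply(which(pass), function(i) {
    rec <- fits[[i]]
    k <- rec$fit
    three <- k$n_states == 3L
    data.frame(
      cell_id = ids[i],
      condition = if (!is.null(rec$condition)) rec$condition else NA_character_,
      replicate = if (!is.null(rec$replicate)) rec$replicate else NA_character_,
      n_trajectories = ntr[i],
      n_jumps = k$n_jumps_used,
      F_bound = unname(k$fractions["bound"]),
      F_free1 = unname(if (three) k$fractions["free1"] else k$fractions["free"]),
      F_free2 = unname(if (three) k$fractions["free2"] else NA_real_),
      D_bound = unname(k$D["bound"]),
      D_free1 = unname(if (three) k$D["free1"] else k$D["free"]),
      D_free2 = unname(if (three) k$D["free2"] else NA_real_),
      sigma = k$sigma,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), condition = character(),
               replicate = character(), n_trajectories = numeric(),
               n_jumps = numeric(), F_bound = numeric(), F_free1 = numeric(),
               F_free2 = numeric(), D_bound = numeric(), D_free1 = numeric(),
               D_free2 = numeric(), sigma = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- ids[!pass]
  out
}

#' Two-sample comparison of per-cell values
#'
#' Two-tailed two-sample t test: pooled-variance Student by default, Welch
#' optionally. Degenerate inputs are handled explicitly: two groups with
#' zero variance and equal means give `t = 0, p = 1`; zero variance with
#' unequal means is reported as `p` below machine precision with a flag.
#'
#' @param a,b Numeric vectors (each `n >= 2`).
#' @param mode `"student"` (pooled variance) or `"welch"`.
#' @param labels Group labels, length 2.
#' @return An object of class `group_comparison`: group labels and sizes,
#'   `t`, `df`, two-tailed `p`, difference of means (`a - b`) with 95%
#'   confidence interval, and `degenerate` flag.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(2, 3, 4))
compare_groups <- function(a, b, mode = c("student", "welch"),
                           labels = c("a", "b")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stopf("groups must be finite")
  va <- var(a); vb <- var(b)
  diff_means <- mean(a) - mean(b)
  degenerate <- (va == 0 && vb == 0)
  if (degenerate) {
    if (diff_means == 0) {
      tt <- 0; df <- length(a) + length(b) - 2; p <- 1
      ci <- c(0, 0)
    } else {
      tt <- sign(diff_means) * Inf; df <- length(a) + length(b) - 2
      p <- .Machine$double.xmin
      ci <- c(diff_means, diff_means)
    }
  } else {
    ht <- t.test(a, b, var.equal = (mode == "student"),
                 alternative = "two.sided")
    tt <- unname(ht$statistic); df <- unname(ht$parameter)
    p <- ht$p.value; ci <- unname(ht$conf.int)
  }
  structure(list(labels = labels, n = c(length(a), length(b)),
                 mode = mode, t = tt, df = df, p = p,
                 diff_means = diff_means, conf_int = ci,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test (two-tailed): %s (n=%d) vs %s (n=%d)\n",
              x$mode, x$labels[1], x$n[1], x$labels[2], x$n[2]))
  cat(sprintf("  t = %.4f, df = %.4g, p = %.3g\n", x$t, x$df, x$p))
  cat(sprintf("  mean difference = %.4g [%.4g, %.4g]\n",
              x$diff_means, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Assess bimodality of a per-cell parameter distribution
#'
#' Fits 1- and 2-component Gaussian mixtures (unequal variances) and
#' declares the distribution bimodal when the 2-component model wins by BIC
#' *and* the component means are separated by more than 2 pooled standard
#' deviations. This is the operational criterion for phenotypes where a
#' treatment acts on only part of the cell population (e.g. S-phase-only
#' drug action making per-cell slow-diffusion coefficients bimodal).
#'
#' @param values Numeric vector of per-cell values, `n >= 10`.
#' @return A list: `bimodal` (flag), `weights`, `means`, `sds` of the
#'   2-component fit, `separation` (|mean difference| / pooled sd), and the
#'   BIC of both models.
#' @export
detect_bimodality <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10L)
    stopf("bimodality assessment needs n >= 10 (got %d)", length(values))
  m1 <- mclust::Mclust(values, G = 1, modelNames = "V", verbose = FALSE)
  m2 <- tryCatch(mclust::Mclust(values, G = 2, modelNames = "V", verbose = FALSE),
                 error = function(e) NULL)
  if (is.null(m2) || is.null(m2$parameters)) {
    return(list(bimodal = FALSE, weights = c(1, 0),
                means = c(mean(values), NA_real_),
                sds = c(sd(values), NA_real_),
                separation = 0, bic = c(one = m1$bic, two = NA_real_)))
  }
  w <- m2$parameters$pro
  mu <- m2$parameters$mean
  sig2 <- m2$parameters$variance$sigmasq
  if (length(sig2) == 1L) sig2 <- rep(sig2, 2L)
  pooled_sd <- sqrt(sum(w * sig2))
  separation <- abs(diff(mu)) / pooled_sd
  # mclust BIC: larger is better
  bimodal <- (m2$bic > m1$bic) && (separation > 2)
  list(bimodal = bimodal, weights = as.numeric(w), means = as.numeric(mu),
       sds = sqrt(sig2), separation = separation,
       bic = c(one = m1$bic, two = m2$bic))
}
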