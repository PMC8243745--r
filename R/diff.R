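#' The diff statistic for portal-vein-adjacent cells
#'
#' At equilibrium, every cell adjacent to a portal-vein cell is scored by a
#' z-score of its reporter level against the rest of the field:
#'
#' \deqn{diff = (R_{neighbor} - Ave) / SD}
#'
#' where `Ave` and `SD` are the mean and (population) standard deviation of
#' the reporter over all cells *except* the PV cells and their von Neumann
#' neighbors. The neighbor diffs are averaged first, and the log2 of that
#' average is taken for plotting; when the average is not positive, or the
#' field SD is zero (perfect homogeneity, diff infinite), the log2 value is a
#' sentinel (`NA` plus a reason) rendered as a cross in figures.
#'
#' With several PV cells, the scored set is the union of their von Neumann
#' neighborhoods minus the PV cells themselves, and the excluded set is the
#' union of PV cells and that neighborhood.
#'
#' @param state A [grid_state()] with at least one PV cell, normally at
#'   equilibrium (the caller's responsibility).
#' @param params A [simulation_params()]; supplies `diff_threshold`.
#' @return An object of class `diff_report`: a list with `ave`, `sd`,
#'   `neighbor_cells` (matrix of `(row, col)`), `neighbor_diffs`,
#'   `mean_diff`, `log2_mean_diff` (`NA` when sentinel), `sentinel` (`NA`,
#'   `"infinite"` or `"negative"`), and `cholangiocyte_calls`.
#' @examples
#' p <- simulation_params()
#' st <- random_initial_state(p, seed = 1, pv_cells = lattice_center(p$lattice))
#' eq <- run_to_equilibrium(st, p)
#' compute_diff(eq$final_state, p)
#' @export
compute_diff <- function(state, params) {
  if (!any(state$pv_mask)) {
    stop("diff statistic requires at least one PV cell", call. = FALSE)
  }
  lat <- lattice_spec(ncol(state$D), nrow(state$D))
  pv_cells <- which(state$pv_mask, arr.ind = TRUE)

  nb_mask <- matrix(FALSE, lat$height, lat$width)
  for (i in seq_len(nrow(pv_cells))) {
    nb_mask[von_neumann_neighbors(pv_cells[i, ], lat)] <- TRUE
  }
  nb_mask <- nb_mask & !state$pv_mask
  included <- !state$pv_mask & !nb_mask
  if (sum(included) < 2L) {
    stop("fewer than 2 cells left after excluding PV cells and their ",
         "neighbors", call. = FALSE)
  }

  r_in <- state$R[included]
  ave <- mean(r_in)
  sdev <- sqrt(mean((r_in - ave)^2))   # population SD

  nb_cells <- which(nb_mask, arr.ind = TRUE)
  ord <- order(nb_cells[, 1L], nb_cells[, 2L])
  nb_cells <- nb_cells[ord, , drop = FALSE]
  delta <- state$R[nb_cells] - ave
  diffs <- if (sdev > 0) delta / sdev else
    ifelse(delta > 0, Inf, ifelse(delta < 0, -Inf, 0))

  mean_diff <- mean(diffs)
  sentinel <- NA_character_
  log2_mean_diff <- NA_real_
  if (sdev == 0 || !is.finite(mean_diff)) {
    sentinel <- "infinite"
  } else if (mean_diff <= 0) {
    sentinel <- "negative"
  } else {
    log2_mean_diff <- log2(mean_diff)
  }

  structure(list(
    ave = ave, sd = sdev,
    neighbor_cells = nb_cells,
    neighbor_diffs = diffs,
    mean_diff = mean_diff,
    log2_mean_diff = log2_mean_diff,
    sentinel = sentinel,
    cholangiocyte_calls = classify_cholangiocytes(diffs, params)
  ), class = "diff_report")
}

#' Cholangiocyte classification of neighbor diffs
#'
#' A PV-adjacent cell is called a cholangiocyte when its diff is strictly
#' greater than the threshold (default 2, chosen so that calls stay rare, as
#' cholangiocytes are a small fraction of liver cells). `diff == threshold`
#' is a negative call.
#'
#' @param diffs A `diff_report` or a numeric vector of diff values.
#' @param params A [simulation_params()]; supplies `diff_threshold`.
#' @return Logical vector, one call per neighbor.
#' @export
classify_cholangiocytes <- function(diffs, params) {
  if (inherits(diffs, "diff_report")) diffs <- diffs$neighbor_diffs
  diffs > params$diff_threshold
}

#' @export
print.diff_report <- function(x, ...) {
  cat("<diff_report>\n")
  cat(sprintf("  field: Ave = %.6g, SD = %.6g over included cells\n",
              x$ave, x$sd))
  cat(sprintf("  neighbor diffs: %s\n",
              paste(signif(x$neighbor_diffs, 4L), collapse = ", ")))
  if (is.na(x$sentinel)) {
    cat(sprintf("  mean diff = %.6g, log2 = %.4f\n",
                x$mean_diff, x$log2_mean_diff))
  } else {
    cat(sprintf("  mean diff sentinel: %s (cross)\n", x$sentinel))
  }
  cat(sprintf("  cholangiocyte calls: %d of %d\n",
              sum(x$cholangiocyte_calls), length(x$cholangiocyte_calls)))
  invisible(x)
}
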