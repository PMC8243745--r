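#' Full single-run pipeline: initial state, equilibrium, diff
#'
#' Generates a seeded random initial state, places the portal-vein cell(s),
#' integrates to equilibrium and — when PV cells are present — computes the
#' diff report. This is the unit of work of the parameter sweeps and of the
#' command-line `simulate` verb.
#'
#' @param params A [simulation_params()].
#' @param seed Integer seed for the initial state (or `NULL`).
#' @param pv_cells PV cell positions (`(row, col)` matrix), `NULL` for none,
#'   or `"center"` (default) for a single PV cell at the lattice centre.
#' @param engine Passed to [run_to_equilibrium()].
#' @return A list of class `pv_run` with `params`, `seed`, `pv_cells`,
#'   `trajectory` (a `trajectory_result`) and `report` (a `diff_report`, or
#'   `NULL` when there are no PV cells).
#' @examples
#' run <- simulate_pv_case(simulation_params(), seed = 1)
#' run$report$log2_mean_diff
#' @export
simulate_pv_case <- function(params, seed = NULL, pv_cells = "center",
                             engine = "cpp") {
  if (identical(pv_cells, "center")) {
    pv_cells <- lattice_center(params$lattice)
  }
  initial <- random_initial_state(params, seed = seed, pv_cells = pv_cells)
  traj <- run_to_equilibrium(initial, params, engine = engine)
  report <- if (any(initial$pv_mask)) {
    compute_diff(traj$final_state, params)
  }
  structure(list(params = params, seed = seed, pv_cells = pv_cells,
                 trajectory = traj, report = report),
            class = "pv_run")
}

#' @export
print.pv_run <- function(x, ...) {
  cat(sprintf("<pv_run> seed %s, %s\n",
              if (is.null(x$seed)) "none" else format(x$seed),
              if (x$trajectory$converged) "converged" else "NOT converged"))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Coefficient of variation of the equilibrium reporter field
#'
#' `sd(R) / mean(R)` over all non-PV cells; a scalar summary of how
#' heterogeneous the reporter distribution is (small for an almost
#' homogeneous field, large for a fine-grained salt-and-pepper pattern).
#'
#' @param state A [grid_state()].
#' @return A single number (NaN if the mean is zero).
#' @export
reporter_cv <- function(state) {
  r <- state$R[!state$pv_mask]
  stats::sd(r) / mean(r)
}
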