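#' One explicit-Euler step of the LIMI system
#'
#' Synchronous update: all three derivatives are evaluated on the pre-step
#' state via [limi_rhs()], every field is advanced by `dt`, negative values
#' are clipped to zero, and the portal-vein Delta clamp is reapplied. This
#' pure-R step is the reference definition of the update rule; the compiled
#' integration loop used by [run_to_equilibrium()] must agree with it
#' step-for-step.
#'
#' @param state A [grid_state()].
#' @param params A [simulation_params()].
#' @return The updated [grid_state()] with `t` advanced by `dt`.
#' @export
limi_step <- function(state, params) {
  d <- limi_rhs(state, params)
  dt <- params$dt
  # pmax(x, 0) rather than pmax(0, x): the result keeps x's dim attributes
  D <- pmax(state$D + dt * d$dD, 0)
  N <- pmax(state$N + dt * d$dN, 0)
  R <- pmax(state$R + dt * d$dR, 0)
  if (params$pv_freeze_NR) {
    N[state$pv_mask] <- state$N[state$pv_mask]
    R[state$pv_mask] <- state$R[state$pv_mask]
  }
  bad <- !is.finite(D) | !is.finite(N) | !is.finite(R)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    fld <- if (!is.finite(D[i[1L], i[2L]])) "D"
      else if (!is.finite(N[i[1L], i[2L]])) "N" else "R"
    stop(sprintf("numerical blowup: field %s non-finite at cell (%d, %d)",
                 fld, i[1L], i[2L]), call. = FALSE)
  }
  st <- state
  st$D <- D; st$N <- N; st$R <- R
  st$t <- state$t + dt
  clamp_pv(st, params)
}

#' Convergence residual of a state
#'
#' The maximum absolute derivative (or, for `residual_type = "increment"`,
#' `dt` times it) over all three fields of every non-portal-vein cell. When
#' the state has no PV cells, all cells are included.
#'
#' @param state A [grid_state()].
#' @param params A [simulation_params()].
#' @return A single nonnegative number.
#' @export
residual <- function(state, params) {
  d <- limi_rhs(state, params)
  keep <- !state$pv_mask
  r <- max(abs(d$dD[keep]), abs(d$dN[keep]), abs(d$dR[keep]))
  if (params$residual_type == "increment") r * params$dt else r
}

#' Integrate the LIMI system to equilibrium
#'
#' Repeats [limi_step()] until the convergence residual of every non-PV cell
#' falls below `params$residual_tol`, or `params$max_steps` updates have been
#' applied. The residual is evaluated on the pre-step derivatives, so a state
#' returned as converged re-evaluates below the tolerance. Non-convergence is
#' reported through the `converged` flag, never silently accepted.
#'
#' @param initial A [grid_state()] (PV clamp already applied, as
#'   [random_initial_state()] does).
#' @param params A [simulation_params()].
#' @param engine `"cpp"` (default, compiled loop) or `"R"` (the reference
#'   pure-R loop; identical results, far slower).
#' @param snapshot_every If positive, record a copy of the state every this
#'   many steps (debugging aid); snapshots are returned in the result.
#' @return An object of class `trajectory_result`: a list with
#'   `final_state`, `steps`, `final_residual`, `converged`, and `snapshots`
#'   (possibly empty).
#' @examples
#' p <- simulation_params(beta_D = 1e-9, max_steps = 2e5)
#' st <- homogeneous_state(0, 0, p)
#' run_to_equilibrium(st, p)$converged
#' @export
run_to_equilibrium <- function(initial, params,
                               engine = c("cpp", "R"),
                               snapshot_every = 0L) {
  engine <- match.arg(engine)
  stopifnot(inherits(initial, "grid_state"),
            inherits(params, "simulation_params"))
  snapshot_every <- as.integer(snapshot_every)
  snapshots <- list()

  if (engine == "R") {
    state <- initial
    steps <- 0
    repeat {
      res <- residual(state, params)
      if (res < params$residual_tol) {
        converged <- TRUE
        break
      }
      if (steps >= params$max_steps) {
        converged <- FALSE
        break
      }
      state <- limi_step(state, params)
      steps <- steps + 1
      if (snapshot_every > 0L && steps %% snapshot_every == 0L) {
        snapshots[[length(snapshots) + 1L]] <- state
      }
    }
    out <- list(final_state = state, steps = steps, final_residual = res,
                converged = converged, snapshots = snapshots)
    return(structure(out, class = "trajectory_result"))
  }

  run_chunk <- function(st, cap) {
    k <- .limi_run_cpp(
      st$D, st$N, st$R, st$pv_mask,
      params$beta_N, params$beta_D, params$beta_R,
      params$m, params$n, params$k_t, params$k_c,
      params$gamma, params$gamma_R, params$k_RS,
      params$pv_delta, params$dt, params$residual_tol,
      cap, params$pv_freeze_NR,
      params$residual_type == "increment"
    )
    list(state = grid_state(k$D, k$N, k$R, st$pv_mask,
                            t = st$t + k$steps * params$dt),
         steps = k$steps, residual = k$residual, converged = k$converged)
  }

  if (snapshot_every <= 0L) {
    k <- run_chunk(initial, params$max_steps)
    out <- list(final_state = k$state, steps = k$steps,
                final_residual = k$residual, converged = k$converged,
                snapshots = snapshots)
    return(structure(out, class = "trajectory_result"))
  }

  state <- initial
  steps <- 0
  repeat {
    cap <- min(snapshot_every, params$max_steps - steps)
    k <- run_chunk(state, cap)
    state <- k$state
    steps <- steps + k$steps
    if (k$converged || steps >= params$max_steps) {
      out <- list(final_state = state, steps = steps,
                  final_residual = k$residual, converged = k$converged,
                  snapshots = snapshots)
      return(structure(out, class = "trajectory_result"))
    }
    snapshots[[length(snapshots) + 1L]] <- state
  }
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> %s after %g steps (t = %g), residual %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$steps, x$final_state$t, x$final_residual))
  invisible(x)
}
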