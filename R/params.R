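#' Simulation parameters for the LIMI model
#'
#' Collects the rate constants of the Lateral Inhibition with Mutual
#' Inactivation (LIMI) model, the portal-vein clamp, and the numerical
#' controls of the explicit-Euler integrator. Defaults follow the standard
#' parameterisation of the model; only the production rates `beta_N` and
#' `beta_D`, the feedback exponent `m` and the Hill coefficient `n` are
#' routinely varied.
#'
#' @param beta_N Notch production rate (concentration/time).
#' @param beta_D Delta production rate.
#' @param beta_R Reporter (Notch target gene) production rate.
#' @param m Feedback-strength exponent of the lateral-inhibition term
#'   `beta_D / (1 + R^m)`; must be >= 1.
#' @param n Hill coefficient of reporter induction; must be >= 1.
#' @param k_t Trans-interaction constant; its inverse scales the strength of
#'   ligand-receptor binding between adjacent cells.
#' @param k_c Cis-interaction constant; its inverse scales mutual
#'   inactivation of Delta and Notch within one cell.
#' @param gamma Degradation rate shared by Notch and Delta.
#' @param gamma_R Degradation rate of the reporter.
#' @param k_RS Affinity constant of reporter induction (denominator offset of
#'   the Hill term).
#' @param pv_delta Clamped Delta value of portal-vein (PV) cells; held fixed
#'   in place of the Delta ODE.
#' @param dt Euler integration step (model time).
#' @param residual_tol Convergence threshold: equilibrium is declared when
#'   every derivative of every non-PV cell is below this in absolute value.
#' @param max_steps Iteration cap; non-convergence within the cap is reported,
#'   never silently accepted.
#' @param lattice A [lattice_spec()].
#' @param init_mean,init_sd Mean and SD of the normal distribution used for
#'   the random initial Delta and Notch fields.
#' @param diff_threshold Cholangiocyte cutoff: a PV-adjacent cell with diff
#'   strictly above this is called a cholangiocyte.
#' @param pv_freeze_NR If `TRUE`, PV cells' Notch and reporter are frozen at
#'   their initial values as well; by default only Delta is clamped and N and
#'   R of PV cells keep evolving under their own ODEs.
#' @param residual_type `"derivative"` (default) checks convergence on the
#'   raw derivative magnitudes; `"increment"` on the per-step increments
#'   `dt * derivative`, which is looser by a factor `1/dt`.
#' @return An object of class `simulation_params` (a validated named list).
#' @examples
#' p <- simulation_params(beta_N = 100, beta_D = 10, m = 1, n = 3)
#' p$k_RS
#' @export
simulation_params <- function(beta_N = 100,
                              beta_D = 10,
                              beta_R = 1e6,
                              m = 1,
                              n = 3,
                              k_t = 1,
                              k_c = 0.1,
                              gamma = 1,
                              gamma_R = 1,
                              k_RS = 3e5,
                              pv_delta = 1000,
                              dt = 1e-4,
                              residual_tol = 1e-3,
                              max_steps = 4e7,
                              lattice = lattice_spec(20L, 20L),
                              init_mean = 1,
                              init_sd = 0.1,
                              diff_threshold = 2,
                              pv_freeze_NR = FALSE,
                              residual_type = c("derivative", "increment")) {
  residual_type <- match.arg(residual_type)
  if (!inherits(lattice, "lattice_spec")) {
    stop("lattice must be a lattice_spec object", call. = FALSE)
  }
  p <- list(
    beta_N = beta_N, beta_D = beta_D, beta_R = beta_R,
    m = m, n = n, k_t = k_t, k_c = k_c,
    gamma = gamma, gamma_R = gamma_R, k_RS = k_RS,
    pv_delta = pv_delta, dt = dt, residual_tol = residual_tol,
    max_steps = max_steps, lattice = lattice,
    init_mean = init_mean, init_sd = init_sd,
    diff_threshold = diff_threshold,
    pv_freeze_NR = isTRUE(pv_freeze_NR),
    residual_type = residual_type
  )
  validate_params(p)
  structure(p, class = "simulation_params")
}

validate_params <- function(p) {
  pos <- c("beta_R", "k_t", "k_c", "gamma", "gamma_R",
           "k_RS", "pv_delta", "dt", "residual_tol", "max_steps")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter '%s' must be a single finite positive number",
                   nm), call. = FALSE)
    }
  }
  # production rates may be zero (e.g. the analytic beta_D = 0 limit)
  for (nm in c("beta_N", "beta_D")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("parameter '%s' must be a single finite nonnegative number",
                   nm), call. = FALSE)
    }
  }
  for (nm in c("m", "n")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1) {
      stop(sprintf("exponent '%s' must be >= 1", nm), call. = FALSE)
    }
  }
  if (!is.numeric(p$init_sd) || p$init_sd < 0) {
    stop("init_sd must be >= 0", call. = FALSE)
  }
  if (!is.numeric(p$init_mean) || !is.finite(p$init_mean)) {
    stop("init_mean must be finite", call. = FALSE)
  }
  invisible(p)
}

#' Modified copy of a parameter set
#'
#' @param params A [simulation_params()] object.
#' @param ... Named fields to replace (e.g. `beta_N = 10`).
#' @return A re-validated `simulation_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "simulation_params"))
  mods <- list(...)
  if (length(mods) == 0L) return(params)
  if (is.null(names(mods)) || any(names(mods) == "")) {
    stop("all replacement fields must be named", call. = FALSE)
  }
  unknown <- setdiff(names(mods), names(params))
  if (length(unknown) > 0L) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(mods)] <- mods
  validate_params(p)
  structure(p, class = "simulation_params")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("<simulation_params>\n")
  cat(sprintf("  production : beta_N=%g beta_D=%g beta_R=%g\n",
              x$beta_N, x$beta_D, x$beta_R))
  cat(sprintf("  exponents  : m=%g n=%g\n", x$m, x$n))
  cat(sprintf("  constants  : k_t=%g k_c=%g gamma=%g gamma_R=%g k_RS=%g\n",
              x$k_t, x$k_c, x$gamma, x$gamma_R, x$k_RS))
  cat(sprintf("  PV clamp   : D=%g (freeze N,R: %s)\n",
              x$pv_delta, x$pv_freeze_NR))
  cat(sprintf("  numerics   : dt=%g tol=%g (%s) max_steps=%g\n",
              x$dt, x$residual_tol, x$residual_type, x$max_steps))
  cat(sprintf("  lattice    : %d x %d; init N(%g, %g); diff cutoff %g\n",
              x$lattice$height, x$lattice$width, x$init_mean, x$init_sd,
              x$diff_threshold))
  invisible(x)
}
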