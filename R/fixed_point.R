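#' Right-hand side of the spatially homogeneous LIMI system
#'
#' On a torus a perfectly homogeneous field stays homogeneous, and the
#' neighbor averages equal the cell's own values, so the lattice system
#' collapses to three scalar ODEs in `(D, N, R)`. This function evaluates
#' their right-hand sides; its roots are the homogeneous fixed points.
#'
#' @param x Numeric vector `c(D, N, R)`, nonnegative.
#' @param params A [simulation_params()].
#' @return Numeric vector `c(dD, dN, dR)`.
#' @export
homogeneous_rhs <- function(x, params) {
  D <- x[1L]; N <- x[2L]; R <- x[3L]
  trans <- N * D
  cis <- N * D / params$k_c
  s <- trans^params$n
  hill <- if (is.finite(s)) s / (params$k_RS + s) else 1
  c(
    params$beta_D / (1 + R^params$m) - params$gamma * D -
      D * N / params$k_t - cis,
    params$beta_N - params$gamma * N - trans / params$k_t - cis,
    params$beta_R * hill - params$gamma_R * R
  )
}

#' Homogeneous fixed points by an independent root-finder
#'
#' Finds nonnegative roots of the homogeneous three-equation system with a
#' Newton-type nonlinear solver ([pracma::fsolve()]) started from a grid of
#' initial guesses, entirely independent of the Euler integration path. At
#' a fixed point the reporter equation gives `R` algebraically from `N * D`,
#' so the solve is performed on the reduced `(D, N)` system with `R`
#' substituted, which is much better conditioned than the raw 3-D system
#' (where `R` can be of order `beta_R / gamma_R`).
#'
#' @param params A [simulation_params()].
#' @param starts Optional matrix of `(D, N)` starting points; by default a
#'   log-spaced grid spanning `1e-4` to `beta/gamma` for each variable.
#' @param root_tol Roots are kept when the maximum absolute value of the
#'   full 3-D right-hand side is below this (default `1e-6`).
#' @return A matrix with columns `D`, `N`, `R`, one distinct nonnegative
#'   root per row (possibly zero rows if the solver finds none).
#' @export
homogeneous_fixed_points <- function(params, starts = NULL,
                                     root_tol = 1e-6) {
  R_of <- function(D, N) {
    s <- (N * D)^params$n
    hill <- if (is.finite(s)) s / (params$k_RS + s) else 1
    params$beta_R * hill / params$gamma_R
  }
  # reduced system: log-parameterised so the solver stays in D, N > 0
  f2 <- function(u) {
    D <- exp(u[1L]); N <- exp(u[2L])
    R <- R_of(D, N)
    r <- homogeneous_rhs(c(D, N, R), params)
    r[1:2]
  }
  if (is.null(starts)) {
    dmax <- max(params$beta_D / params$gamma, 1e-3)
    nmax <- max(params$beta_N / params$gamma, 1e-3)
    dg <- exp(seq(log(1e-4), log(dmax), length.out = 5L))
    ng <- exp(seq(log(1e-4), log(nmax), length.out = 5L))
    starts <- as.matrix(expand.grid(D = dg, N = ng))
  }
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    u0 <- log(pmax(starts[i, 1:2], 1e-12))
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(f2, u0, maxiter = 200, tol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(sol)) next
    D <- exp(sol$x[1L]); N <- exp(sol$x[2L])
    R <- R_of(D, N)
    if (!all(is.finite(c(D, N, R)))) next
    if (max(abs(homogeneous_rhs(c(D, N, R), params))) > root_tol) next
    roots[[length(roots) + 1L]] <- c(D = D, N = N, R = R)
  }
  if (length(roots) == 0L) {
    return(matrix(numeric(0), 0L, 3L,
                  dimnames = list(NULL, c("D", "N", "R"))))
  }
  m <- do.call(rbind, roots)
  # deduplicate to relative precision
  key <- apply(m, 1L, function(r) paste(signif(r, 8L), collapse = "/"))
  m[!duplicated(key), , drop = FALSE]
}

#' Homogeneous fixed point nearest to a reference state
#'
#' Convenience wrapper around [homogeneous_fixed_points()]: returns the root
#' closest (in maximum per-variable absolute difference) to a reference
#' `(D, N, R)` triple, typically a simulated equilibrium being checked.
#'
#' @param params A [simulation_params()].
#' @param reference Numeric vector `c(D, N, R)`.
#' @param ... Passed to [homogeneous_fixed_points()].
#' @return A named vector `c(D, N, R)` or `NULL` if no root was found.
#' @export
nearest_fixed_point <- function(params, reference, ...) {
  m <- homogeneous_fixed_points(params, ...)
  if (nrow(m) == 0L) return(NULL)
  d <- apply(m, 1L, function(r) max(abs(r - reference)))
  m[which.min(d), ]
}
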