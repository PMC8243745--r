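#' Per-cell state of the lattice
#'
#' Bundles the three concentration fields of the LIMI model — Delta (`D`),
#' Notch (`N`) and reporter (`R`) — together with the portal-vein mask and
#' the elapsed model time. All fields are `height x width` matrices and must
#' be nonnegative everywhere (the integrator clips negatives to zero).
#'
#' @param D,N,R Nonnegative numeric matrices of identical shape.
#' @param pv_mask Logical matrix of the same shape flagging portal-vein
#'   cells, or `NULL` for none.
#' @param t Elapsed model time.
#' @return An object of class `grid_state`.
#' @export
grid_state <- function(D, N, R, pv_mask = NULL, t = 0) {
  if (!is.matrix(D) || !is.matrix(N) || !is.matrix(R)) {
    stop("D, N and R must be matrices", call. = FALSE)
  }
  dm <- dim(D)
  if (!identical(dm, dim(N)) || !identical(dm, dim(R))) {
    stop("D, N and R must share the same dimensions", call. = FALSE)
  }
  if (is.null(pv_mask)) {
    pv_mask <- matrix(FALSE, dm[1L], dm[2L])
  }
  if (!is.logical(pv_mask) || !identical(dim(pv_mask), dm)) {
    stop("pv_mask must be a logical matrix matching the fields",
         call. = FALSE)
  }
  for (nm in c("D", "N", "R")) {
    f <- get(nm)
    if (anyNA(f) || any(f < 0)) {
      stop(sprintf("field %s contains negative or missing values", nm),
           call. = FALSE)
    }
  }
  structure(list(D = D, N = N, R = R, pv_mask = pv_mask, t = t),
            class = "grid_state")
}

#' @export
print.grid_state <- function(x, ...) {
  cat(sprintf("<grid_state> %d x %d, %d PV cell(s), t = %g\n",
              nrow(x$D), ncol(x$D), sum(x$pv_mask), x$t))
  cat(sprintf("  D in [%.4g, %.4g]  N in [%.4g, %.4g]  R in [%.4g, %.4g]\n",
              min(x$D), max(x$D), min(x$N), max(x$N), min(x$R), max(x$R)))
  invisible(x)
}

pv_mask_from_cells <- function(pv_cells, lattice) {
  mask <- matrix(FALSE, lattice$height, lattice$width)
  if (is.null(pv_cells) || (is.matrix(pv_cells) && nrow(pv_cells) == 0L)) {
    return(mask)
  }
  cells <- check_cells(pv_cells, lattice)
  if (anyDuplicated(cells) > 0L) {
    stop("duplicate PV cells", call. = FALSE)
  }
  mask[cells] <- TRUE
  mask
}

#' Clamp portal-vein cells' Delta
#'
#' Sets `D` of every PV cell to `params$pv_delta`, leaving all other values
#' untouched. PV cells model portal-vein smooth muscle with persistently very
#' high Jagged1 (Delta-family ligand) expression; their Delta is held fixed
#' in place of the Delta ODE. Idempotent.
#'
#' @param state A [grid_state()].
#' @param params A [simulation_params()].
#' @return The state with PV Delta clamped.
#' @export
clamp_pv <- function(state, params) {
  state$D[state$pv_mask] <- params$pv_delta
  state
}

#' Seeded random initial state
#'
#' Draws the initial Delta and Notch of every cell independently from
#' `Normal(init_mean, init_sd)` (negative draws clipped to zero), sets the
#' reporter to zero everywhere, and applies the PV clamp. The same seed gives
#' a bit-identical state.
#'
#' @param params A [simulation_params()]; supplies the lattice and the
#'   initial-condition mean and SD.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param pv_cells Portal-vein cells as a matrix/data.frame with `(row, col)`
#'   rows, or `NULL` for none. Must be pairwise distinct and in range.
#' @return A [grid_state()] at `t = 0`.
#' @examples
#' p <- simulation_params()
#' s <- random_initial_state(p, seed = 1, pv_cells = lattice_center(p$lattice))
#' sum(s$pv_mask)
#' @export
random_initial_state <- function(params, seed = NULL, pv_cells = NULL) {
  lat <- params$lattice
  if (!is.null(seed)) set.seed(as.integer(seed))
  nc <- n_cells(lat)
  D <- matrix(pmax(0, rnorm(nc, params$init_mean, params$init_sd)),
              lat$height, lat$width)
  N <- matrix(pmax(0, rnorm(nc, params$init_mean, params$init_sd)),
              lat$height, lat$width)
  R <- matrix(0, lat$height, lat$width)
  st <- grid_state(D, N, R, pv_mask_from_cells(pv_cells, lat), t = 0)
  clamp_pv(st, params)
}

#' Homogeneous deterministic state
#'
#' A fixture builder: every cell holds the same Delta and Notch value, the
#' reporter is zero, and there are no PV cells. Useful for symmetry tests and
#' for comparing the integrator against the homogeneous fixed point.
#'
#' @param value_D,value_N Nonnegative scalars.
#' @param params A [simulation_params()].
#' @return A [grid_state()].
#' @export
homogeneous_state <- function(value_D, value_N, params) {
  if (value_D < 0 || value_N < 0) {
    stop("homogeneous field values must be nonnegative", call. = FALSE)
  }
  lat <- params$lattice
  grid_state(matrix(value_D, lat$height, lat$width),
             matrix(value_N, lat$height, lat$width),
             matrix(0, lat$height, lat$width))
}
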