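#' Deterministic per-cell seed derivation
#'
#' Expands one master seed into `n` distinct sub-seeds, independent of the
#' order in which sweep cells are later evaluated.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

run_sweep_cell <- function(params, seed, engine = "cpp") {
  out <- list(seed = seed, log2 = NA_real_, mean_diff = NA_real_,
              converged = NA, steps = NA_real_, code = "error")
  res <- tryCatch(simulate_pv_case(params, seed = seed, engine = engine),
                  error = function(e) e)
  if (inherits(res, "error")) {
    out$code <- paste0("error: ", conditionMessage(res))
    return(out)
  }
  out$converged <- res$trajectory$converged
  out$steps <- res$trajectory$steps
  out$mean_diff <- res$report$mean_diff
  if (!res$trajectory$converged) {
    out$code <- "nonconverged"
  } else if (!is.na(res$report$sentinel)) {
    out$code <- res$report$sentinel
  } else {
    out$code <- "ok"
    out$log2 <- res$report$log2_mean_diff
  }
  out
}

#' Two-dimensional production-rate sweep
#'
#' For every pair of Notch and Delta production rates, runs the full
#' pipeline — seeded random initial state, one central PV cell, integration
#' to equilibrium, diff statistic — and records the log2 of the averaged
#' neighbor diff, or a sentinel code. Sentinels arise from an exactly
#' homogeneous field (`"infinite"`), a non-positive averaged diff
#' (`"negative"`), a run hitting the step cap (`"nonconverged"`), or a
#' numerical failure (`"error"`); all are rendered as crosses in the heatmap.
#' Per-cell failures never abort the sweep.
#'
#' @param beta_N_values,beta_D_values Positive, nonempty vectors of
#'   production rates (rows and columns of the grid respectively).
#' @param m,n Feedback exponent and Hill coefficient of this panel.
#' @param base_params A [simulation_params()] providing everything else.
#' @param master_seed Master seed; per-cell seeds derive from it.
#' @param seed_policy `"derived"` (default): distinct per-cell sub-seeds from
#'   the master seed; `"fixed"`: the master seed reused identically in every
#'   cell.
#' @param engine Passed to [run_to_equilibrium()].
#' @return An object of class `sweep_grid`: a list with `beta_N_values`,
#'   `beta_D_values`, `panel_params` (`c(m, n)`), and matrices `log2`
#'   (`NA` where sentinel), `code`, `seeds`, `steps` of dimension
#'   `length(beta_N_values) x length(beta_D_values)`.
#' @export
sweep_2d <- function(beta_N_values, beta_D_values, m, n, base_params,
                     master_seed = 1L,
                     seed_policy = c("derived", "fixed"),
                     engine = "cpp") {
  seed_policy <- match.arg(seed_policy)
  if (length(beta_N_values) == 0L || length(beta_D_values) == 0L ||
      any(beta_N_values <= 0) || any(beta_D_values <= 0)) {
    stop("production-rate axes must be nonempty and positive", call. = FALSE)
  }
  nr <- length(beta_N_values)
  nc <- length(beta_D_values)
  seeds <- if (seed_policy == "derived") {
    matrix(derive_seeds(master_seed, nr * nc), nr, nc)
  } else {
    matrix(as.integer(master_seed), nr, nc)
  }
  log2m <- matrix(NA_real_, nr, nc)
  codem <- matrix(NA_character_, nr, nc)
  stepsm <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      p <- update_params(base_params, beta_N = beta_N_values[i],
                         beta_D = beta_D_values[j], m = m, n = n)
      cell <- run_sweep_cell(p, seeds[i, j], engine = engine)
      log2m[i, j] <- cell$log2
      codem[i, j] <- cell$code
      stepsm[i, j] <- cell$steps
    }
  }
  structure(list(beta_N_values = beta_N_values,
                 beta_D_values = beta_D_values,
                 panel_params = c(m = m, n = n),
                 log2 = log2m, code = codem, seeds = seeds,
                 steps = stepsm),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("<sweep_grid> %d x %d (beta_N x beta_D), m = %g, n = %g\n",
              nrow(x$log2), ncol(x$log2),
              x$panel_params["m"], x$panel_params["n"]))
  cat(sprintf("  finite cells: %d, sentinels: %d\n",
              sum(!is.na(x$log2)), sum(is.na(x$log2))))
  invisible(x)
}

#' Parameters eligible for one-dimensional sensitivity sweeps
#' @return Character vector of parameter names.
#' @export
sweepable_params <- function() {
  c("beta_R", "k_t", "k_c", "gamma", "gamma_R", "k_RS", "pv_delta", "dt")
}

#' One-dimensional sensitivity sweep
#'
#' Varies a single fixed-rate parameter over a set of values (all other
#' parameters at their base values, including the production rates) and runs
#' the full PV pipeline for each value and seed.
#'
#' @param param_name One of [sweepable_params()].
#' @param values Positive values to sweep over, in order.
#' @param base_params A [simulation_params()].
#' @param seeds Integer vector of seeds; every value is run once per seed.
#' @param engine Passed to [run_to_equilibrium()].
#' @return A data.frame with one row per `(value, seed)`: columns `param`,
#'   `value`, `seed`, `log2_mean_diff` (`NA` where sentinel), `mean_diff`,
#'   `code`, `converged`, `steps`.
#' @export
sweep_1d <- function(param_name, values, base_params, seeds = 1L,
                     engine = "cpp") {
  if (!param_name %in% sweepable_params()) {
    stop("unknown sweep parameter '", param_name, "'; must be one of: ",
         paste(sweepable_params(), collapse = ", "), call. = FALSE)
  }
  if (length(values) == 0L || any(values <= 0)) {
    stop("sweep values must be nonempty and positive", call. = FALSE)
  }
  rows <- list()
  for (v in values) {
    args <- stats::setNames(list(v), param_name)
    p <- do.call(update_params, c(list(base_params), args))
    for (s in seeds) {
      cell <- run_sweep_cell(p, s, engine = engine)
      rows[[length(rows) + 1L]] <- data.frame(
        param = param_name, value = v, seed = s,
        log2_mean_diff = cell$log2, mean_diff = cell$mean_diff,
        code = cell$code, converged = cell$converged, steps = cell$steps,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Default log-spaced sweep axis
#'
#' @param from,to Positive endpoints.
#' @param length.out Number of points.
#' @return Numeric vector, log-spaced inclusive of both endpoints.
#' @export
log_axis <- function(from = 1, to = 1000, length.out = 10L) {
  exp(seq(log(from), log(to), length.out = length.out))
}
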