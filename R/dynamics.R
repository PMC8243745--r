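#' Right-hand sides of the LIMI ODE system
#'
#' Evaluates, for every cell `i`, the three coupled derivatives of the
#' Lateral Inhibition with Mutual Inactivation model:
#'
#' \deqn{dN_i/dt = \beta_N - \gamma N_i - N_i \langle D_j\rangle_i / k_t -
#'   N_i D_i / k_c}
#' \deqn{dR_i/dt = \beta_R (N_i \langle D_j\rangle_i)^n /
#'   (k_{RS} + (N_i \langle D_j\rangle_i)^n) - \gamma_R R_i}
#' \deqn{dD_i/dt = \beta_D / (1 + R_i^m) - \gamma D_i -
#'   D_i \langle N_j\rangle_i / k_t - N_i D_i / k_c}
#'
#' where \eqn{\langle\cdot\rangle_i} is the von Neumann neighbor average.
#' Notch is consumed by trans-interaction with neighboring Delta and by
#' cis-inactivation with the cell's own Delta; the reporter is induced by the
#' trans signal through a Hill function (note the denominator offset is
#' `k_RS`, not `k_RS^n`); Delta production is laterally inhibited by the
#' reporter and Delta is consumed by the same trans and cis terms. For
#' portal-vein cells the Delta derivative is reported as zero, since their
#' Delta is clamped.
#'
#' @param state A [grid_state()] with nonnegative fields.
#' @param params A [simulation_params()].
#' @return A list of matrices `dD`, `dN`, `dR`.
#' @export
limi_rhs <- function(state, params) {
  if (any(state$D < 0) || any(state$N < 0) || any(state$R < 0)) {
    stop("state fields must be nonnegative", call. = FALSE)
  }
  D <- state$D
  N <- state$N
  R <- state$R
  Dbar <- neighbor_average(D)
  Nbar <- neighbor_average(N)

  trans <- N * Dbar
  cis <- N * D / params$k_c

  dN <- params$beta_N - params$gamma * N - trans / params$k_t - cis

  s <- trans^params$n
  hill <- s / (params$k_RS + s)
  hill[!is.finite(s)] <- 1   # Hill term saturates at 1 for overflowing signal
  dR <- params$beta_R * hill - params$gamma_R * R

  dD <- params$beta_D / (1 + R^params$m) - params$gamma * D -
    D * Nbar / params$k_t - cis
  dD[state$pv_mask] <- 0

  if (params$pv_freeze_NR) {
    dN[state$pv_mask] <- 0
    dR[state$pv_mask] <- 0
  }
  list(dD = dD, dN = dN, dR = dR)
}
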