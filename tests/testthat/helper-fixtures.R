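# Small parameter sets and states used across tests. Tests that do not need
# a converged equilibrium use a small lattice and a modest step cap so the
# whole suite stays fast.

small_params <- function(...) {
  simulation_params(lattice = lattice_spec(6L, 6L), ...)
}

# Homogeneous dynamics are independent of lattice size (the neighbor average
# of a uniform field is the cell value itself), so homogeneous-equilibrium
# checks run on a 4x4 lattice for speed.
homog_params <- function(...) {
  simulation_params(lattice = lattice_spec(4L, 4L), init_sd = 0, ...)
}

# A reproducible random field matrix.
random_field <- function(lattice, seed, mean = 1, sd = 0.3) {
  set.seed(seed)
  matrix(pmax(0, rnorm(n_cells(lattice), mean, sd)),
         lattice$height, lattice$width)
}

# Brute-force neighbor average: per-cell loop over von_neumann_neighbors().
neighbor_average_loop <- function(field, lattice) {
  out <- field * 0
  for (r in seq_len(lattice$height)) {
    for (co in seq_len(lattice$width)) {
      nb <- von_neumann_neighbors(c(r, co), lattice)
      out[r, co] <- mean(field[nb])
    }
  }
  out
}

# Brute-force diff statistic for a single PV cell: per-cell loops only.
compute_diff_loop <- function(state, params) {
  lat <- lattice_spec(ncol(state$D), nrow(state$D))
  pv <- which(state$pv_mask, arr.ind = TRUE)
  stopifnot(nrow(pv) == 1L)
  nb <- von_neumann_neighbors(pv[1L, ], lat)
  excluded <- rbind(pv, nb)
  r_in <- c()
  for (r in seq_len(lat$height)) {
    for (co in seq_len(lat$width)) {
      if (!any(excluded[, 1L] == r & excluded[, 2L] == co)) {
        r_in <- c(r_in, state$R[r, co])
      }
    }
  }
  ave <- mean(r_in)
  sdev <- sqrt(sum((r_in - ave)^2) / length(r_in))
  diffs <- (state$R[nb] - ave) / sdev
  list(ave = ave, sd = sdev, diffs = diffs, mean_diff = mean(diffs))
}

# Toroidal shift of a grid_state (fields and PV mask) by (dr, dc).
shift_state <- function(state, dr, dc) {
  sh <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    m[((seq_len(nr) - 1L - dr) %% nr) + 1L,
      ((seq_len(nc) - 1L - dc) %% nc) + 1L, drop = FALSE]
  }
  grid_state(sh(state$D), sh(state$N), sh(state$R), sh(state$pv_mask),
             t = state$t)
}
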