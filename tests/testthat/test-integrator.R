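test_that("a single Euler step does the expected arithmetic and clipping", {
  p <- small_params(beta_N = 100)
  # from the all-zero state only Notch production acts: N <- dt * beta_N
  st <- homogeneous_state(0, 0, p)
  st1 <- limi_step(st, p)
  expect_equal(st1$N, matrix(0.01, 6L, 6L))
  expect_equal(st1$D, matrix(1e-3, 6L, 6L))  # dt * beta_D with R = 0
  expect_equal(st1$R, matrix(1e-4 * 1e6 * 0^3, 6L, 6L))
  expect_equal(st1$t, p$dt)

  # a state engineered so Euler would drive D negative is clipped to 0
  p2 <- small_params(beta_D = 1e-6, dt = 0.5)
  st2 <- grid_state(matrix(0.01, 6L, 6L), matrix(100, 6L, 6L),
                    matrix(0, 6L, 6L))
  d <- limi_rhs(st2, p2)
  expect_lt(st2$D[1L, 1L] + p2$dt * d$dD[1L, 1L], 0)
  expect_equal(limi_step(st2, p2)$D, matrix(0, 6L, 6L))
})

test_that("compiled and pure-R integration loops agree step for step", {
  p <- small_params(max_steps = 60)
  st <- random_initial_state(p, seed = 11L, pv_cells = cbind(2L, 5L))
  rr <- run_to_equilibrium(st, p, engine = "R")
  rc <- run_to_equilibrium(st, p, engine = "cpp")
  expect_equal(rr$steps, rc$steps)
  expect_equal(rr$converged, rc$converged)
  expect_equal(rc$final_state$D, rr$final_state$D, tolerance = 1e-10)
  expect_equal(rc$final_state$N, rr$final_state$N, tolerance = 1e-10)
  expect_equal(rc$final_state$R, rr$final_state$R, tolerance = 1e-10)
  expect_equal(rc$final_residual, rr$final_residual, tolerance = 1e-8)
})

test_that("the step cap is honoured and reported", {
  p <- small_params(max_steps = 1)
  st <- homogeneous_state(0, 0, p)  # far from equilibrium
  for (eng in c("R", "cpp")) {
    res <- run_to_equilibrium(st, p, engine = eng)
    expect_false(res$converged)
    expect_equal(res$steps, 1)
  }
})

test_that("with beta_D = 0 the equilibrium is the analytic N = beta_N/gamma", {
  for (bn in c(100, 7)) {
    p <- homog_params(beta_D = 0, beta_N = bn, max_steps = 3e5)
    res <- run_to_equilibrium(homogeneous_state(0, 0, p), p)
    expect_true(res$converged)
    expect_equal(res$final_state$D, matrix(0, 4L, 4L))
    expect_equal(res$final_state$R, matrix(0, 4L, 4L))
    # converged when |beta_N - gamma N| < tol, so N is within tol/gamma
    expect_lt(max(abs(res$final_state$N - bn / p$gamma)), p$residual_tol)
    # the returned state re-evaluates below the tolerance
    expect_lt(residual(res$final_state, p), p$residual_tol)
  }
})

test_that("homogeneous equilibria match the independent root-finder", {
  # both headline parameter pairs plus randomised draws; homogeneous initial
  # states stay homogeneous, so the lattice collapses to the 3-ODE system
  # whose fixed points an independent Newton solver finds
  draws <- list(c(100, 10), c(10, 100))
  set.seed(2024)
  for (k in 1:5) draws[[k + 2L]] <- exp(runif(2L, log(5), log(200)))
  for (d in draws) {
    p <- homog_params(beta_N = d[1L], beta_D = d[2L], m = 1, n = 3,
                      max_steps = 4e6)
    res <- run_to_equilibrium(random_initial_state(p, seed = 1L), p)
    expect_true(res$converged)
    eq <- c(D = res$final_state$D[1L, 1L], N = res$final_state$N[1L, 1L],
            R = res$final_state$R[1L, 1L])
    root <- nearest_fixed_point(p, eq)
    expect_false(is.null(root))
    expect_lt(max(abs(eq - root)), 10 * p$residual_tol)
  }
})

test_that("homogeneity is preserved exactly at every step", {
  p <- small_params(init_sd = 0, max_steps = 4000)
  res <- run_to_equilibrium(random_initial_state(p, seed = 1L), p)
  for (f in c("D", "N", "R")) {
    fld <- res$final_state[[f]]
    expect_equal(max(fld) - min(fld), 0)
  }
})

test_that("all fields stay nonnegative after every step", {
  # strong cis-inactivation and production push Euler toward negative
  # excursions; clipping must keep every field at >= 0 throughout
  p <- small_params(beta_N = 500, beta_D = 500, k_c = 0.01, dt = 5e-4)
  st <- random_initial_state(p, seed = 3L, pv_cells = cbind(1L, 1L))
  for (i in 1:200) {
    st <- limi_step(st, p)
    expect_true(all(st$D >= 0) && all(st$N >= 0) && all(st$R >= 0))
  }
})

test_that("the pipeline is equivariant under toroidal translation", {
  p <- small_params(max_steps = 2e4)
  Df <- random_field(p$lattice, 21L, mean = 1, sd = 0.1)
  Nf <- random_field(p$lattice, 22L, mean = 1, sd = 0.1)
  R0 <- matrix(0, 6L, 6L)
  mask <- matrix(FALSE, 6L, 6L); mask[2L, 3L] <- TRUE
  st <- clamp_pv(grid_state(Df, Nf, R0, mask), p)
  st_shift <- shift_state(st, 2L, 4L)

  r1 <- run_to_equilibrium(st, p)
  r2 <- run_to_equilibrium(st_shift, p)
  expect_equal(r2$final_state$D, shift_state(r1$final_state, 2L, 4L)$D,
               tolerance = 1e-12)
  expect_equal(r2$final_state$R, shift_state(r1$final_state, 2L, 4L)$R,
               tolerance = 1e-12)
  expect_equal(r1$steps, r2$steps)
})

test_that("PV freeze option holds N and R of PV cells fixed", {
  p <- small_params(pv_freeze_NR = TRUE, max_steps = 500)
  st <- random_initial_state(p, seed = 9L, pv_cells = cbind(3L, 3L))
  res <- run_to_equilibrium(st, p)
  expect_equal(res$final_state$N[3L, 3L], st$N[3L, 3L])
  expect_equal(res$final_state$R[3L, 3L], 0)
  expect_equal(res$final_state$D[3L, 3L], 1000)
})

test_that("increment-based convergence is looser by the step size", {
  p_deriv <- small_params(max_steps = 1e5)
  p_incr <- update_params(p_deriv, residual_type = "increment")
  st <- random_initial_state(p_deriv, seed = 5L)
  r_incr <- run_to_equilibrium(st, p_incr)
  r_deriv <- run_to_equilibrium(st, p_deriv)
  expect_true(r_incr$converged)
  expect_lt(r_incr$steps, r_deriv$steps)
})

test_that("snapshots are recorded at the requested cadence", {
  p <- small_params(max_steps = 1000)
  st <- random_initial_state(p, seed = 2L)
  res <- run_to_equilibrium(st, p, snapshot_every = 300L)
  expect_false(res$converged)
  expect_equal(length(res$snapshots), 3L)
  expect_equal(res$snapshots[[1L]]$t, 300 * p$dt, tolerance = 1e-9)
})
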