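# Sweep bookkeeping tests run on a small lattice with a modest step cap:
# they exercise wiring and determinism, not converged equilibria.

fast_base <- function(...) {
  args <- list(...)
  if (!"max_steps" %in% names(args)) args$max_steps <- 2e4
  do.call(simulation_params, c(list(lattice = lattice_spec(6L, 6L)), args))
}

test_that("2-D sweep records shape, seeds and per-cell codes", {
  base <- fast_base()
  g <- sweep_2d(c(10, 100), c(10, 100), m = 1, n = 3, base,
                master_seed = 5L)
  expect_s3_class(g, "sweep_grid")
  expect_equal(dim(g$log2), c(2L, 2L))
  expect_equal(dim(g$seeds), c(2L, 2L))
  expect_equal(length(unique(c(g$seeds))), 4L)  # derived policy: distinct
  expect_true(all(g$code %in%
                    c("ok", "infinite", "negative", "nonconverged") |
                    startsWith(g$code, "error")))
  # every non-sentinel cell is finite
  expect_true(all(is.finite(g$log2[g$code == "ok"])))
  expect_true(all(is.na(g$log2[g$code != "ok"])))

  gf <- sweep_2d(c(10, 100), c(10, 100), m = 1, n = 3, base,
                 master_seed = 5L, seed_policy = "fixed")
  expect_equal(length(unique(c(gf$seeds))), 1L)
})

test_that("same master seed reproduces the grid; sweep matches single runs", {
  base <- fast_base()
  g1 <- sweep_2d(c(20, 80), c(15, 60), m = 1, n = 3, base, master_seed = 9L)
  g2 <- sweep_2d(c(20, 80), c(15, 60), m = 1, n = 3, base, master_seed = 9L)
  expect_identical(g1, g2)

  # an individual cell reproduces the corresponding pipeline run exactly
  p <- update_params(base, beta_N = 80, beta_D = 60, m = 1, n = 3)
  run <- simulate_pv_case(p, seed = g1$seeds[2L, 2L])
  if (run$trajectory$converged && is.na(run$report$sentinel)) {
    expect_equal(g1$log2[2L, 2L], run$report$log2_mean_diff)
  } else {
    expect_true(is.na(g1$log2[2L, 2L]))
  }
})

test_that("per-cell failures are recorded without aborting the sweep", {
  # a step cap of 10 cannot converge: all cells marked nonconverged
  base <- fast_base(max_steps = 10)
  g <- sweep_2d(c(10, 100), 10, m = 1, n = 3, base)
  expect_true(all(g$code == "nonconverged"))
  expect_true(all(is.na(g$log2)))
})

test_that("1-D sensitivity sweep varies exactly one parameter", {
  base <- fast_base()
  df <- sweep_1d("beta_R", c(1e5, 1e6, 1e7), base, seeds = c(1L, 2L))
  expect_equal(nrow(df), 6L)
  expect_equal(df$value, rep(c(1e5, 1e6, 1e7), each = 2L))
  expect_equal(df$seed, rep(c(1L, 2L), 3L))
  expect_true(all(df$param == "beta_R"))

  expect_error(sweep_1d("beta_N", 1, base), "unknown sweep parameter")
  expect_error(sweep_1d("beta_R", numeric(0), base), "nonempty")
  # single-element value list gives a single-row result per seed
  expect_equal(nrow(sweep_1d("k_c", 0.1, base, seeds = 3L)), 1L)
})

test_that("log-spaced axis helper brackets its endpoints", {
  ax <- log_axis(1, 1000, 10L)
  expect_equal(length(ax), 10L)
  expect_equal(ax[1L], 1)
  expect_equal(ax[10L], 1000)
  expect_true(all(diff(log(ax)) > 0))
  expect_equal(diff(log(ax)), rep(diff(log(ax))[1L], 9L))
})
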