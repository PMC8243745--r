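# A state whose reporter field is chosen directly, bypassing the integrator:
# the diff statistic is a pure function of the equilibrium state.
made_state <- function(Rfield, pv_cells, params) {
  lat <- params$lattice
  st <- grid_state(matrix(1, lat$height, lat$width),
                   matrix(1, lat$height, lat$width),
                   Rfield, pv_mask_from_cells_test(pv_cells, lat))
  clamp_pv(st, params)
}

pv_mask_from_cells_test <- function(cells, lat) {
  m <- matrix(FALSE, lat$height, lat$width)
  if (!is.null(cells)) m[as.matrix(cells)] <- TRUE
  m
}

test_that("diff is the z-score of a neighbor against the included field", {
  p <- simulation_params()
  # engineer included cells with Ave = 1, SD = 1 (half at 0, half at 2)
  Rf <- matrix(rep(c(0, 2), length.out = 400L), 20L, 20L)
  pv <- cbind(10L, 10L)
  st <- made_state(Rf, pv, p)
  nb <- von_neumann_neighbors(c(10L, 10L), p$lattice)
  st$R[nb] <- 3
  # recompute what Ave and SD are after fixing the neighbors
  rep_ <- compute_diff(st, p)
  excl <- rbind(pv, nb)
  incl <- st$R[-(excl[, 1L] + (excl[, 2L] - 1L) * 20L)]
  expect_equal(rep_$ave, mean(incl))
  expect_equal(rep_$sd, sqrt(mean((incl - mean(incl))^2)))
  expect_equal(rep_$neighbor_diffs,
               rep((3 - rep_$ave) / rep_$sd, 4L))
  expect_equal(rep_$mean_diff, mean(rep_$neighbor_diffs))
  expect_equal(rep_$log2_mean_diff, log2(rep_$mean_diff))
  expect_true(is.na(rep_$sentinel))
})

test_that("one PV cell on a 20x20 torus scores 4 neighbors over 395 cells", {
  p <- simulation_params()
  st <- random_initial_state(p, seed = 1L,
                             pv_cells = lattice_center(p$lattice))
  st$R <- matrix(runif(400L), 20L, 20L)
  rep_ <- compute_diff(st, p)
  expect_equal(nrow(rep_$neighbor_cells), 4L)
  expect_equal(length(rep_$neighbor_diffs), 4L)
  # Ave over 395 = 400 - 1 PV - 4 neighbor cells
  excl <- rbind(which(st$pv_mask, arr.ind = TRUE), rep_$neighbor_cells)
  incl <- st$R[-(excl[, 1L] + (excl[, 2L] - 1L) * 20L)]
  expect_equal(length(incl), 395L)
  expect_equal(rep_$ave, mean(incl))
})

test_that("diff agrees with a brute-force loop on random fields", {
  p <- small_params()
  for (seed in 1:5) {
    st <- random_initial_state(p, seed = seed, pv_cells = cbind(2L, 4L))
    set.seed(seed + 50L)
    st$R <- matrix(runif(36L, 0, 10), 6L, 6L)
    a <- compute_diff(st, p)
    b <- compute_diff_loop(st, p)
    expect_equal(a$ave, b$ave)
    expect_equal(a$sd, b$sd)
    expect_equal(sort(a$neighbor_diffs), sort(b$diffs))
    expect_equal(a$mean_diff, b$mean_diff)
  }
})

test_that("diff is invariant under affine rescaling of the reporter", {
  p <- small_params()
  st <- random_initial_state(p, seed = 8L, pv_cells = cbind(3L, 3L))
  set.seed(99L)
  st$R <- matrix(runif(36L, 0, 5), 6L, 6L)
  base <- compute_diff(st, p)
  for (ab in list(c(2, 0), c(0.5, 3), c(7, 11))) {
    st2 <- st
    st2$R <- ab[1L] * st$R + ab[2L]
    scaled <- compute_diff(st2, p)
    expect_equal(scaled$neighbor_diffs, base$neighbor_diffs,
                 tolerance = 1e-9)
  }
})

test_that("sentinels flag homogeneous fields and negative averaged diffs", {
  p <- simulation_params()
  # all included cells identical -> SD = 0 -> infinity sentinel
  st <- made_state(matrix(1, 20L, 20L), cbind(10L, 10L), p)
  rep_inf <- compute_diff(st, p)
  expect_equal(rep_inf$sentinel, "infinite")
  expect_true(is.na(rep_inf$log2_mean_diff))

  # neighbors below the field average -> negative sentinel
  st2 <- made_state(matrix(rep(c(0, 2), length.out = 400L), 20L, 20L),
                    cbind(10L, 10L), p)
  nb <- von_neumann_neighbors(c(10L, 10L), p$lattice)
  st2$R[nb] <- 0
  rep_neg <- compute_diff(st2, p)
  expect_lt(rep_neg$mean_diff, 0)
  expect_equal(rep_neg$sentinel, "negative")
  expect_true(is.na(rep_neg$log2_mean_diff))

  # log2 identity on a clean case: mean_diff 2 -> log2 1
  st3 <- made_state(matrix(rep(c(0, 2), length.out = 400L), 20L, 20L),
                    cbind(10L, 10L), p)
  rep3 <- compute_diff(st3, p)
  st3$R[nb] <- rep3$ave + 2 * rep3$sd
  rep3b <- compute_diff(st3, p)
  expect_equal(rep3b$mean_diff, 2, tolerance = 1e-9)
  expect_equal(rep3b$log2_mean_diff, 1, tolerance = 1e-9)
})

test_that("cholangiocyte calls use a strict inequality at the threshold", {
  p <- simulation_params()
  expect_equal(classify_cholangiocytes(c(2.5, 2.0, -1, Inf, 1.999), p),
               c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("multiple PV cells union their neighborhoods", {
  p <- simulation_params()
  pv <- rbind(c(5L, 5L), c(5L, 6L))  # adjacent PV pair
  st <- made_state(matrix(rep(c(0, 2), length.out = 400L), 20L, 20L), pv, p)
  rep_ <- compute_diff(st, p)
  # neighbors: union of the two von Neumann sets minus the PV cells = 6
  expect_equal(nrow(rep_$neighbor_cells), 6L)
  # excluded: 2 PV + 6 neighbors -> 392 included
  excl_n <- 400L - 2L - 6L
  expect_equal(length(st$R) - 2L - 6L, excl_n)
})

test_that("diff contract errors: no PV cell, too few included cells", {
  p <- simulation_params()
  st <- made_state(matrix(1, 20L, 20L), NULL, p)
  st$pv_mask[] <- FALSE
  expect_error(compute_diff(st, p), "PV cell")
  p3 <- simulation_params(lattice = lattice_spec(3L, 3L))
  st3 <- made_state(matrix(1, 3L, 3L), cbind(2L, 2L), p3)
  st3$pv_mask[1L, 1L] <- TRUE
  st3$pv_mask[3L, 3L] <- TRUE
  # 9 cells - 3 PV - 5 neighbors leaves too few
  expect_error(compute_diff(st3, p3), "fewer than 2")
})
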