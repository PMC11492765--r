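small_ba_grid <- function() {
  search_grid(list(chest_norm = c(0.4, 0.05, 1.0),
                   pull_norm = c(0.3, 0.05, 1.0)))
}

ba_fixture <- function(n = 12, seed = 101, sd = c(0.08, 0.07),
                       centroid = c(0.75, 0.58)) {
  set.seed(seed)
  U <- cbind(rnorm(n, centroid[1], sd[1]), rnorm(n, centroid[2], sd[2]))
  trial_block(U, "BA", "near")
}

test_that("default grids reproduce the printed search limits", {
  g <- default_search_grid("BA")
  expect_equal(g$axes$chest_norm, c(0, 0.0033, 1.2))
  expect_equal(g$axes$pull_norm, c(0, 0.01, 1.5))
  g2 <- default_search_grid("RS")
  expect_equal(g2$axes$vx, c(-2.0, 0.02, 2.0))
  expect_equal(g2$axes$vy, c(-1.0, 0.1, 7.0))
  expect_equal(g2$axes$vz, c(-11.5, 0.0656, -1.0))
  g3 <- default_search_grid("PB")
  expect_equal(g3$axes$vx, c(0, -0.0296, -5.0))
  expect_equal(g3$axes$vz, c(0, -0.08, -8.0))
  expect_equal(g3$axes$d, c(2.875, 0.0056, 3.458))
  expect_true(all(diff(g3$values$vx) > 0))  # oriented ascending
})

test_that("single-trial T-cost equals the exhaustive lattice scan", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  grid <- small_ba_grid()
  u <- c(0.85, 0.45)
  tc <- t_cost(matrix(u, 1), gf, grid, mode = "exact")
  lattice <- as.matrix(expand.grid(grid$values))
  lattice_err <- gf$error_fn(lattice)
  expect_equal(tc$T, evaluate_goal_function(gf, u) - min(lattice_err),
               tolerance = 1e-12)
  expect_equal(unname(tc$argmin),
               unname(lattice[which.min(lattice_err), ]))
})

test_that("T-cost centred on a zero-error lattice centroid is ~zero", {
  env <- ba_environment(0.25, "near")
  gf <- ba_goal_function(env)
  # symmetric cloud about the optimum, which is a lattice point of this grid
  grid <- search_grid(list(chest_norm = c(0.45, 0.05, 0.85),
                           pull_norm = c(0.45, 0.05, 0.85)))
  D <- rbind(c(0.02, 0), c(-0.02, 0), c(0, 0.03), c(0, -0.03))
  U <- sweep(D, 2, c(env$chest_opt, env$pull_opt), `+`)
  tc <- t_cost(U, gf, grid, mode = "exact")
  expect_lt(abs(tc$T), 1e-9)
})

test_that("T-cost optimized set preserves all central moments", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  b <- ba_fixture()
  tc <- t_cost(b, gf, small_ba_grid(), mode = "exact")
  D0 <- sweep(b$U, 2, colMeans(b$U))
  D1 <- sweep(tc$U_star, 2, colMeans(tc$U_star))
  expect_equal(D0, D1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("coarse-to-fine T-cost matches exact mode", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  b <- ba_fixture(seed = 7)
  grid <- search_grid(list(chest_norm = c(0.3, 0.01, 1.1),
                           pull_norm = c(0.3, 0.01, 1.1)))
  exact <- t_cost(b, gf, grid, mode = "exact")
  coarse <- t_cost(b, gf, grid, mode = "coarse")
  expect_equal(coarse$T, exact$T, tolerance = 1e-10)
  expect_equal(coarse$argmin, exact$argmin)
})

test_that("N-cost equals direct enumeration over the 101 candidates", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  b <- ba_fixture(seed = 5)
  nc <- n_cost(b, gf)
  c0 <- colMeans(b$U)
  oracle <- vapply(seq(1, 0, by = -0.01), function(s) {
    mean(gf$error_fn(sweep(sweep(b$U, 2, c0) * s, 2, c0, `+`)))
  }, numeric(1))
  expect_equal(unname(nc$candidate_means), oracle)
  expect_equal(nc$N, oracle[1] - min(oracle))
  expect_equal(nc$shrink, seq(1, 0, by = -0.01)[which.min(oracle)])
  # centroid is preserved exactly
  expect_equal(colMeans(nc$U_star), c0, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-variance blocks have zero N-cost; full shrink collapses", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  U <- matrix(rep(c(0.8, 0.5), each = 5), ncol = 2)
  nc <- n_cost(trial_block(U, "BA"), gf)
  expect_equal(nc$N, 0)
  # a spread straddling the optimum shrinks fully onto the centroid
  env <- ba_environment(0.25, "near")
  opt <- c(env$chest_opt, env$pull_opt)
  U2 <- rbind(opt + c(0.1, 0.12), opt - c(0.1, 0.12))
  nc2 <- n_cost(trial_block(U2, "BA"), gf)
  expect_equal(nc2$shrink, 0)
  expect_equal(nc2$U_star[1, ], nc2$U_star[2, ], ignore_attr = TRUE)
})

test_that("per-variable N-cost isolates flat and harmful directions", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  # constant column: its N-cost is exactly zero
  set.seed(3)
  U <- cbind(rep(0.75, 10), rnorm(10, 0.55, 0.1))
  expect_equal(n_cost_by_variable(trial_block(U, "BA"), gf, 1)$N_j, 0)
  nj2 <- n_cost_by_variable(trial_block(U, "BA"), gf, 2)
  expect_gt(nj2$N_j, 0)
  # enumeration oracle for the scaled column
  c0 <- colMeans(U)
  oracle <- vapply(seq(1, 0, by = -0.01), function(s) {
    Us <- U
    Us[, 2] <- c0[2] + s * (U[, 2] - c0[2])
    mean(gf$error_fn(Us))
  }, numeric(1))
  expect_equal(nj2$N_j, oracle[1] - min(oracle))
  expect_error(n_cost_by_variable(trial_block(U, "BA"), gf, 5), "invalid")
})

test_that("C-cost preserves column multisets and is zero for n = 1", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  b <- ba_fixture(n = 10, seed = 23)
  cc <- c_cost(b, gf)
  expect_gte(cc$C, 0)
  for (j in 1:2) {
    expect_equal(sort(cc$U_star[, j]), sort(b$U[, j]), ignore_attr = TRUE)
  }
  expect_equal(c_cost(matrix(c(0.8, 0.5), 1), gf)$C, 0)
})

test_that("greedy C-cost matches the factorial oracle on small instances", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  match_count <- 0
  n_inst <- 40
  for (s in seq_len(n_inst)) {
    set.seed(1000 + s)
    n <- sample(3:6, 1)
    U <- cbind(rnorm(n, 0.75, 0.12), rnorm(n, 0.55, 0.12))
    greedy <- c_cost(U, gf)$C
    exact <- c_cost_exhaustive_2var(U, gf)
    expect_lte(greedy, exact + 1e-12)
    if (abs(greedy - exact) < 1e-9) match_count <- match_count + 1
  }
  expect_gte(match_count / n_inst, 0.9)
})

test_that("a block already optimally paired accepts no swaps", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  set.seed(77)
  U <- cbind(rnorm(5, 0.75, 0.1), rnorm(5, 0.55, 0.1))
  first <- c_cost(U, gf)
  again <- c_cost(first$U_star[, , drop = FALSE], gf)
  expect_equal(again$swaps, 0L)
  expect_equal(again$C, 0, tolerance = 1e-12)
})

test_that("TNC costs are nonnegative and deterministic across runs", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  for (s in 1:5) {
    b <- ba_fixture(seed = 200 + s)
    r1 <- tnc_cost(b, gf, small_ba_grid(), mode = "exact")
    r2 <- tnc_cost(b, gf, small_ba_grid(), mode = "exact")
    expect_identical(r1$T, r2$T)
    expect_identical(r1$C, r2$C)
    expect_gte(r1$T, -1e-9 - 0.05)  # grid-resolution slack
    expect_gte(r1$N, -1e-9)
    expect_gte(r1$C, -1e-9)
    expect_true(all(r1$N_by_variable >= -1e-9))
  }
})

test_that("gross-miss trials are excluded from TNC and counted", {
  gf <- rs_goal_function(rs_environment())
  u_opt <- rs_optimal_execution(gf$env)
  U <- rbind(u_opt + c(0.3, 0.2, -0.4), u_opt + c(-0.2, 0.4, 0.3),
             c(0, 0, 1))  # never reaches the plane
  b <- trial_block(U, "RS")
  nc <- n_cost(b, gf)
  expect_true(is.finite(nc$N))
  res <- tnc_cost(b, gf, search_grid(list(vx = c(-0.5, 0.1, 0.5),
                                          vy = c(4, 0.1, 6),
                                          vz = c(-7, 0.1, -5))),
                  mode = "exact")
  expect_equal(res$diagnostics$n_gross_miss, 1L)
  # the sentinel row passes through the optimized sets untouched
  expect_equal(res$U_N[3, ], U[3, ], ignore_attr = TRUE)
})

test_that("three-variable C-cost improves a deliberately mispaired block", {
  env <- rs_environment()
  gf <- rs_goal_function(env)
  # rows built from manifold points, then columns shuffled apart
  set.seed(5)
  base <- t(vapply(runif(8, -8, -3), function(z) {
    rs_optimal_execution(env, z)
  }, numeric(3)))
  U <- base
  U[, 2] <- sample(U[, 2])
  U[, 3] <- sample(U[, 3])
  cc <- c_cost(U, gf)
  expect_gt(cc$C, 0)
  expect_gt(cc$swaps, 0)
  for (j in 1:3) expect_equal(sort(cc$U_star[, j]), sort(U[, j]))
  # re-pairing can recover (near-)zero mean error for this construction
  expect_lt(cc$mean_optimized, cc$mean_observed)
})
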