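rs_block_fixture <- function(n = 15, seed = 50, centroid = c(-0.4, 4.2, -5.3),
                             sd = c(0.4, 0.5, 0.7)) {
  set.seed(seed)
  U <- cbind(rnorm(n, centroid[1], sd[1]), rnorm(n, centroid[2], sd[2]),
             rnorm(n, centroid[3], sd[3]))
  trial_block(U, "RS")
}

test_that("velocity scaling floors at 1 and solves single-axis ratios", {
  gf <- rs_goal_function(rs_environment())
  # centroid already beyond the bound
  U_fast <- matrix(rep(c(0, 5, -12), each = 4), ncol = 3)
  expect_equal(compute_velocity_scale(U_fast, gf, c(vz = -11))$kv, 1)
  # forced ratio: centroid vz = -5.5 against bound -11.0
  U_slow <- matrix(rep(c(0, 5, -5.5), each = 4), ncol = 3)
  expect_equal(compute_velocity_scale(U_slow, gf, c(vz = -11))$kv, 2)
  # two bound axes: the max of the per-axis ratios, checked by a kv scan
  U2 <- matrix(rep(c(0, 2, -5.5), each = 4), ncol = 3)
  res <- compute_velocity_scale(U2, gf, c(vy = 5, vz = -11))
  kv_grid <- seq(1, 5, by = 1e-4)
  ok <- vapply(kv_grid, function(k) {
    ctr <- colMeans(U2) * k
    ctr[2] >= 5 && ctr[3] <= -11
  }, logical(1))
  expect_equal(res$kv, min(kv_grid[ok]), tolerance = 1e-3)
  expect_equal(res$kv, max(res$ratios))
  # infeasible: centroid points away from the bound
  U_bad <- matrix(rep(c(0, 5, 2), each = 4), ncol = 3)
  expect_error(compute_velocity_scale(U_bad, gf, c(vz = -11)),
               "infeasible")
})

test_that("target resizing follows the N / e_max algebra", {
  gf <- rs_goal_function(rs_environment())
  b <- rs_block_fixture(seed = 61)
  grid <- search_grid(list(vx = c(-1, 0.05, 1), vy = c(3.5, 0.05, 5.5),
                           vz = c(-7, 0.05, -4)))
  res <- resize_target(b, gf, e_max = 0.4, grid = grid, mode = "exact")
  if (res$N / gf$target_radius < 0.4) {
    expect_equal(res$rt, gf$target_radius)
  } else {
    expect_equal(res$rt, res$N / 0.4, tolerance = 1e-6)
    expect_lt(res$N / res$rt, 0.4)
  }
  expect_gte(res$rt, gf$target_radius)  # never shrinks below baseline
  # a huge threshold leaves the radius unchanged
  res2 <- resize_target(b, gf, e_max = 100, grid = grid, mode = "exact")
  expect_equal(res2$rt, gf$target_radius)
  # doubling the noise never shrinks the required radius
  b2 <- rs_block_fixture(seed = 61, sd = c(0.8, 1.0, 1.4))
  res3 <- resize_target(b2, gf, e_max = 0.4, grid = grid, mode = "exact")
  expect_gte(res3$rt, res$rt - 1e-9)
})

test_that("visual error modification is identity at c = 1 and zeroing at c = 0", {
  gf <- rs_goal_function(rs_environment())
  b <- rs_block_fixture(n = 8, seed = 71)
  U1 <- apply_visual_error_modification(b$U, gf, 1)
  expect_equal(U1, b$U, tolerance = 1e-9, ignore_attr = TRUE)
  U0 <- apply_visual_error_modification(b$U, gf, 0)
  expect_true(all(gf$error_fn(U0) < 1e-6 * gf$target_radius))
  # fluctuation norms never grow for c in [0, 1]
  us <- t(apply(b$U, 1, function(u) project_to_manifold(u, gf)))
  for (cv in c(0.25, 0.5, 0.75)) {
    Ur <- apply_visual_error_modification(b$U, gf, cv, u_star = us)
    expect_true(all(sqrt(rowSums((Ur - us)^2)) <=
                      sqrt(rowSums((b$U - us)^2)) + 1e-12))
  }
})

test_that("a quadratic 1-D toy goal function scales error as c^2", {
  # e(u) = (u - 2)^2 in a 1-variable custom goal function is not a task;
  # use BA with chest fixed at optimum, where the manifold point is the
  # optimal pull and error is locally smooth: check e(u_r) < e(u) ordering
  env <- ba_environment(0.25, "near")
  gf <- ba_goal_function(env)
  u <- c(env$chest_opt, 0.75)
  e1 <- evaluate_goal_function(gf, u)
  e_half <- evaluate_goal_function(
    gf, apply_visual_error_modification(u, gf, 0.5))
  # vertical drop error is ~quadratic in flight time, locally ~linear in
  # pull deviation: halving the fluctuation roughly halves the error
  expect_lt(e_half, e1)
  expect_equal(e_half / e1, 0.5, tolerance = 0.15)
})

test_that("speed-preserving modification preserves norms and PB amplitude", {
  env <- pb_environment()
  gf <- pb_goal_function(env)
  set.seed(81)
  n <- 10
  U <- cbind(rnorm(n, -1.4, 0.3), rnorm(n, -2.8, 0.35), rnorm(n, 3.15, 0.1))
  U[, 3] <- pmin(pmax(U[, 3], env$bag_bottom), env$bag_top)
  Us <- apply_speed_preserving_modification(U, gf, c(0.5, 0.5, 1))
  expect_lt(max(abs(sqrt(rowSums(Us^2)) - sqrt(rowSums(U^2)))), 1e-9)
  # swing amplitude per trial is exactly unchanged
  amp <- function(M) {
    pb_peak_amplitude(env$k * M[, 3] * sqrt(M[, 1]^2 + M[, 2]^2), env$hang)
  }
  expect_lt(max(abs(amp(Us) - amp(U))), 1e-6)
  # direction error strictly shrinks wherever it was nonzero
  dir_err <- function(M) {
    vapply(seq_len(nrow(M)), function(i) {
      az <- atan2(-M[i, 1], -M[i, 2])
      abs(pb_error_decomposition(c(amp(M)[i], az),
                                 c(env$theta_des, env$phi_des))$direction)
    }, numeric(1))
  }
  d0 <- dir_err(U)
  d1 <- dir_err(Us)
  expect_true(all(d1[d0 > 1e-8] < d0[d0 > 1e-8]))
  # c = 1 is the identity
  expect_equal(apply_speed_preserving_modification(U, gf, c(1, 1, 1)), U,
               ignore_attr = TRUE)
})

test_that("modification-vector selection respects the axis policy", {
  env <- rs_environment()
  gf <- rs_goal_function(env)
  # vertical-error dominance: vy scattered widely, vx tight
  set.seed(91)
  n <- 12
  base <- t(vapply(rnorm(n, -5.5, 0.3), function(z) {
    rs_optimal_execution(env, z)
  }, numeric(3)))
  U <- base
  U[, 1] <- U[, 1] + rnorm(n, 0, 0.05)
  U[, 2] <- U[, 2] + rnorm(n, 0.8, 0.4)   # dominant vertical error
  b <- trial_block(U, "RS")
  rt <- gf$target_radius
  sel_vy <- select_modification_vector(b, gf, rt, 0.4,
                                       policy = "single-axis", axis = "vy")
  sel_vx <- select_modification_vector(b, gf, rt, 0.4,
                                       policy = "single-axis", axis = "vx")
  expect_true(sel_vy$feasible)
  expect_false(sel_vx$feasible)   # lateral axis cannot fix vertical error
  # exhaustive c-grid oracle for the feasible axis: largest feasible c
  us <- t(apply(U, 1, function(u) project_to_manifold(u, gf)))
  feas <- vapply(seq(1, 0, by = -0.05), function(cv) {
    Ur <- apply_visual_error_modification(U, gf, c(1, cv, 1), u_star = us)
    mean(gf$error_fn(Ur)) / rt <= 0.4
  }, logical(1))
  expect_equal(sel_vy$c_value, seq(1, 0, by = -0.05)[which(feas)[1]])
  # a block already satisfying the constraint keeps c = 1
  tight <- trial_block(base + matrix(rnorm(3 * n, 0, 0.02), n), "RS")
  sel1 <- select_modification_vector(tight, gf, rt, 0.4)
  expect_equal(sel1$c_value, 1)
})

test_that("the three-step pipeline meets the normalized error bound", {
  env <- rs_environment()
  gf <- rs_goal_function(env)
  grid <- search_grid(list(vx = c(-1.5, 0.1, 1.5), vy = c(0, 0.1, 6.5),
                           vz = c(-11, 0.1, -2)))
  for (s in 1:5) {
    b <- rs_block_fixture(n = 10, seed = 300 + s)
    params <- adjust_task(b, gf, e_max = 0.4, v_min = c(vz = -11),
                          grid = grid, mode = "exact")
    expect_gte(params$kv, 1)
    expect_gte(params$rt, gf$target_radius)
    if (params$feasible) {
      out <- score_block(gf, apply_adjustment(b, gf, params))
      expect_lte(block_mean_error(out) / params$rt, 0.4 + 1e-9)
    }
  }
})

test_that("adjustment application is deterministic and repeatable", {
  env <- rs_environment()
  gf <- rs_goal_function(env)
  b <- rs_block_fixture(n = 8, seed = 400)
  params <- adjust_task(b, gf, e_max = 0.4, v_min = c(vz = -11),
                        grid = search_grid(list(vx = c(-1, 0.1, 1),
                                                vy = c(2, 0.1, 6),
                                                vz = c(-9, 0.1, -3))),
                        mode = "exact")
  out1 <- apply_adjustment(b, gf, params)
  out2 <- apply_adjustment(b, gf, params)
  expect_identical(out1$U, out2$U)
})
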