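test_that("MRE, BVE, and centroid bias match hand computations", {
  hits <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(mre(hits), 1)
  expect_equal(bve(hits), 1)
  expect_equal(centroid_bias(hits), 0)
  expect_equal(mre(rbind(c(0, 0), c(0, 0))), 0)
  expect_equal(bve(rbind(c(0.3, 0.4), c(0.3, 0.4))), 0)
  expect_equal(centroid_bias(rbind(c(0.3, 0.4), c(0.3, 0.4))), 0.5)  # 3-4-5
  expect_error(mre(matrix(numeric(0), 0, 2)), "at least")
  expect_error(bve(rbind(c(1, 1))), "at least")
})

test_that("BVE is translation invariant and the RMS identity holds", {
  set.seed(33)
  hits <- matrix(rnorm(40), ncol = 2)
  shift <- c(5, -3)
  expect_equal(bve(hits), bve(sweep(hits, 2, shift, `+`)), tolerance = 1e-12)
  # RMSE^2 = bias^2 + BVE^2 exactly; MRE bounded by bias + BVE
  expect_equal(rmse_radial(hits)^2,
               centroid_bias(hits)^2 + bve(hits)^2, tolerance = 1e-12)
  expect_lte(mre(hits), centroid_bias(hits) + bve(hits) + 1e-12)
  # metrics are invariant to trial order
  perm <- sample(nrow(hits))
  expect_equal(mre(hits), mre(hits[perm, ]))
  expect_equal(bve(hits), bve(hits[perm, ]))
})

test_that("execution-space centroid bias recovers a planted offset", {
  env <- ba_environment(0.25, "near")
  gf <- ba_goal_function(env)
  bias <- c(0.10, -0.08)
  set.seed(44)
  n <- 40
  U <- cbind(rnorm(n, env$chest_opt + bias[1], 0.03),
             rnorm(n, env$pull_opt + bias[2], 0.03))
  grid <- search_grid(list(chest_norm = c(0.4, 0.01, 1.0),
                           pull_norm = c(0.3, 0.01, 1.0)))
  off <- centroid_bias_execution(trial_block(U, "BA"), gf, grid,
                                 mode = "exact")
  planted <- colMeans(U) - c(env$chest_opt, env$pull_opt)
  # recovered within one grid step per axis
  expect_lt(max(abs(unname(off) - unname(planted))), 0.01 + 1e-9)
})

test_that("trial filters flag the planted outliers exactly, idempotently", {
  env <- rs_environment()
  gf <- rs_goal_function(env)
  u_opt <- rs_optimal_execution(env)
  set.seed(55)
  n <- 12
  U <- t(replicate(n, u_opt + rnorm(3, 0, 0.15)))
  # trial 1: ~16x the target radius (slow lob falling far short)
  U[1, ] <- c(0, 1.0, -1.05)
  b <- score_block(gf, trial_block(U, "RS"))
  expect_gt(b$error[1], 15 * gf$target_radius)
  fb <- filter_trials(b, gf)
  counts <- attr(fb, "filter_counts")
  expect_true(fb$excluded[1])
  expect_equal(unname(counts["n_gross"]), 1L)
  # stage 2: a >4-SD outlier among otherwise tight errors
  set.seed(56)
  n <- 60
  U2 <- t(replicate(n, u_opt + rnorm(3, 0, 0.05)))
  b2 <- score_block(gf, trial_block(U2, "RS"))
  e <- b2$error
  target_e <- mean(e) + 4.5 * sd(e)
  # build a trial with that error by lofting vy upward
  worse <- u_opt
  worse[2] <- worse[2] + target_e / (env$plane_dist / (-u_opt[3]))
  U2 <- rbind(U2, worse)
  b2 <- score_block(gf, trial_block(U2, "RS"))
  fb2 <- filter_trials(b2, gf)
  expect_true(fb2$excluded[n + 1])
  expect_equal(sum(fb2$excluded), 1L)
  # idempotence: a second pass flags nothing new
  fb2again <- filter_trials(fb2, gf)
  expect_identical(fb2again$excluded, fb2$excluded)
  # equal errors: SD = 0, stage 2 flags none
  b3 <- score_block(gf, trial_block(t(replicate(5, u_opt)), "RS"))
  expect_equal(sum(filter_trials(b3, gf)$excluded), 0L)
})

test_that("on-target time measures the on-target suffix on the sample grid", {
  env <- rs_environment()
  gf <- rs_goal_function(env)
  u_opt <- rs_optimal_execution(env)
  rate <- 100
  tt <- seq(-1.2, 0, by = 1 / rate)
  n <- length(tt)
  # constant on-target velocity for the whole window: full 1 s
  V <- matrix(u_opt, n, 3, byrow = TRUE)
  traj <- trajectory_series(tt, V)
  expect_equal(on_target_time(traj, gf), 1)
  # on-target only in the final 0.25 s
  V2 <- V
  off <- tt < -0.25
  V2[off, 2] <- V2[off, 2] + 3  # large vertical error before -0.25 s
  traj2 <- trajectory_series(tt, V2)
  expect_equal(on_target_time(traj2, gf), 0.25, tolerance = 1 / rate + 1e-9)
  # never on-target before the strike sample: one sample period
  V3 <- V
  V3[-n, 2] <- V3[-n, 2] + 3
  expect_equal(on_target_time(trajectory_series(tt, V3), gf), 1 / rate)
  # a missed strike returns NA
  V4 <- V + 2
  expect_true(is.na(on_target_time(trajectory_series(tt, V4), gf)))
})

test_that("pre-movement lateral speed averages over the >20% speed window", {
  tt <- seq(-1.5, 0, by = 0.01)
  n <- length(tt)
  u <- c(-0.6, 1.2, -5)
  # constant velocity: mean vx is the strike vx
  traj <- trajectory_series(tt, matrix(u, n, 3, byrow = TRUE))
  res <- mean_lateral_speed_premovement(traj)
  expect_equal(res$mean_vx, u[1])
  expect_equal(res$mean_abs_vx, abs(u[1]))
  # linear speed ramp crossing 20% at a known time: closed-form window mean
  speed <- sqrt(sum(u^2))
  ramp <- pmax(0, (tt + 1.5) / 1.5)          # 0 -> 1 over the window
  V <- outer(ramp, u)
  traj2 <- trajectory_series(tt, V)
  res2 <- mean_lateral_speed_premovement(traj2)
  in_win <- ramp * speed > 0.2 * speed
  expect_equal(res2$mean_vx, mean(V[in_win, 1]), tolerance = 1e-12)
  # all speeds below threshold until the strike sample: single sample
  V3 <- matrix(0.1 * u, n, 3, byrow = TRUE)
  V3[n, ] <- u
  res3 <- mean_lateral_speed_premovement(trajectory_series(tt, V3))
  expect_equal(res3$n_samples, 1L)
  expect_equal(res3$mean_vx, u[1])
})

test_that("block metrics emit a flat row with Table-style columns", {
  gf <- ba_goal_function(ba_environment(0.25, "near"))
  set.seed(66)
  U <- cbind(rnorm(15, 0.7, 0.06), rnorm(15, 0.6, 0.06))
  row <- block_metrics(trial_block(U, "BA", "near", 2L), gf,
                       grid = search_grid(list(chest_norm = c(0.4, 0.02, 1),
                                               pull_norm = c(0.3, 0.02, 1))),
                       mode = "exact")
  expect_equal(nrow(row), 1L)
  expect_true(all(c("MRE", "bias", "BVE", "T", "N", "C", "N_chest_norm",
                    "N_pull_norm", "mu_chest_norm", "sigma_pull_norm") %in%
                    names(row)))
  expect_gte(row$MRE, row$bias)
})
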