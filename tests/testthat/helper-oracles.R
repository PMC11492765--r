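# Shared fixtures and independent oracles used across the suite.

std_limits <- function() {
  workspace_limits(
    chest_limit = c(R = 0.25, FR = 0.21, F = 0.13, FL = 0.21, L = 0.25),
    hand_limit = c(R = 0.95, FR = 0.87, F = 0.79, FL = 0.87, L = 0.95),
    neutral_hmd_height = 1.65)
}

std_anthro <- function() anthropometrics(1.75, 0.72, "right")

# Fixed-step RK4 integration of point-mass flight under gravity, with
# bisection onto the crossing surface. Independent of the closed forms:
# integrates the full 3D state and locates the plane crossing numerically.
rk4_flight_oracle <- function(pos0, v0, g, progress_fn, target_progress,
                              dt = 1e-4, tmax = 20) {
  deriv <- function(s) c(s[4:6], 0, -g, 0)
  step <- function(s, h) {
    k1 <- deriv(s)
    k2 <- deriv(s + h / 2 * k1)
    k3 <- deriv(s + h / 2 * k2)
    k4 <- deriv(s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s <- c(pos0, v0)
  t <- 0
  repeat {
    s_next <- step(s, dt)
    t_next <- t + dt
    if (progress_fn(s_next) >= target_progress) break
    s <- s_next
    t <- t_next
    if (t > tmax) return(NULL)  # never reaches the plane
  }
  lo <- 0; hi <- dt
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (progress_fn(step(s, mid)) >= target_progress) hi <- mid else lo <- mid
  }
  list(state = step(s, hi), t = t + hi)
}

# RS: integrate the ball to the vertical plane 4 m forward; return the
# radial miss distance from the bullseye.
rs_rk4_error <- function(u, env) {
  v0 <- env$k * u
  res <- rk4_flight_oracle(env$ball_pos, v0, env$g,
                           progress_fn = function(s) env$ball_pos[["z"]] - s[3],
                           target_progress = env$plane_dist)
  if (is.null(res)) return(Inf)
  lat <- res$state[1] - env$ball_pos[["x"]]
  vert <- res$state[2] - (env$ball_pos[["y"]] + env$bullseye_height)
  unname(sqrt(lat^2 + vert^2))
}

# BA: integrate the arrow (launched at the origin) to the tilted vertical
# target plane and return the radial miss distance from the bullseye.
ba_rk4_error <- function(u, env) {
  theta <- ba_bow_angle(u[1], 1, env$theta_bow_max, env$clamp_angle)
  speed <- env$k * u[2]
  if (speed <= 0) return(Inf)
  v0 <- c(speed * sin(theta), 0, -speed * cos(theta))
  n <- c(sin(env$theta_star), -cos(env$theta_star))  # ground-plane normal
  prog <- function(s) s[1] * n[1] + s[3] * n[2]
  res <- rk4_flight_oracle(c(0, 0, 0), v0, env$g, prog, env$d_target)
  if (is.null(res)) return(Inf)
  l <- c(cos(env$theta_star), sin(env$theta_star))  # in-plane horizontal
  bullseye_xz <- env$d_target * n
  lat <- (res$state[1] - bullseye_xz[1]) * l[1] +
    (res$state[3] - bullseye_xz[2]) * l[2]
  vert <- res$state[2] - (-env$drop_star)
  unname(sqrt(lat^2 + vert^2))
}

# Batch RK4 oracle: integrates many flights simultaneously with the fixed
# 1e-4 s step, then bisects each crossing individually. progress_fn takes
# an n x 6 state matrix and returns per-row progress toward the plane.
rk4_batch_flight <- function(P0, V0, g, progress_fn, target, dt = 1e-4,
                             tmax = 20) {
  n <- nrow(P0)
  S <- cbind(P0, V0)
  bracket <- matrix(NA_real_, n, 6)
  active <- rep(TRUE, n)
  acc <- matrix(rep(c(0, -g, 0), each = n), n)
  step_all <- function(S, h) {
    # constant-acceleration RK4 (all four stages evaluated explicitly)
    a <- acc[seq_len(nrow(S)), , drop = FALSE]
    V <- S[, 4:6, drop = FALSE]
    k1p <- V;              k1v <- a
    k2p <- V + h / 2 * k1v; k2v <- a
    k3p <- V + h / 2 * k2v; k3v <- a
    k4p <- V + h * k3v;     k4v <- a
    cbind(S[, 1:3, drop = FALSE] + h / 6 * (k1p + 2 * k2p + 2 * k3p + k4p),
          V + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v))
  }
  t <- 0
  while (any(active) && t < tmax) {
    S_next <- step_all(S, dt)
    crossed <- active & progress_fn(S_next) >= target
    bracket[crossed, ] <- S[crossed, , drop = FALSE]
    active[crossed] <- FALSE
    S[active, ] <- S_next[active, , drop = FALSE]
    t <- t + dt
  }
  hit <- matrix(NA_real_, n, 6)
  for (i in which(!is.na(bracket[, 1]))) {
    s <- bracket[i, , drop = FALSE]
    lo <- 0; hi <- dt
    for (b in 1:60) {
      mid <- (lo + hi) / 2
      if (progress_fn(step_all(s, mid))[1] >= target[i]) hi <- mid
      else lo <- mid
    }
    hit[i, ] <- step_all(s, hi)
  }
  hit
}

rs_rk4_errors_batch <- function(U, env) {
  n <- nrow(U)
  P0 <- matrix(env$ball_pos, n, 3, byrow = TRUE)
  V0 <- env$k * U
  prog <- function(S) env$ball_pos[["z"]] - S[, 3]
  hit <- rk4_batch_flight(P0, V0, env$g, prog, rep(env$plane_dist, n))
  lat <- hit[, 1] - env$ball_pos[["x"]]
  vert <- hit[, 2] - (env$ball_pos[["y"]] + env$bullseye_height)
  sqrt(lat^2 + vert^2)
}

ba_rk4_errors_batch <- function(U, env) {
  n <- nrow(U)
  theta <- ba_bow_angle(U[, 1], 1, env$theta_bow_max, env$clamp_angle)
  speed <- env$k * U[, 2]
  V0 <- cbind(speed * sin(theta), 0, -speed * cos(theta))
  nvec <- c(sin(env$theta_star), -cos(env$theta_star))
  prog <- function(S) S[, 1] * nvec[1] + S[, 3] * nvec[2]
  hit <- rk4_batch_flight(matrix(0, n, 3), V0, env$g, prog,
                          rep(env$d_target, n))
  l <- c(cos(env$theta_star), sin(env$theta_star))
  bxz <- env$d_target * nvec
  lat <- (hit[, 1] - bxz[1]) * l[1] + (hit[, 3] - bxz[2]) * l[2]
  vert <- hit[, 2] + env$drop_star
  sqrt(lat^2 + vert^2)
}

# All permutations of 1..n (n small), one per row.
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Exhaustive two-variable covariation optimum: minimal mean error over all
# n! pairings of the second column with the first.
c_cost_exhaustive_2var <- function(U, gf) {
  n <- nrow(U)
  perms <- permutations_all(n)
  best <- Inf
  for (p in seq_len(nrow(perms))) {
    V <- cbind(U[, 1], U[perms[p, ], 2])
    best <- min(best, mean(gf$error_fn(V)))
  }
  mean(gf$error_fn(U)) - best
}

# Quaternion for a twist-free tilt of the hanging bag: rotation by theta
# about the horizontal axis perpendicular to the swing direction (azimuth
# az, toward-dominant convention; tilt direction (-sin az, 0, -cos az)).
pb_tilt_quaternion <- function(theta, az) {
  axis <- c(-cos(az), 0, sin(az))  # y-hat x tilt-direction
  c(cos(theta / 2), sin(theta / 2) * axis)
}

quat_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + c(
      a[3] * b[4] - a[4] * b[3],
      a[4] * b[2] - a[2] * b[4],
      a[2] * b[3] - a[3] * b[2]))
}

quat_conj <- function(q) c(q[1], -q[2:4])

# Relative-rotation magnitude (degrees) between two tilt orientations.
pb_rotation_oracle <- function(obs, des) {
  q <- quat_mult(pb_tilt_quaternion(obs[1], obs[2]),
                 quat_conj(pb_tilt_quaternion(des[1], des[2])))
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
}
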