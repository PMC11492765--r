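#' Reach-and-strike task environment
#'
#' The reach-and-strike (RS) task floats a ball (0.31 m diameter) in the
#' reaching workspace; the subject strikes it toward a 2.0 m diameter
#' target whose bullseye lies `plane_dist` (4.0 m) in front of and
#' `bullseye_height` (1.0 m) above the ball. The execution variables are
#' the hand-tracker velocity components at impact, `(vx, vy, vz)` m/s; the
#' ball leaves with velocity `k * u` and flies under gravity to the
#' vertical target plane. Error is the in-plane distance from the bullseye.
#'
#' With the default `k = 1` a forward strike speed of 6 m/s solves the
#' two-point ballistic problem to the bullseye with
#' `u = (0, 4.7705, -6)` m/s (the documented zero-error reference), which
#' lies inside the default TNC search grid.
#'
#' @param ball_pos Ball centre `c(x, y, z)` (m); the default places it
#'   forward of the origin at a typical HMD height.
#' @param k Dimensionless velocity scale from hand velocity to ball
#'   velocity.
#' @param plane_dist Ball-to-target-plane distance (m).
#' @param bullseye_height Bullseye height above the ball (m).
#' @param target_radius Target radius (m); printed target diameter 2.0 m.
#' @param ball_diameter Ball diameter (m).
#' @param g Gravitational acceleration (m/s^2).
#' @return An `rs_environment` (also `task_environment`).
#' @export
rs_environment <- function(ball_pos = c(x = 0.3, y = 1.65, z = -0.4), k = 1,
                           plane_dist = 4, bullseye_height = 1,
                           target_radius = 1, ball_diameter = 0.31,
                           g = GRAVITY) {
  stopifnot(length(ball_pos) == 3L, all(is.finite(ball_pos)),
            k > 0, plane_dist > 0, target_radius > 0, ball_diameter > 0,
            g > 0)
  names(ball_pos) <- c("x", "y", "z")
  structure(
    list(task_id = "RS", ball_pos = ball_pos, k = k, plane_dist = plane_dist,
         bullseye_height = bullseye_height, target_radius = target_radius,
         ball_diameter = ball_diameter, g = g),
    class = c("rs_environment", "task_environment"))
}

#' Reach-and-strike execution mapping
#'
#' The ball position is unchanged by the strike; the ball velocity is the
#' hand velocity scaled by `k`.
#'
#' @param u Execution vector `c(vx, vy, vz)` (m/s).
#' @param env An [rs_environment()].
#' @return A list with `position` and `velocity`.
#' @export
rs_execution_mapping <- function(u, env) {
  stopifnot(inherits(env, "rs_environment"))
  u <- as_execution_matrix(u, 3L)
  if (!all(is.finite(u))) stop("u must be finite", call. = FALSE)
  list(position = env$ball_pos,
       velocity = c(vx = env$k * u[1L], vy = env$k * u[2L],
                    vz = env$k * u[3L]))
}

# Vectorized RS target-plane hit offsets (lateral, vertical) from bullseye.
rs_hits_matrix <- function(U, env) {
  vx <- env$k * U[, 1L]
  vy <- env$k * U[, 2L]
  vz <- env$k * U[, 3L]
  ok <- vz < 0  # forward is -z; the ball must head toward the plane
  tf <- ifelse(ok, env$plane_dist / (-vz), NA_real_)
  lateral <- vx * tf
  vertical <- vy * tf - 0.5 * env$g * tf^2 - env$bullseye_height
  cbind(lateral = lateral, vertical = vertical)
}

#' Reach-and-strike target-plane error
#'
#' Closed-form projectile flight of the ball from the post-execution state
#' to the vertical target plane; error is the planar distance from the
#' bullseye to the intersection point. A strike that does not carry the
#' ball toward the plane is a gross miss.
#'
#' @param state Post-execution ball state from [rs_execution_mapping()].
#' @param env An [rs_environment()].
#' @return A `flight_solution` list: `tflight`, `hit` (lateral, vertical
#'   offsets; m), `radial_error`, `v_i`, `gross_miss`.
#' @export
rs_error <- function(state, env) {
  stopifnot(inherits(env, "rs_environment"))
  v <- state$velocity
  if (v[["vz"]] >= 0) {
    return(structure(list(tflight = NA_real_, hit = c(NA_real_, NA_real_),
                          radial_error = Inf, v_i = v, gross_miss = TRUE),
                     class = "flight_solution"))
  }
  tf <- env$plane_dist / (-v[["vz"]])
  lateral <- v[["vx"]] * tf
  vertical <- v[["vy"]] * tf - 0.5 * env$g * tf^2 - env$bullseye_height
  structure(list(tflight = tf, hit = c(lateral = lateral, vertical = vertical),
                 radial_error = sqrt(lateral^2 + vertical^2), v_i = v,
                 gross_miss = FALSE),
            class = "flight_solution")
}

# Zero-error manifold parameterized by the forward component uz < 0:
# ux = 0 and uy solves the two-point ballistic problem for that flight time.
rs_manifold_point <- function(uz, env) {
  tf <- env$plane_dist / (-env$k * uz)
  uy <- (env$bullseye_height + 0.5 * env$g * tf^2) / (env$k * tf)
  c(0, uy, uz)
}

#' Reach-and-strike goal function
#'
#' @param env An [rs_environment()].
#' @return A [goal_function()] for the RS task. The solution manifold is
#'   the 1-D curve `ux = 0`, `uy = uy(uz)` solving the ballistic problem;
#'   the built-in projection minimizes (optionally weighted) Euclidean
#'   distance along it.
#' @examples
#' gf <- rs_goal_function(rs_environment())
#' evaluate_goal_function(gf, c(0, 4.77045, -6))  # ~0
#' @export
rs_goal_function <- function(env) {
  stopifnot(inherits(env, "rs_environment"))
  error_fn <- function(U) {
    hits <- rs_hits_matrix(U, env)
    e <- sqrt(hits[, 1L]^2 + hits[, 2L]^2)
    ifelse(is.na(e), Inf, e)
  }
  hit_fn <- function(U) rs_hits_matrix(U, env)
  project_fn <- function(u, weights = NULL) {
    w <- if (is.null(weights)) rep(1, 3L) else weights
    dist2 <- function(uz) {
      p <- rs_manifold_point(uz, env)
      sum(w * (u - p)^2)
    }
    opt <- stats::optimize(dist2, interval = c(-60, -1e-3), tol = 1e-12)
    rs_manifold_point(opt$minimum, env)
  }
  goal_function("RS", env, error_fn, hit_fn, project_fn, env$target_radius)
}

#' Zero-error reach-and-strike execution for a given forward speed
#'
#' Solves the two-point ballistic problem to the bullseye: for a forward
#' hand-speed component `uz` (negative, toward the target), returns the
#' unique execution vector on the solution manifold.
#'
#' @param env An [rs_environment()].
#' @param uz Forward velocity component (m/s, negative).
#' @return Execution vector `c(vx, vy, vz)` with zero error.
#' @export
rs_optimal_execution <- function(env, uz = -6) {
  stopifnot(inherits(env, "rs_environment"), uz < 0)
  u <- rs_manifold_point(uz, env)
  names(u) <- c("vx", "vy", "vz")
  u
}
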