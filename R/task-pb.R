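#' Punching bag task environment
#'
#' A capsule-shaped bag (0.875 m long, 0.438 m diameter) hangs with its
#' centre 1.118 m below a pivot. The subject strikes it so that the peak
#' swing orientation matches a desired orientation: amplitude
#' `theta_max_des` at azimuth `phi_des` toward the dominant side. The
#' execution variables are the ground-plane hand velocities `(vx, vz)` m/s
#' and the vertical hit height `d` (m) on the bag. The hit sets the bag's
#' angular speed `omega = k * d * sqrt(vx^2 + vz^2)` and swing direction;
#' the peak amplitude follows from the point-mass energy balance and the
#' scalar error is the axis-angle magnitude of the rotation from the
#' desired to the observed peak orientation, reported in degrees.
#'
#' Azimuth convention: swing azimuth is measured in the ground plane from
#' straight forward (-z), positive toward the dominant side. For the PB
#' strike (which crosses the body from the non-dominant side) the
#' dominant-lateral hand-velocity direction is negative x, so azimuth
#' `= atan2(-vx, -vz)`; the default search grid's negative `vx`, `vz`
#' region maps to azimuths 0-90 degrees toward the dominant side.
#'
#' @param hang Pivot-to-bag-centre distance (m).
#' @param bag_bottom,bag_top Vertical extent of the bag (m); hits must land
#'   within it. Defaults follow the reference scene (bottom at 2.875 m).
#' @param bag_diameter Bag diameter (m), stored for geometry records.
#' @param k Velocity scale (1/m) from `d * speed` to angular speed.
#' @param theta_max_des Desired peak swing amplitude, degrees.
#' @param phi_des Desired swing azimuth toward the dominant side, degrees.
#' @param target_radius Angular target radius, degrees (used by trial
#'   filters and adjustment thresholds).
#' @param g Gravitational acceleration (m/s^2).
#' @param bag_center Optional bag centre position `c(x, y, z)` (m) for
#'   placement records.
#' @return A `pb_environment` (also `task_environment`).
#' @export
pb_environment <- function(hang = 1.118, bag_bottom = 2.875,
                           bag_top = 3.75, bag_diameter = 0.438, k = 0.1,
                           theta_max_des = 20, phi_des = 30,
                           target_radius = 10, g = GRAVITY,
                           bag_center = NULL) {
  stopifnot(hang > 0, bag_top > bag_bottom, bag_bottom > 0, bag_diameter > 0,
            k > 0, theta_max_des > 0, target_radius > 0, g > 0)
  theta_des <- deg2rad(theta_max_des)
  # Angular speed that carries the point-mass bag exactly to theta_des.
  omega_des <- sqrt(2 * g * (1 - cos(theta_des)) / hang)
  structure(
    list(task_id = "PB", hang = hang, bag_bottom = bag_bottom,
         bag_top = bag_top, bag_diameter = bag_diameter, k = k,
         theta_des = theta_des, phi_des = deg2rad(phi_des),
         omega_des = omega_des, target_radius = target_radius, g = g,
         bag_center = bag_center),
    class = c("pb_environment", "task_environment"))
}

#' Punching bag execution mapping
#'
#' Maps `u = (vx, vz, d)` to the bag state just after impact: angular speed
#' `omega = k * d * sqrt(vx^2 + vz^2)` and swing direction `phi`. The
#' returned `phi` is the quadrant-correct two-argument arctangent
#' `atan2(vz, vx)` of the hand velocity (the one-argument form is singular
#' at `vx = 0`); `azimuth` is the same direction re-expressed in the
#' package's toward-dominant convention (see [pb_environment()]).
#'
#' @param u Execution vector `c(vx, vz, d)`.
#' @param env A [pb_environment()].
#' @return A list with `omega` (rad/s), `phi` (rad, `atan2(vz, vx)`), and
#'   `azimuth` (rad, from forward toward the dominant side).
#' @export
pb_execution_mapping <- function(u, env) {
  stopifnot(inherits(env, "pb_environment"))
  u <- as_execution_matrix(u, 3L)
  if (!all(is.finite(u))) stop("u must be finite", call. = FALSE)
  d <- u[3L]
  if (d < env$bag_bottom || d > env$bag_top)
    stop(sprintf("hit height d = %.3f m misses the bag [%.3f, %.3f]",
                 d, env$bag_bottom, env$bag_top), call. = FALSE)
  speed <- sqrt(u[1L]^2 + u[2L]^2)
  list(omega = env$k * d * speed,
       phi = atan2(u[2L], u[1L]),
       azimuth = atan2(-u[1L], -u[2L]))
}

#' Peak swing amplitude from the energy balance
#'
#' Point-mass pendulum energy balance (mass cancels): the initial
#' rotational kinetic energy `L^2 omega^2 / 2` converts to potential energy
#' `g L (1 - cos(theta_max))`, so
#' `theta_max = acos(1 - L * omega^2 / (2 g))`. If the energy would carry
#' the bag past inversion (`L omega^2 / (2g) > 2`) the trial is a gross
#' miss.
#'
#' @param omega Initial angular speed (rad/s). Vectorized.
#' @param hang Pivot-to-bag-centre distance L (m).
#' @param g Gravitational acceleration (m/s^2).
#' @return Peak amplitude(s) `theta_max` (rad); `Inf` on over-energy.
#' @export
pb_peak_amplitude <- function(omega, hang = 1.118, g = GRAVITY) {
  stopifnot(hang > 0, g > 0)
  x <- 1 - hang * omega^2 / (2 * g)
  ifelse(x < -1, Inf, acos(pmax(pmin(x, 1), -1)))
}

#' Small-angle pendulum swing time course
#'
#' Closed-form small-angle solution
#' `theta(t) = theta_max * cos(omega_n * t + phase)` with natural frequency
#' `omega_n = sqrt(g / L)`. Note this oscillation frequency is distinct
#' from the initial angular speed set by the strike. The default phase
#' `-pi/2` starts the bag at the bottom of the swing moving toward the
#' peak, which it reaches at `t = (pi/2) / omega_n`.
#'
#' @param theta_max Peak amplitude (rad).
#' @param t Time(s) since impact (s). Vectorized.
#' @param hang Pivot-to-bag-centre distance L (m).
#' @param phase Phase offset (rad).
#' @param g Gravitational acceleration (m/s^2).
#' @return Swing angle(s) `theta(t)` (rad).
#' @export
pb_swing_time_course <- function(theta_max, t, hang = 1.118, phase = -pi / 2,
                                 g = GRAVITY) {
  stopifnot(hang > 0, g > 0)
  theta_max * cos(sqrt(g / hang) * t + phase)
}

#' Punching bag angular error
#'
#' The scalar error is the axis-angle magnitude of the rotation taking the
#' desired peak swing orientation to the observed one. Each orientation is
#' the twist-free tilt of the hanging bag by its amplitude `theta` about
#' the horizontal axis perpendicular to its swing direction; composing the
#' two rotations (quaternion product) gives the relative rotation, whose
#' scalar part is
#' `cos(error/2) = cos(t1/2) cos(t2/2) + sin(t1/2) sin(t2/2) cos(az1 - az2)`.
#'
#' @param observed `c(theta_max, azimuth)` in radians (toward-dominant
#'   azimuth convention).
#' @param desired `c(theta_max, azimuth)` in radians.
#' @return Angular error in degrees.
#' @export
pb_error <- function(observed, desired) {
  stopifnot(length(observed) == 2L, length(desired) == 2L,
            all(is.finite(observed)), all(is.finite(desired)))
  rad2deg(relative_tilt_angle(observed[1L], observed[2L], desired[1L],
                              desired[2L]))
}

# Axis-angle magnitude of q(t1, az1) * q(t2, az2)^-1 for twist-free tilt
# quaternions, in the atan2 form which stays accurate near zero (the acos
# form loses half the significant digits there).
relative_tilt_angle <- function(t1, az1, t2, az2) {
  c1 <- cos(t1 / 2); s1 <- sin(t1 / 2)
  c2 <- cos(t2 / 2); s2 <- sin(t2 / 2)
  dphi <- az1 - az2
  w <- c1 * c2 + s1 * s2 * cos(dphi)
  # vector part: horizontal component plus the vertical n1 x n2 component
  horiz2 <- (c2 * s1)^2 + (c1 * s2)^2 -
    2 * c1 * c2 * s1 * s2 * cos(dphi)
  vert2 <- (s1 * s2 * sin(dphi))^2
  2 * atan2(sqrt(pmax(horiz2 + vert2, 0)), abs(w))
}

#' Swing direction / swing height error decomposition
#'
#' Splits the total angular error into a swing-height component (amplitude
#' mismatch, `|theta_obs - theta_des|` in degrees) and a signed
#' swing-direction component: the angular error after equalizing the
#' observed amplitude to the desired one, signed positive when the
#' observed swing is more lateral than desired (azimuth short of the
#' desired toward-dominant azimuth). For small angles the two components
#' recombine to the total error in quadrature.
#'
#' @param observed `c(theta_max, azimuth)` in radians.
#' @param desired `c(theta_max, azimuth)` in radians.
#' @return A list with `direction` and `height`, both degrees.
#' @export
pb_error_decomposition <- function(observed, desired) {
  stopifnot(length(observed) == 2L, length(desired) == 2L)
  height <- rad2deg(abs(observed[1L] - desired[1L]))
  dir_mag <- pb_error(c(desired[1L], observed[2L]), desired)
  direction <- sign(desired[2L] - observed[2L]) * dir_mag
  list(direction = direction, height = height)
}

# Vectorized PB angular error in degrees; Inf for gross miss (over-energy)
# and for hits outside the bag's vertical extent.
pb_error_matrix <- function(U, env) {
  d <- U[, 3L]
  speed <- sqrt(U[, 1L]^2 + U[, 2L]^2)
  omega <- env$k * d * speed
  theta <- pb_peak_amplitude(omega, env$hang, env$g)
  over <- !is.finite(theta)
  theta[over] <- 0
  az <- atan2(-U[, 1L], -U[, 2L])
  e <- rad2deg(relative_tilt_angle(theta, az, env$theta_des, env$phi_des))
  e[over] <- Inf
  e[d < env$bag_bottom | d > env$bag_top] <- Inf
  e
}

# Zero-error manifold parameterized by hit height d: speed fixed by the
# desired angular speed, direction fixed by the desired azimuth.
pb_manifold_point <- function(d, env) {
  speed <- env$omega_des / (env$k * d)
  c(-speed * sin(env$phi_des), -speed * cos(env$phi_des), d)
}

#' Punching bag goal function
#'
#' @param env A [pb_environment()].
#' @return A [goal_function()] for the PB task (errors in degrees). The
#'   solution manifold is the 1-D curve of hits along the bag whose speed
#'   yields the desired angular speed in the desired direction. In the
#'   vectorized error function, hits outside the bag's vertical extent map
#'   to the gross-miss sentinel (the single-trial
#'   [pb_execution_mapping()] raises an input error instead) so that
#'   optimization sweeps over candidate sets remain well-defined.
#' @examples
#' env <- pb_environment()
#' gf <- pb_goal_function(env)
#' u0 <- pb_optimal_execution(env)
#' evaluate_goal_function(gf, u0)  # 0
#' @export
pb_goal_function <- function(env) {
  stopifnot(inherits(env, "pb_environment"))
  error_fn <- function(U) pb_error_matrix(U, env)
  project_fn <- function(u, weights = NULL) {
    w <- if (is.null(weights)) rep(1, 3L) else weights
    dist2 <- function(d) {
      p <- pb_manifold_point(d, env)
      sum(w * (u - p)^2)
    }
    opt <- stats::optimize(dist2, interval = c(env$bag_bottom, env$bag_top),
                           tol = 1e-12)
    pb_manifold_point(opt$minimum, env)
  }
  goal_function("PB", env, error_fn, hit_fn = NULL, project_fn,
                env$target_radius)
}

#' Zero-error punching bag execution at a given hit height
#'
#' @param env A [pb_environment()].
#' @param d Hit height (m) within the bag extent; defaults to the bag's
#'   lower-half midpoint used by the default search grid.
#' @return Execution vector `c(vx, vz, d)` with zero angular error.
#' @export
pb_optimal_execution <- function(env, d = NULL) {
  stopifnot(inherits(env, "pb_environment"))
  if (is.null(d)) d <- env$bag_bottom + 0.2915
  stopifnot(d >= env$bag_bottom, d <= env$bag_top)
  u <- pb_manifold_point(d, env)
  names(u) <- c("vx", "vz", "d")
  u
}
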