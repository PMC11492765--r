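#' Bow-and-arrow task environment
#'
#' Builds the calibrated bow-and-arrow (BA) environment. The two execution
#' variables are the lateral chest excursion normalized by the baseline
#' lateral chest limit (`chest_norm`) and the bowstring draw length
#' normalized by upper limb length (`pull_norm`). Leaning rotates the bow
#' about the vertical axis: the bow yaw angle is linear in chest excursion
#' and reaches `theta_bow_max` (15 degrees) at the baseline maximum
#' excursion. The arrow leaves the bow centre with ground-plane speed
#' `k * pull_norm` along the bow direction and flies under gravity to a
#' target plane perpendicular to the optimal arrow path.
#'
#' Calibration: the optimal bow angle `theta_star` corresponds to leaning
#' exactly to the condition's excursion fraction (0.65 / 0.80 / 0.95 of the
#' baseline limit), and the optimal draw is 65% of upper limb length. The
#' bullseye sits `d_target` metres from the bow along the optimal direction,
#' lowered by the gravity drop of that optimal shot, so the optimal
#' execution has exactly zero radial error while gravity still acts on
#' every arrow.
#'
#' @param x_max Baseline maximal lateral chest excursion (m).
#' @param condition Lean condition `"near"` (65%), `"mid"` (80%), or
#'   `"far"` (95%); sets the optimal chest excursion fraction.
#' @param k Velocity scaling constant mapping normalized draw to arrow
#'   speed (m/s per unit normalized draw).
#' @param d_target Bow-to-bullseye distance (m).
#' @param theta_bow_max Maximal bow yaw angle, degrees.
#' @param target_radius Target radius (m).
#' @param pull_opt Optimal normalized draw length (fraction of upper limb
#'   length).
#' @param g Gravitational acceleration (m/s^2).
#' @param clamp_angle Clamp the bow angle to `[0, theta_bow_max]` for
#'   excursions outside the baseline range (on by default; the mapping is
#'   otherwise linear and unbounded).
#' @param include_drop Include the vertical (gravity-drop) component in the
#'   radial error (default) or use only the ground-plane deviation.
#' @param bow_center Optional bow centre position `c(x, y, z)` (m), stored
#'   for serialization/placement; the error depends only on relative
#'   geometry.
#' @return A `ba_environment` (also `task_environment`).
#' @examples
#' env <- ba_environment(x_max = 0.25, condition = "far")
#' rad2deg <- function(x) x * 180 / pi
#' rad2deg(env$theta_star)  # 0.95 * 15 degrees
#' @export
ba_environment <- function(x_max, condition = "mid", k = 20, d_target = 10,
                           theta_bow_max = 15, target_radius = 0.5,
                           pull_opt = 0.65, g = GRAVITY, clamp_angle = TRUE,
                           include_drop = TRUE, bow_center = NULL) {
  condition <- match.arg(condition, c("near", "mid", "far"))
  stopifnot(is.numeric(x_max), length(x_max) == 1L, is.finite(x_max))
  if (x_max <= 0) stop("x_max must be positive", call. = FALSE)
  stopifnot(k > 0, d_target > 0, theta_bow_max > 0, target_radius > 0,
            pull_opt > 0, g > 0)
  frac <- condition_fraction(condition)
  theta_max <- deg2rad(theta_bow_max)
  theta_star <- frac * theta_max
  v_opt <- k * pull_opt
  t_opt <- d_target / v_opt
  drop_star <- 0.5 * g * t_opt^2
  structure(
    list(task_id = "BA", condition = condition, x_max = x_max, k = k,
         d_target = d_target, theta_bow_max = theta_max,
         theta_star = theta_star, chest_opt = frac, pull_opt = pull_opt,
         drop_star = drop_star, target_radius = target_radius, g = g,
         clamp_angle = clamp_angle, include_drop = include_drop,
         bow_center = bow_center),
    class = c("ba_environment", "task_environment"))
}

condition_fraction <- function(condition) {
  c(near = 0.65, mid = 0.80, far = 0.95)[[condition]]
}

#' Bow yaw angle from chest excursion
#'
#' The bow angle is linear in the lateral chest excursion and reaches
#' `theta_bow_max` when the excursion equals the baseline maximum. Outside
#' `[0, x_max]` the angle is clamped to `[0, theta_bow_max]` when
#' `clamp = TRUE` (over-leaning cannot rotate the bow past its stop).
#'
#' @param x_chest Instantaneous lateral chest excursion (m). Vectorized.
#' @param x_max Baseline maximal lateral chest excursion (m), positive.
#' @param theta_bow_max Maximal bow angle (rad); default 15 degrees.
#' @param clamp Clamp to `[0, theta_bow_max]`.
#' @return Bow angle(s), radians.
#' @examples
#' ba_bow_angle(0.25, 0.25) * 180 / pi  # 15
#' @export
ba_bow_angle <- function(x_chest, x_max, theta_bow_max = deg2rad(15),
                         clamp = TRUE) {
  if (!is.numeric(x_max) || length(x_max) != 1L || !is.finite(x_max) ||
      x_max <= 0)
    stop("x_max must be a positive scalar", call. = FALSE)
  theta <- (x_chest / x_max) * theta_bow_max
  if (clamp) theta <- pmin(pmax(theta, 0), theta_bow_max)
  theta
}

#' Bow-and-arrow execution mapping
#'
#' Maps the execution vector `u = (chest_norm, pull_norm)` to the arrow
#' state just before flight: position at the bow centre (regardless of draw)
#' and ground-plane velocity of magnitude `k * pull_norm` directed at the
#' bow angle from the forward axis.
#'
#' @param u Execution vector `c(chest_norm, pull_norm)`.
#' @param env A [ba_environment()].
#' @return A list with `position` (`c(x, y, z)`, m), `velocity`
#'   (`c(vx, vy, vz)`, m/s), and `theta_bow` (rad).
#' @export
ba_execution_mapping <- function(u, env) {
  stopifnot(inherits(env, "ba_environment"))
  u <- as_execution_matrix(u, 2L)
  if (!all(is.finite(u))) stop("u must be finite", call. = FALSE)
  theta <- ba_bow_angle(u[1L], 1, env$theta_bow_max, env$clamp_angle)
  speed <- env$k * u[2L]
  pos <- if (is.null(env$bow_center)) c(x = 0, y = 0, z = 0) else env$bow_center
  list(position = pos,
       velocity = c(vx = speed * sin(theta), vy = 0,
                    vz = -speed * cos(theta)),
       theta_bow = theta)
}

#' Arrow flight to the target plane
#'
#' Computes the closed-form flight of the arrow from the post-execution
#' state to the target plane (the vertical plane through the bullseye,
#' perpendicular to the optimal ground-plane arrow direction). The flight
#' time is `d_target / (speed * cos(theta_star - theta_bow))`; the in-plane
#' lateral offset follows from ground-plane kinematics and the vertical
#' offset from the gravity drop relative to the calibrated bullseye height.
#'
#' @param state Post-execution arrow state from [ba_execution_mapping()].
#' @param env A [ba_environment()].
#' @return A `flight_solution` list: `tflight` (s), `hit` (2D offset from
#'   the bullseye: lateral, vertical; m), `radial_error` (m), `v_i`
#'   (initial velocity). Gross misses (no ground-plane speed, or arrow
#'   heading away from the plane) return `tflight = NA`, `radial_error =
#'   Inf`, and `gross_miss = TRUE`.
#' @export
ba_flight <- function(state, env) {
  stopifnot(inherits(env, "ba_environment"))
  v <- state$velocity
  speed <- sqrt(v[["vx"]]^2 + v[["vz"]]^2)
  theta <- atan2(v[["vx"]], -v[["vz"]])
  delta <- env$theta_star - theta
  if (speed <= 0 || cos(delta) <= 0) {
    return(structure(list(tflight = NA_real_, hit = c(NA_real_, NA_real_),
                          radial_error = Inf, v_i = v, gross_miss = TRUE),
                     class = "flight_solution"))
  }
  tf <- env$d_target / (speed * cos(delta))
  lateral <- env$d_target * tan(delta)
  vertical <- env$drop_star - 0.5 * env$g * tf^2
  err <- if (env$include_drop) sqrt(lateral^2 + vertical^2) else abs(lateral)
  structure(list(tflight = tf, hit = c(lateral = lateral, vertical = vertical),
                 radial_error = err, v_i = v, gross_miss = FALSE),
            class = "flight_solution")
}

# Vectorized BA target-plane geometry shared by error_fn and hit_fn.
ba_hits_matrix <- function(U, env) {
  theta <- ba_bow_angle(U[, 1L], 1, env$theta_bow_max, env$clamp_angle)
  speed <- env$k * U[, 2L]
  delta <- env$theta_star - theta
  ok <- speed > 0 & cos(delta) > 0
  tf <- ifelse(ok, env$d_target / (speed * cos(delta)), NA_real_)
  lateral <- ifelse(ok, env$d_target * tan(delta), NA_real_)
  vertical <- ifelse(ok, env$drop_star - 0.5 * env$g * tf^2, NA_real_)
  cbind(lateral = lateral, vertical = vertical)
}

#' Bow-and-arrow goal function
#'
#' @param env A [ba_environment()].
#' @return A [goal_function()] for the BA task. The solution manifold of
#'   this task is the single point `(chest_opt, pull_opt)`.
#' @examples
#' gf <- ba_goal_function(ba_environment(0.25, "near"))
#' evaluate_goal_function(gf, c(0.65, 0.65))  # 0
#' @export
ba_goal_function <- function(env) {
  stopifnot(inherits(env, "ba_environment"))
  error_fn <- function(U) {
    hits <- ba_hits_matrix(U, env)
    e <- if (env$include_drop) sqrt(hits[, 1L]^2 + hits[, 2L]^2)
         else abs(hits[, 1L])
    ifelse(is.na(e), Inf, e)
  }
  hit_fn <- function(U) ba_hits_matrix(U, env)
  project_fn <- function(u, weights = NULL) c(env$chest_opt, env$pull_opt)
  goal_function("BA", env, error_fn, hit_fn, project_fn, env$target_radius)
}

#' Bow release / misfire classifier
#'
#' Classifies a draw from two time-aligned tracker series: the off-hand
#' (grip hand) distance to the bow grip, and the dominant-hand displacement
#' out of the draw plane. The draw is a misfire as soon as the off-hand
#' drifts more than `misfire_dist` (0.08 m) from the grip; otherwise the
#' arrow fires at the first sample where the off-plane displacement exceeds
#' `fire_dist` (0.14 m); otherwise the arrow is held. Misfired trials earn
#' no points and are flagged in the trial block.
#'
#' @param offhand_dist Numeric series: off-hand distance to the bow grip (m).
#' @param offplane_disp Numeric series, same length: dominant-hand
#'   displacement out of the bow plane (m).
#' @param misfire_dist Misfire threshold (m).
#' @param fire_dist Fire threshold (m).
#' @return A list with `status` (`"fired"`, `"misfired"`, or `"held"`) and
#'   `fire_index` (first sample past the fire threshold, or `NA`).
#' @export
ba_release_classifier <- function(offhand_dist, offplane_disp,
                                  misfire_dist = 0.08, fire_dist = 0.14) {
  if (length(offhand_dist) == 0L || length(offplane_disp) == 0L)
    stop("empty trajectory", call. = FALSE)
  if (length(offhand_dist) != length(offplane_disp))
    stop("trajectories must be time-aligned (equal length)", call. = FALSE)
  fire_idx <- which(offplane_disp > fire_dist)
  fire_at <- if (length(fire_idx)) fire_idx[1L] else NA_integer_
  # Misfire applies during the draw, i.e. before any release.
  draw_end <- if (is.na(fire_at)) length(offhand_dist) else fire_at
  if (any(offhand_dist[seq_len(draw_end)] > misfire_dist))
    return(list(status = "misfired", fire_index = NA_integer_))
  if (!is.na(fire_at)) return(list(status = "fired", fire_index = fire_at))
  list(status = "held", fire_index = NA_integer_)
}
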