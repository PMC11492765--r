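#' Place task objects in the subject's workspace
#'
#' Computes a calibrated task environment from star-test workspace limits
#' and anthropometrics. Conditions map to fractions of the relevant
#' baseline limit: near 65%, mid 80%, far 95%.
#'
#' Placement rules: the bow centre sits 90% of the upper limb length
#' forward and laterally (dominant side) at the condition fraction of the
#' baseline lateral chest limit; the ball sits at the neutral HMD height,
#' 50% of the baseline forward reach, and laterally (dominant side) at the
#' condition fraction of the lateral reach limit; the bag centre sits at
#' the neutral HMD height, 50% of the forward reach, laterally on the
#' non-dominant side at the condition fraction of the lateral reach limit,
#' 1.118 m below its pivot.
#'
#' @param limits A [workspace_limits()].
#' @param anthro An [anthropometrics()].
#' @param task_id `"BA"`, `"RS"`, or `"PB"`.
#' @param condition `"near"`, `"mid"`, or `"far"`.
#' @param ... Further arguments (physics constants, target radii) passed to
#'   the task's environment constructor.
#' @return A task environment ([ba_environment()], [rs_environment()], or
#'   [pb_environment()]) with the placed object position attached.
#' @examples
#' lim <- workspace_limits(
#'   chest_limit = c(R = 0.20, FR = 0.18, F = 0.12, FL = 0.18, L = 0.20),
#'   hand_limit  = c(R = 0.95, FR = 0.88, F = 0.80, FL = 0.88, L = 0.95),
#'   neutral_hmd_height = 1.65)
#' ant <- anthropometrics(1.75, 0.70)
#' env <- place_objects(lim, ant, "BA", "far")
#' env$bow_center  # 0.63 m forward, 0.19 m lateral
#' @export
place_objects <- function(limits, anthro, task_id, condition = "mid", ...) {
  stopifnot(inherits(limits, "workspace_limits"),
            inherits(anthro, "anthropometrics"))
  task_id <- match.arg(task_id, c("BA", "RS", "PB"))
  condition <- match.arg(condition, c("near", "mid", "far"))
  frac <- condition_fraction(condition)
  # +x is the dominant side; the star test is symmetric in naming, so the
  # dominant-lateral chest/hand limit is the R limit for right-handers.
  dom <- if (anthro$handedness == "right") "R" else "L"
  nondom <- if (anthro$handedness == "right") "L" else "R"
  switch(task_id,
    BA = {
      x_max <- limits$chest_limit[[dom]]
      bow_center <- c(x = frac * x_max, y = limits$neutral_hmd_height,
                      z = -0.9 * anthro$upper_limb_length)
      ba_environment(x_max = x_max, condition = condition,
                     bow_center = bow_center, ...)
    },
    RS = {
      ball_pos <- c(x = frac * limits$hand_limit[[dom]],
                    y = limits$neutral_hmd_height,
                    z = -0.5 * limits$hand_limit[["F"]])
      rs_environment(ball_pos = ball_pos, ...)
    },
    PB = {
      args <- list(...)
      hang <- if (!is.null(args$hang)) args$hang else 1.118
      bag_len <- 0.875
      center_y <- limits$neutral_hmd_height
      bag_center <- c(x = -frac * limits$hand_limit[[nondom]],
                      y = center_y, z = -0.5 * limits$hand_limit[["F"]])
      args$bag_bottom <- center_y - bag_len / 2
      args$bag_top <- center_y + bag_len / 2
      args$bag_center <- bag_center
      do.call(pb_environment, args)
    })
}

#' Build the goal function for a task environment
#'
#' Generic dispatcher: returns [ba_goal_function()], [rs_goal_function()],
#' or [pb_goal_function()] according to the environment class.
#'
#' @param env A task environment.
#' @return A [goal_function()].
#' @export
task_goal_function <- function(env) {
  stopifnot(inherits(env, "task_environment"))
  switch(env$task_id,
         BA = ba_goal_function(env),
         RS = rs_goal_function(env),
         PB = pb_goal_function(env))
}
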