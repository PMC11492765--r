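#' Coordinate frame and shared conventions
#'
#' All geometry in goalfun uses a right-handed frame with +y up, -z forward
#' (away from the subject), and +x toward the subject's dominant side, with
#' the origin at the mid-stance ground point. Units are SI throughout (m,
#' m/s, rad); degrees appear only at I/O boundaries (configuration files and
#' reported punching-bag angular errors).
#'
#' @name goalfun-frame
#' @keywords internal
NULL

# Star-test directions, 45 degrees apart.
STAR_DIRECTIONS <- c("R", "FR", "F", "FL", "L")

GRAVITY <- 9.81

#' Subject anthropometrics
#'
#' @param height Standing height in metres.
#' @param upper_limb_length Upper limb length (shoulder to hand) in metres.
#' @param handedness `"right"` or `"left"`.
#' @return An object of class `anthropometrics`.
#' @examples
#' anthropometrics(1.75, 0.72)
#' @export
anthropometrics <- function(height, upper_limb_length, handedness = "right") {
  stopifnot(is.numeric(height), length(height) == 1L, is.finite(height),
            is.numeric(upper_limb_length), length(upper_limb_length) == 1L,
            is.finite(upper_limb_length))
  if (height <= 0 || upper_limb_length <= 0)
    stop("anthropometric lengths must be positive", call. = FALSE)
  if (upper_limb_length >= height)
    stop("upper_limb_length must be smaller than height", call. = FALSE)
  handedness <- match.arg(handedness, c("right", "left"))
  structure(
    list(height = height, upper_limb_length = upper_limb_length,
         handedness = handedness),
    class = "anthropometrics")
}

#' Lean/reach standing star-test workspace limits
#'
#' Maximal chest and hand excursions measured along the five star directions
#' (right, forward-right, forward, forward-left, left, 45 degrees apart),
#' plus the neutral-stance height of the head-mounted display. These limits
#' scale task geometry to the subject's reachable workspace.
#'
#' @param chest_limit Named numeric vector of maximal chest excursions (m)
#'   for directions `R`, `FR`, `F`, `FL`, `L`.
#' @param hand_limit Named numeric vector of maximal hand reach distances (m)
#'   for the same five directions.
#' @param neutral_hmd_height Neutral-stance HMD height (m).
#' @return An object of class `workspace_limits`.
#' @examples
#' workspace_limits(
#'   chest_limit = c(R = 0.27, FR = 0.22, F = 0.14, FL = 0.22, L = 0.27),
#'   hand_limit  = c(R = 0.97, FR = 0.88, F = 0.79, FL = 0.87, L = 0.97),
#'   neutral_hmd_height = 1.65)
#' @export
workspace_limits <- function(chest_limit, hand_limit, neutral_hmd_height) {
  check_limits <- function(x, what) {
    if (is.null(names(x)) || !setequal(names(x), STAR_DIRECTIONS))
      stop(sprintf("%s must be named with exactly the star directions %s",
                   what, paste(STAR_DIRECTIONS, collapse = ", ")),
           call. = FALSE)
    if (!all(is.finite(x)) || any(x <= 0))
      stop(sprintf("%s must be finite and positive", what), call. = FALSE)
    x[STAR_DIRECTIONS]
  }
  chest_limit <- check_limits(chest_limit, "chest_limit")
  hand_limit <- check_limits(hand_limit, "hand_limit")
  stopifnot(is.numeric(neutral_hmd_height), length(neutral_hmd_height) == 1L,
            is.finite(neutral_hmd_height))
  if (neutral_hmd_height <= 0)
    stop("neutral_hmd_height must be positive", call. = FALSE)
  structure(
    list(chest_limit = chest_limit, hand_limit = hand_limit,
         neutral_hmd_height = neutral_hmd_height),
    class = "workspace_limits")
}

#' Execution-variable schema per task
#'
#' Returns the ordered execution-variable names for a task, together with
#' each variable's kind (`"position"` or `"velocity"`), which the adjustment
#' step uses to decide which columns velocity scaling applies to.
#'
#' Variables: bow-and-arrow (`BA`) uses lateral chest excursion normalized by
#' the baseline lateral chest limit (`chest_norm`) and bowstring draw length
#' normalized by upper limb length (`pull_norm`); reach-and-strike (`RS`)
#' uses the hand velocity components at impact (`vx`, `vy`, `vz`, m/s);
#' punching bag (`PB`) uses the ground-plane hand velocities (`vx`, `vz`,
#' m/s) and the vertical hit height on the bag (`d`, m).
#'
#' @param task_id One of `"BA"`, `"RS"`, `"PB"`.
#' @return A list with elements `names`, `kind`, and `arity`.
#' @export
task_variables <- function(task_id) {
  task_id <- match.arg(task_id, c("BA", "RS", "PB"))
  switch(task_id,
    BA = list(names = c("chest_norm", "pull_norm"),
              kind = c("position", "position"), arity = 2L),
    RS = list(names = c("vx", "vy", "vz"),
              kind = c("velocity", "velocity", "velocity"), arity = 3L),
    PB = list(names = c("vx", "vz", "d"),
              kind = c("velocity", "velocity", "position"), arity = 3L))
}

#' @export
print.anthropometrics <- function(x, ...) {
  cat(sprintf("Anthropometrics: height %.3f m, upper limb %.3f m, %s-handed\n",
              x$height, x$upper_limb_length, x$handedness))
  invisible(x)
}

#' @export
print.workspace_limits <- function(x, ...) {
  cat("Workspace limits (m):\n")
  print(rbind(chest = x$chest_limit, hand = x$hand_limit))
  cat(sprintf("Neutral HMD height: %.3f m\n", x$neutral_hmd_height))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Ensure a candidate execution matrix: accepts vector (one trial) or matrix.
as_execution_matrix <- function(u, arity, var_names = NULL) {
  if (is.null(dim(u))) {
    if (length(u) != arity)
      stop(sprintf("execution vector has %d components; task arity is %d",
                   length(u), arity), call. = FALSE)
    u <- matrix(u, nrow = 1L)
  } else {
    u <- as.matrix(u)
    if (ncol(u) != arity)
      stop(sprintf("execution matrix has %d columns; task arity is %d",
                   ncol(u), arity), call. = FALSE)
  }
  if (!is.numeric(u)) stop("execution variables must be numeric", call. = FALSE)
  if (!is.null(var_names)) colnames(u) <- var_names
  u
}
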