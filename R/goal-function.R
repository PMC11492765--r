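#' Goal-function objects
#'
#' A goal function is the two-step mapping from a trial's execution
#' variables to a scalar performance error: the execution mapping `S` takes
#' the execution vector `u` and the pre-execution virtual-object state to
#' the post-execution object state, and the environment mapping `V` takes
#' that state through the virtual physics to a nonnegative error. Trials
#' whose object cannot reach the target plane (or whose pendulum would pass
#' inversion) receive the gross-miss sentinel `Inf`.
#'
#' `goal_function()` is the low-level constructor used by the task builders
#' [ba_goal_function()], [rs_goal_function()], and [pb_goal_function()];
#' most users construct task environments with [place_objects()] and build
#' the goal function from those.
#'
#' @param task_id Task identifier, `"BA"`, `"RS"`, or `"PB"`.
#' @param env Task environment (geometry, physics constants, target radius).
#' @param error_fn Vectorized error function: n x m execution matrix in,
#'   length-n nonnegative numeric out (`Inf` marks a gross miss).
#' @param hit_fn Optional vectorized target-frame hit function: execution
#'   matrix in, n x 2 matrix of hit coordinates relative to the bullseye out
#'   (rows of `NA` for gross misses). `NULL` for tasks without a target
#'   plane (PB).
#' @param project_fn Optional task-specific solution-manifold projection,
#'   `function(u, weights)` returning the nearest zero-error execution; when
#'   `NULL` the generic multi-start search in [project_to_manifold()] is
#'   used.
#' @param target_radius Target radius, metres (BA/RS) or degrees (PB).
#' @return An object of class `goal_function`.
#' @export
goal_function <- function(task_id, env, error_fn, hit_fn = NULL,
                          project_fn = NULL, target_radius) {
  task_id <- match.arg(task_id, c("BA", "RS", "PB"))
  stopifnot(is.function(error_fn),
            is.null(hit_fn) || is.function(hit_fn),
            is.null(project_fn) || is.function(project_fn),
            is.numeric(target_radius), length(target_radius) == 1L,
            is.finite(target_radius), target_radius > 0)
  schema <- task_variables(task_id)
  structure(
    list(task_id = task_id, env = env, error_fn = error_fn, hit_fn = hit_fn,
         project_fn = project_fn, target_radius = target_radius,
         arity = schema$arity, var_names = schema$names,
         var_kind = schema$kind),
    class = "goal_function")
}

#' @export
print.goal_function <- function(x, ...) {
  unit <- if (x$task_id == "PB") "deg" else "m"
  cat(sprintf("Goal function: task %s (%s), target radius %.3f %s\n",
              x$task_id, paste(x$var_names, collapse = ", "),
              x$target_radius, unit))
  invisible(x)
}

#' Evaluate a goal function on one execution vector
#'
#' Applies the execution mapping and then the environment mapping, returning
#' the scalar performance error. Deterministic; repeated calls on identical
#' inputs give identical results. Returns `Inf` (the gross-miss sentinel)
#' when the virtual object cannot reach the target plane.
#'
#' @param gf A [goal_function()].
#' @param u Numeric execution vector whose length matches the task arity.
#' @return Scalar nonnegative error, or `Inf` for a gross miss.
#' @examples
#' env <- ba_environment(x_max = 0.25, condition = "mid")
#' gf <- ba_goal_function(env)
#' evaluate_goal_function(gf, c(0.80, 0.65))  # calibrated optimum: 0
#' @export
evaluate_goal_function <- function(gf, u) {
  stopifnot(inherits(gf, "goal_function"))
  u <- as_execution_matrix(u, gf$arity, gf$var_names)
  if (nrow(u) != 1L)
    stop("evaluate_goal_function takes a single execution vector", call. = FALSE)
  if (!all(is.finite(u)))
    stop("execution variables must be finite", call. = FALSE)
  as.numeric(gf$error_fn(u))
}

#' Target-frame hit coordinates for a block of executions
#'
#' @param gf A [goal_function()] with a target plane (BA or RS).
#' @param U Execution matrix or [trial_block()].
#' @return n x 2 matrix of hit offsets from the bullseye (m); rows of `NA`
#'   for gross misses.
#' @export
target_hits <- function(gf, U) {
  stopifnot(inherits(gf, "goal_function"))
  if (is.null(gf$hit_fn))
    stop(sprintf("task %s has no target plane", gf$task_id), call. = FALSE)
  if (inherits(U, "trial_block")) U <- U$U
  U <- as_execution_matrix(U, gf$arity, gf$var_names)
  gf$hit_fn(U)
}
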