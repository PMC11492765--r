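#' Trial blocks
#'
#' A trial block is an n x m matrix `U` of trial executions (one row per
#' trial, columns named after the task's execution variables) plus task and
#' condition metadata and per-trial flags. Excluded and misfired trials are
#' flagged, never dropped: filtering and exclusion semantics belong to the
#' metrics layer.
#'
#' @param U Numeric matrix (or single numeric vector) of executions, one row
#'   per trial; column count must match the task arity.
#' @param task_id One of `"BA"`, `"RS"`, `"PB"`.
#' @param condition Lean/reach condition: `"near"`, `"mid"`, or `"far"`.
#' @param block_index Positive integer block number.
#' @param misfire Logical per-trial misfire flags (BA only in practice).
#' @param excluded Logical per-trial exclusion flags.
#' @param error Optional per-trial scalar error cache (`NA` until scored).
#' @return An object of class `trial_block`.
#' @seealso [score_block()], [filter_trials()]
#' @export
trial_block <- function(U, task_id, condition = "mid", block_index = 1L,
                        misfire = NULL, excluded = NULL, error = NULL) {
  task_id <- match.arg(task_id, c("BA", "RS", "PB"))
  condition <- match.arg(condition, c("near", "mid", "far"))
  schema <- task_variables(task_id)
  U <- as_execution_matrix(U, schema$arity, schema$names)
  n <- nrow(U)
  if (n < 1L) stop("a trial block needs at least one trial", call. = FALSE)
  if (!all(is.finite(U)))
    stop("all execution variables must be finite", call. = FALSE)
  block_index <- as.integer(block_index)
  stopifnot(length(block_index) == 1L, block_index >= 1L)
  check_flag <- function(x, what) {
    if (is.null(x)) return(rep(FALSE, n))
    x <- as.logical(x)
    if (length(x) != n || anyNA(x))
      stop(sprintf("%s must be a logical vector of length n", what),
           call. = FALSE)
    x
  }
  misfire <- check_flag(misfire, "misfire")
  excluded <- check_flag(excluded, "excluded")
  if (is.null(error)) error <- rep(NA_real_, n)
  stopifnot(length(error) == n)
  structure(
    list(U = U, task_id = task_id, condition = condition,
         block_index = block_index, misfire = misfire, excluded = excluded,
         error = as.numeric(error)),
    class = "trial_block")
}

#' @export
print.trial_block <- function(x, ...) {
  cat(sprintf("Trial block: task %s, %s condition, block %d, %d trials\n",
              x$task_id, x$condition, x$block_index, nrow(x$U)))
  cat(sprintf("  misfires: %d, excluded: %d, scored: %d\n",
              sum(x$misfire), sum(x$excluded), sum(!is.na(x$error))))
  invisible(x)
}

#' @export
as.data.frame.trial_block <- function(x, ...) {
  data.frame(task_id = x$task_id, condition = x$condition,
             block_index = x$block_index, as.data.frame(x$U),
             misfire = x$misfire, excluded = x$excluded, error = x$error,
             stringsAsFactors = FALSE)
}

n_trials <- function(block) nrow(block$U)

# Trials that enter analyses: not excluded, not misfired.
valid_trials <- function(block) !block$excluded & !block$misfire

#' Score a trial block under a goal function
#'
#' Fills the per-trial error cache for all non-excluded trials and computes
#' the block mean error over non-excluded, non-misfire, non-gross-miss
#' trials. Gross misses (trials whose virtual object never reaches the
#' target plane) carry an infinite error and are reported, not dropped.
#'
#' @param gf A [goal_function()].
#' @param block A [trial_block()] with matching task.
#' @return The block, with `error` filled, and attributes `mean_error`
#'   (mean over valid finite-error trials) and `n_gross_miss`.
#' @export
score_block <- function(gf, block) {
  stopifnot(inherits(gf, "goal_function"), inherits(block, "trial_block"))
  if (gf$task_id != block$task_id)
    stop("goal function and block belong to different tasks", call. = FALSE)
  if (n_trials(block) < 1L) stop("empty block", call. = FALSE)
  e <- gf$error_fn(block$U)
  block$error <- e
  use <- valid_trials(block) & is.finite(e)
  attr(block, "mean_error") <- if (any(use)) mean(e[use]) else NA_real_
  attr(block, "n_gross_miss") <- sum(valid_trials(block) & !is.finite(e))
  block
}

#' Block mean error
#'
#' Mean of the cached per-trial errors over non-excluded, non-misfire,
#' finite-error trials.
#'
#' @param block A scored [trial_block()].
#' @return Scalar mean error (NA if no usable trial).
#' @export
block_mean_error <- function(block) {
  stopifnot(inherits(block, "trial_block"))
  use <- valid_trials(block) & is.finite(block$error) & !is.na(block$error)
  if (!any(use)) return(NA_real_)
  mean(block$error[use])
}
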