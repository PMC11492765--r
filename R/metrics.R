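#' Target-frame performance statistics
#'
#' For target tasks, hits are 2D coordinates in the target plane relative
#' to the bullseye (see [target_hits()]). Mean radial error (MRE) is the
#' mean distance from the bullseye to the hits and reflects accuracy;
#' bivariate variable error (BVE) is the root-mean-square distance of the
#' hits from their own centroid and reflects consistency; centroid bias is
#' the distance from the bullseye to the hit centroid and reflects
#' systematic offset. Note that for the mean-of-norms MRE the exact
#' decomposition `MRE^2 = bias^2 + BVE^2` does not hold; it holds for the
#' RMS radial error ([rmse_radial()]), and in general
#' `MRE <= bias + BVE`.
#'
#' @param hits n x 2 numeric matrix of hit offsets from the bullseye (m);
#'   rows with `NA` (gross misses) are dropped with a count check.
#' @return Scalar statistic in metres.
#' @name target_metrics
NULL

clean_hits <- function(hits, min_n) {
  hits <- as.matrix(hits)
  stopifnot(ncol(hits) == 2L)
  hits <- hits[stats::complete.cases(hits), , drop = FALSE]
  if (nrow(hits) < min_n)
    stop(sprintf("need at least %d finite hits", min_n), call. = FALSE)
  hits
}

#' @rdname target_metrics
#' @export
mre <- function(hits) {
  hits <- clean_hits(hits, 1L)
  mean(sqrt(rowSums(hits^2)))
}

#' @rdname target_metrics
#' @export
bve <- function(hits) {
  hits <- clean_hits(hits, 2L)
  ctr <- colMeans(hits)
  sqrt(mean(rowSums(sweep(hits, 2L, ctr)^2)))
}

#' @rdname target_metrics
#' @export
centroid_bias <- function(hits) {
  hits <- clean_hits(hits, 1L)
  sqrt(sum(colMeans(hits)^2))
}

#' @rdname target_metrics
#' @export
rmse_radial <- function(hits) {
  hits <- clean_hits(hits, 1L)
  sqrt(mean(rowSums(hits^2)))
}

#' Centroid bias in execution space
#'
#' The per-variable offset of the block's execution centroid from the
#' T-cost argmin centroid (the best-performing centroid location on the
#' search grid).
#'
#' @param block A [trial_block()] or execution matrix.
#' @param gf The task [goal_function()].
#' @param grid Search grid; default [default_search_grid()].
#' @param ... Passed to [t_cost()].
#' @return Named numeric vector of per-variable centroid offsets
#'   (observed minus optimal).
#' @export
centroid_bias_execution <- function(block, gf, grid = NULL, ...) {
  tc <- t_cost(block, gf, grid, ...)
  tb <- as_tnc_input(block, gf)
  colMeans(tb$U_use) - tc$argmin
}

#' Trial filters
#'
#' Two-stage error filter, applied in fixed order: stage 1 flags trials
#' with errors above `gross_mult` (15) times the target radius (applies to
#' the target tasks BA and RS, where arrows and balls falling short can
#' carry very high errors; gross-miss sentinel trials are always flagged);
#' stage 2 flags trials whose error lies more than `sd_mult` (3) standard
#' deviations from the mean error of the trials surviving stage 1. Flags
#' are recorded on the block, never dropped, and the stage-2 reference
#' statistics are always computed on the stage-1 survivors so the filter
#' is idempotent.
#'
#' @param block A scored [trial_block()] (see [score_block()]).
#' @param gf The task [goal_function()] (for the target radius; also used
#'   to score the block if errors are missing).
#' @param gross_mult Stage-1 multiple of the target radius.
#' @param sd_mult Stage-2 standard-deviation multiple.
#' @return The block with updated `excluded` flags and attribute
#'   `filter_counts` (`n_gross`, `n_outlier`).
#' @export
filter_trials <- function(block, gf, gross_mult = 15, sd_mult = 3) {
  stopifnot(inherits(block, "trial_block"), inherits(gf, "goal_function"))
  if (anyNA(block$error)) block <- score_block(gf, block)
  e <- block$error
  base <- !block$misfire
  stage1 <- rep(FALSE, length(e))
  if (gf$task_id %in% c("BA", "RS")) {
    stage1 <- base & (!is.finite(e) | e > gross_mult * gf$target_radius)
  } else {
    stage1 <- base & !is.finite(e)
  }
  ref <- base & !stage1
  mu <- mean(e[ref])
  sdv <- stats::sd(e[ref])
  stage2 <- rep(FALSE, length(e))
  if (is.finite(sdv) && sdv > 0)
    stage2 <- ref & abs(e - mu) > sd_mult * sdv
  block$excluded <- block$excluded | stage1 | stage2
  attr(block, "filter_counts") <- c(n_gross = sum(stage1),
                                    n_outlier = sum(stage2))
  block
}

#' Tracker trajectory series
#'
#' Uniformly sampled pre-execution tracker series ending at the strike.
#'
#' @param time Strictly increasing time stamps (s); by convention 0 is the
#'   strike and pre-strike samples are negative.
#' @param velocity n x 3 matrix of tracker velocities (`vx`, `vy`, `vz`,
#'   m/s).
#' @param position Optional n x 3 matrix of tracker positions (m);
#'   integrated from velocity when omitted.
#' @param strike_index Index of the execution sample (default: last).
#' @return An object of class `trajectory_series`.
#' @export
trajectory_series <- function(time, velocity, position = NULL,
                              strike_index = length(time)) {
  stopifnot(is.numeric(time), length(time) >= 2L, all(diff(time) > 0))
  velocity <- as.matrix(velocity)
  stopifnot(ncol(velocity) == 3L, nrow(velocity) == length(time),
            all(is.finite(velocity)))
  colnames(velocity) <- c("vx", "vy", "vz")
  if (is.null(position)) {
    dt <- diff(time)
    position <- apply(velocity, 2L, function(v) {
      cumsum(c(0, (v[-1L] + v[-length(v)]) / 2 * dt))
    })
  }
  position <- as.matrix(position)
  stopifnot(nrow(position) == length(time), ncol(position) == 3L)
  colnames(position) <- c("x", "y", "z")
  strike_index <- as.integer(strike_index)
  stopifnot(strike_index >= 1L, strike_index <= length(time))
  structure(list(time = time, velocity = velocity, position = position,
                 strike_index = strike_index),
            class = "trajectory_series")
}

#' On-target movement time before execution
#'
#' For strikes that hit the target, the uninterrupted period ending at the
#' strike, within the 1 s pre-strike window, during which the
#' instantaneous execution variables (tracker velocity, with the trial's
#' position-based variables held fixed) map to errors below the target
#' radius. Computed on the sampled grid without interpolation; a strike
#' whose only on-target sample is the strike itself scores one sample
#' period.
#'
#' @param traj A [trajectory_series()].
#' @param gf The task [goal_function()].
#' @param rt Target radius; defaults to the goal function's.
#' @param fixed Named values for position-kind execution variables (e.g.
#'   `c(d = 3.1)` for the punching bag); unused for RS.
#' @param window Pre-strike window length (s).
#' @return On-target time (s), or `NA` when the strike itself missed.
#' @export
on_target_time <- function(traj, gf, rt = gf$target_radius, fixed = NULL,
                           window = 1) {
  stopifnot(inherits(traj, "trajectory_series"),
            inherits(gf, "goal_function"))
  k <- traj$strike_index
  tt <- traj$time
  in_win <- tt >= tt[k] - window & seq_along(tt) <= k
  idx <- which(in_win)
  U <- execution_from_velocity(traj$velocity[idx, , drop = FALSE], gf, fixed)
  e <- gf$error_fn(U)
  on <- is.finite(e) & e < rt
  n_in <- length(idx)
  if (!on[n_in]) return(NA_real_)
  run <- rle(rev(on))
  len <- run$lengths[1L]  # consecutive on-target samples ending at strike
  first <- idx[n_in - len + 1L]
  dt <- stats::median(diff(tt))
  if (len == 1L) dt else tt[k] - tt[first]
}

execution_from_velocity <- function(V, gf, fixed) {
  switch(gf$task_id,
    RS = V,
    PB = {
      if (is.null(fixed) || is.null(fixed[["d"]]))
        stop("PB execution needs the fixed hit height d", call. = FALSE)
      cbind(V[, "vx"], V[, "vz"], fixed[["d"]])
    },
    stop("trajectory-based execution is defined for RS and PB",
         call. = FALSE))
}

#' Mean lateral velocity in the pre-execution movement window
#'
#' Over the uninterrupted pre-execution period ending at the strike during
#' which the tracker speed exceeds 20% of the strike speed, returns the
#' mean lateral (x-axis) velocity, both signed and as mean magnitude.
#'
#' @param traj A [trajectory_series()].
#' @param speed_frac Speed threshold as a fraction of strike speed.
#' @return A list with `mean_vx` (signed), `mean_abs_vx`, `window`
#'   (start/end times), and `n_samples`.
#' @export
mean_lateral_speed_premovement <- function(traj, speed_frac = 0.2) {
  stopifnot(inherits(traj, "trajectory_series"))
  k <- traj$strike_index
  V <- traj$velocity[seq_len(k), , drop = FALSE]
  speed <- sqrt(rowSums(V^2))
  strike_speed <- speed[k]
  if (strike_speed <= 0)
    stop("strike speed must be positive", call. = FALSE)
  fast <- speed > speed_frac * strike_speed
  run <- rle(rev(fast))
  len <- if (run$values[1L]) run$lengths[1L] else 1L  # strike sample at least
  idx <- (k - len + 1L):k
  list(mean_vx = mean(V[idx, "vx"]),
       mean_abs_vx = mean(abs(V[idx, "vx"])),
       window = c(start = traj$time[idx[1L]], end = traj$time[k]),
       n_samples = len)
}

#' Flat per-block metrics row
#'
#' Computes the block's outcome variables as a single flat data frame row
#' for export to external statistics environments: mean radial error,
#' centroid bias and BVE in the target frame (target tasks), the TNC
#' costs with per-variable N-costs, and per-variable execution means and
#' standard deviations.
#'
#' @param block A [trial_block()].
#' @param gf The task [goal_function()].
#' @param grid Search grid for the TNC step.
#' @param filter Apply [filter_trials()] first.
#' @param ... Passed to [tnc_cost()].
#' @return A one-row `data.frame`.
#' @export
block_metrics <- function(block, gf, grid = NULL, filter = TRUE, ...) {
  stopifnot(inherits(block, "trial_block"), inherits(gf, "goal_function"))
  block <- score_block(gf, block)
  if (filter) block <- filter_trials(block, gf)
  use <- valid_trials(block) & is.finite(block$error)
  res <- tnc_cost(block, gf, grid, ...)
  out <- data.frame(task_id = block$task_id, condition = block$condition,
                    block_index = block$block_index, n_trials = sum(use),
                    n_misfire = sum(block$misfire),
                    n_excluded = sum(block$excluded),
                    mean_error = mean(block$error[use]),
                    T = res$T, N = res$N, C = res$C,
                    stringsAsFactors = FALSE)
  for (nm in names(res$N_by_variable))
    out[[paste0("N_", nm)]] <- res$N_by_variable[[nm]]
  Uu <- block$U[use, , drop = FALSE]
  for (nm in colnames(Uu)) {
    out[[paste0("mu_", nm)]] <- mean(Uu[, nm])
    out[[paste0("sigma_", nm)]] <- stats::sd(Uu[, nm])
  }
  if (!is.null(gf$hit_fn)) {
    hits <- gf$hit_fn(Uu)
    out$MRE <- mre(hits)
    out$bias <- centroid_bias(hits)
    out$BVE <- if (sum(stats::complete.cases(hits)) >= 2L) bve(hits)
               else NA_real_
  }
  out
}
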