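#' Search grids in execution space
#'
#' A rectangular lattice defined per execution variable by a
#' `(start, step, stop)` triple. Steps may be written negative when the
#' axis runs from high to low (as the default punching-bag axes do); the
#' lattice is the same either way.
#'
#' @param axes Named list of numeric `c(start, step, stop)` triples, one
#'   per execution variable, in task variable order.
#' @return An object of class `search_grid` with the realized axis values.
#' @export
search_grid <- function(axes) {
  stopifnot(is.list(axes), length(axes) >= 1L, !is.null(names(axes)))
  values <- lapply(axes, function(a) {
    stopifnot(length(a) == 3L, all(is.finite(a)))
    if (a[2L] == 0) stop("grid step must be nonzero", call. = FALSE)
    if (sign(a[3L] - a[1L]) * sign(a[2L]) < 0)
      stop("grid step runs away from stop", call. = FALSE)
    sort(seq(a[1L], a[3L], by = a[2L]))
  })
  structure(list(axes = axes, values = values,
                 size = prod(vapply(values, length, 1L))),
            class = "search_grid")
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf("Search grid: %s axes, %s lattice points\n",
              length(x$values), format(x$size, big.mark = ",")))
  for (nm in names(x$values)) {
    v <- x$values[[nm]]
    cat(sprintf("  %s: %d points in [%g, %g]\n", nm, length(v), min(v),
                max(v)))
  }
  invisible(x)
}

#' Default per-task search grids
#'
#' The shipped `(start, step, stop)` limits per execution variable:
#' bow-and-arrow `chest_norm` in `[0, 0.0033, 1.2]`, `pull_norm` in
#' `[0, 0.01, 1.5]`; reach-and-strike `vx` in `[-2.0, 0.02, 2.0]`, `vy` in
#' `[-1.0, 0.1, 7.0]`, `vz` in `[-11.5, 0.0656, -1.0]` (m/s); punching bag
#' `vx` in `[0, -0.0296, -5.0]`, `vz` in `[0, -0.08, -8.0]` (m/s), `d` in
#' `[2.875, 0.0056, 3.458]` (m). When a PB environment with a re-placed bag
#' is supplied, the hit-height axis is translated to start at the actual
#' bag bottom, preserving step and span.
#'
#' @param task_id `"BA"`, `"RS"`, or `"PB"` (or a [goal_function()] /
#'   task environment, from which the task and geometry are taken).
#' @return A [search_grid()].
#' @export
default_search_grid <- function(task_id) {
  env <- NULL
  if (inherits(task_id, "goal_function")) {
    env <- task_id$env
    task_id <- task_id$task_id
  } else if (inherits(task_id, "task_environment")) {
    env <- task_id
    task_id <- env$task_id
  }
  task_id <- match.arg(task_id, c("BA", "RS", "PB"))
  axes <- switch(task_id,
    BA = list(chest_norm = c(0, 0.0033, 1.2), pull_norm = c(0, 0.01, 1.5)),
    RS = list(vx = c(-2.0, 0.02, 2.0), vy = c(-1.0, 0.1, 7.0),
              vz = c(-11.5, 0.0656, -1.0)),
    PB = list(vx = c(0, -0.0296, -5.0), vz = c(0, -0.08, -8.0),
              d = c(2.875, 0.0056, 3.458)))
  if (task_id == "PB" && !is.null(env) && env$bag_bottom != 2.875) {
    shift <- env$bag_bottom - 2.875
    axes$d <- axes$d + c(shift, 0, shift)
  }
  search_grid(axes)
}

# Mean error of the deviation set D recentred on each candidate centroid.
# centroids: q x m matrix. Chunked so no intermediate exceeds ~2e6 rows.
mean_error_at_centroids <- function(D, error_fn, centroids) {
  n <- nrow(D)
  q <- nrow(centroids)
  m <- ncol(D)
  out <- numeric(q)
  chunk <- max(1L, floor(2e6 / n))
  start <- 1L
  while (start <= q) {
    end <- min(q, start + chunk - 1L)
    idx <- start:end
    qq <- length(idx)
    big <- centroids[rep(idx, each = n), , drop = FALSE] +
      D[rep(seq_len(n), qq), , drop = FALSE]
    e <- error_fn(big)
    out[idx] <- colMeans(matrix(e, nrow = n))
    start <- end + 1L
  }
  out
}

grid_expand <- function(values) {
  as.matrix(expand.grid(values, KEEP.OUT.ATTRS = FALSE))
}

#' T-cost: performance cost of centroid location
#'
#' Creates candidate optimized sets by shifting the centroid of the
#' observed executions to every point of a search grid without changing
#' the distribution about the centroid, and returns the best. T-cost is
#' the observed mean error minus the optimized set's mean error.
#'
#' For large grids an exhaustive scan is expensive, so `mode = "coarse"`
#' (the default choice of `mode = "auto"` for grids above ~200k points)
#' scans a lattice coarsened by `coarsen` per axis and then scans the full
#' resolution exhaustively in the local window around the coarse argmin;
#' `mode = "exact"` always scans every lattice point.
#'
#' @param block A [trial_block()] (or plain execution matrix).
#' @param gf The task [goal_function()].
#' @param grid A [search_grid()]; default [default_search_grid()].
#' @param mode `"auto"`, `"exact"`, or `"coarse"`.
#' @param coarsen Coarsening factor per axis for the two-stage scan.
#' @return A list with `T` (cost), `U_star` (optimized set, same shape as
#'   the input with excluded rows untouched), `argmin` (best centroid),
#'   `mean_observed`, `mean_optimized`, and `mode`.
#' @export
t_cost <- function(block, gf, grid = NULL, mode = c("auto", "exact",
                                                    "coarse"), coarsen = 8L) {
  mode <- match.arg(mode)
  if (is.null(grid)) grid <- default_search_grid(gf)
  stopifnot(inherits(grid, "search_grid"), inherits(gf, "goal_function"))
  if (grid$size < 1L) stop("empty search grid", call. = FALSE)
  tb <- as_tnc_input(block, gf)
  U <- tb$U_use
  n <- nrow(U)
  if (n < 1L) stop("no usable trials", call. = FALSE)
  c0 <- colMeans(U)
  D <- sweep(U, 2L, c0)
  mean_obs <- mean(gf$error_fn(U))
  if (mode == "auto") mode <- if (grid$size > 2e5) "coarse" else "exact"
  vals <- grid$values
  if (mode == "exact") {
    cand <- grid_expand(vals)
    me <- mean_error_at_centroids(D, gf$error_fn, cand)
    best <- which.min(me)
    argmin <- cand[best, ]
    mean_opt <- me[best]
  } else {
    coarse_vals <- lapply(vals, function(v) {
      idx <- unique(c(seq(1L, length(v), by = coarsen), length(v)))
      v[idx]
    })
    cand <- grid_expand(coarse_vals)
    me <- mean_error_at_centroids(D, gf$error_fn, cand)
    cbest <- cand[which.min(me), ]
    # Full-resolution scan within +/- coarsen steps around the coarse argmin.
    fine_vals <- Map(function(v, ctr) {
      i <- which.min(abs(v - ctr))
      v[max(1L, i - coarsen):min(length(v), i + coarsen)]
    }, vals, as.list(cbest))
    cand2 <- grid_expand(fine_vals)
    me2 <- mean_error_at_centroids(D, gf$error_fn, cand2)
    best <- which.min(me2)
    argmin <- cand2[best, ]
    mean_opt <- me2[best]
  }
  names(argmin) <- gf$var_names
  U_star <- tb$U_full
  U_star[tb$use, ] <- sweep(D, 2L, argmin, `+`)
  list(T = mean_obs - mean_opt, U_star = U_star, argmin = argmin,
       mean_observed = mean_obs, mean_optimized = mean_opt, mode = mode)
}

# Normalize block/matrix input for the TNC algorithms: usable rows are
# non-excluded, non-misfire trials with finite error (gross misses are
# excluded and reported, since one infinite error poisons every mean).
as_tnc_input <- function(block, gf) {
  if (inherits(block, "trial_block")) {
    if (block$task_id != gf$task_id)
      stop("block and goal function tasks differ", call. = FALSE)
    U_full <- block$U
    use <- valid_trials(block)
  } else {
    U_full <- as_execution_matrix(block, gf$arity, gf$var_names)
    use <- rep(TRUE, nrow(U_full))
  }
  e <- gf$error_fn(U_full)
  use <- use & is.finite(e)
  list(U_full = U_full, use = use, U_use = U_full[use, , drop = FALSE],
       n_gross_miss = sum(!is.finite(e)))
}

#' N-cost: performance cost of trial-to-trial variability
#'
#' Candidate optimized sets shrink every observed execution toward the
#' block centroid in 1% increments (scaling factors 1.00, 0.99, ..., 0.00)
#' without moving the centroid; N-cost is the observed mean error minus
#' the best candidate's mean error. A scaling factor of 0 collapses the
#' set onto its centroid.
#'
#' @inheritParams t_cost
#' @param factors Shrink factors to enumerate (defaults to the 101-step 1%
#'   schedule; ties resolve to the largest factor).
#' @return A list with `N`, `U_star`, `shrink` (selected factor),
#'   `mean_observed`, `mean_optimized`, and `candidate_means`.
#' @export
n_cost <- function(block, gf, factors = seq(1, 0, by = -0.01)) {
  stopifnot(inherits(gf, "goal_function"))
  tb <- as_tnc_input(block, gf)
  U <- tb$U_use
  n <- nrow(U)
  if (n < 1L) stop("no usable trials", call. = FALSE)
  c0 <- colMeans(U)
  D <- sweep(U, 2L, c0)
  me <- vapply(factors, function(s) {
    mean(gf$error_fn(sweep(D * s, 2L, c0, `+`)))
  }, numeric(1))
  best <- which.min(me)
  s <- factors[best]
  U_star <- tb$U_full
  U_star[tb$use, ] <- sweep(D * s, 2L, c0, `+`)
  list(N = me[1L] - me[best], U_star = U_star, shrink = s,
       mean_observed = me[1L], mean_optimized = me[best],
       candidate_means = stats::setNames(me, factors))
}

#' Per-variable N-cost
#'
#' Same 1%-increment shrink enumeration as [n_cost()], but scaling the
#' deviations along only one execution-space axis, isolating the
#' performance cost of that variable's trial-to-trial variability.
#'
#' @inheritParams n_cost
#' @param j Execution-variable index (or name) to shrink.
#' @return As [n_cost()], with element `N_j`.
#' @export
n_cost_by_variable <- function(block, gf, j, factors = seq(1, 0, by = -0.01)) {
  stopifnot(inherits(gf, "goal_function"))
  if (is.character(j)) j <- match(j, gf$var_names)
  if (is.na(j) || j < 1L || j > gf$arity)
    stop("invalid execution-variable index", call. = FALSE)
  tb <- as_tnc_input(block, gf)
  U <- tb$U_use
  if (nrow(U) < 1L) stop("no usable trials", call. = FALSE)
  c0 <- colMeans(U)
  me <- vapply(factors, function(s) {
    Us <- U
    Us[, j] <- c0[j] + s * (U[, j] - c0[j])
    mean(gf$error_fn(Us))
  }, numeric(1))
  best <- which.min(me)
  s <- factors[best]
  U_star <- tb$U_full
  Us <- U
  Us[, j] <- c0[j] + s * (U[, j] - c0[j])
  U_star[tb$use, ] <- Us
  list(N_j = me[1L] - me[best], U_star = U_star, shrink = s,
       mean_observed = me[1L], mean_optimized = me[best])
}

#' C-cost: performance cost of poor covariation
#'
#' Greedy hill-climbing re-pairing of execution-variable values across
#' trials: in each batch, every pair of observations is examined in index
#' order and candidate swaps exchange their second-variable values and
#' (for three-variable tasks) their third-variable values; a swap is
#' accepted if and only if the set's mean error strictly decreases. The
#' algorithm terminates when a batch accepts no swap. Column marginals are
#' preserved exactly (the optimization only re-pairs values), so C-cost
#' isolates the benefit available from better covariation.
#'
#' @inheritParams t_cost
#' @param max_batches Safety cap on hill-climbing batches.
#' @param randomize Examine pairs in a seeded random order instead of index
#'   order (the default fixed order makes results deterministic).
#' @param seed Seed for `randomize = TRUE`.
#' @return A list with `C`, `U_star`, `swaps` (accepted swap count),
#'   `batches`, `mean_observed`, `mean_optimized`.
#' @export
c_cost <- function(block, gf, max_batches = 200L, randomize = FALSE,
                   seed = NULL) {
  stopifnot(inherits(gf, "goal_function"))
  tb <- as_tnc_input(block, gf)
  U <- tb$U_use
  n <- nrow(U)
  if (n < 1L) stop("no usable trials", call. = FALSE)
  e <- gf$error_fn(U)
  mean_obs <- mean(e)
  swaps <- 0L
  batches <- 0L
  if (n >= 2L) {
    m <- ncol(U)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    if (randomize) {
      if (!is.null(seed)) set.seed(seed)
      pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    }
    total <- sum(e)
    repeat {
      batches <- batches + 1L
      accepted <- FALSE
      for (v in 2:m) {
        for (p in seq_len(nrow(pairs))) {
          i <- pairs[p, 1L]; j <- pairs[p, 2L]
          if (U[i, v] == U[j, v]) next
          cand <- U[c(i, j), , drop = FALSE]
          cand[, v] <- cand[2:1, v]
          enew <- gf$error_fn(cand)
          delta <- sum(enew) - (e[i] + e[j])
          if (is.finite(delta) && delta < 0) {
            U[c(i, j), v] <- cand[, v]
            e[c(i, j)] <- enew
            total <- total + delta
            swaps <- swaps + 1L
            accepted <- TRUE
          }
        }
      }
      if (!accepted || batches >= max_batches) break
    }
  }
  U_star <- tb$U_full
  U_star[tb$use, ] <- U
  list(C = mean_obs - mean(e), U_star = U_star, swaps = swaps,
       batches = batches, mean_observed = mean_obs, mean_optimized = mean(e))
}

#' Full TNC-cost decomposition of a trial block
#'
#' Runs [t_cost()], [n_cost()], [n_cost_by_variable()] for every execution
#' variable, and [c_cost()] under one goal function. Each component is the
#' observed mean error minus the corresponding optimized set's mean error.
#' Gross-miss trials are excluded from the computation and counted in the
#' diagnostics.
#'
#' @inheritParams t_cost
#' @param ... Passed to [t_cost()] (e.g. `mode`).
#' @return An object of class `tnc_result`: costs `T`, `N`, `C`,
#'   `N_by_variable`, optimized sets `U_T`, `U_N`, `U_C`, and
#'   `diagnostics` (argmin centroid, shrink factor, swap count, gross-miss
#'   count, mean observed error).
#' @examples
#' env <- ba_environment(0.25, "near")
#' gf <- ba_goal_function(env)
#' U <- cbind(chest_norm = c(0.7, 0.6, 0.75), pull_norm = c(0.6, 0.7, 0.66))
#' res <- tnc_cost(trial_block(U, "BA", "near"), gf)
#' res$T; res$N; res$C
#' @export
tnc_cost <- function(block, gf, grid = NULL, ...) {
  tc <- t_cost(block, gf, grid, ...)
  nc <- n_cost(block, gf)
  cc <- c_cost(block, gf)
  nj <- vapply(seq_len(gf$arity), function(j) {
    n_cost_by_variable(block, gf, j)$N_j
  }, numeric(1))
  names(nj) <- gf$var_names
  tb <- as_tnc_input(block, gf)
  structure(
    list(T = tc$T, N = nc$N, C = cc$C, N_by_variable = nj,
         U_T = tc$U_star, U_N = nc$U_star, U_C = cc$U_star,
         diagnostics = list(argmin_centroid = tc$argmin,
                            shrink_factor = nc$shrink, swaps = cc$swaps,
                            t_mode = tc$mode,
                            n_gross_miss = tb$n_gross_miss,
                            mean_observed = tc$mean_observed)),
    class = "tnc_result")
}

#' @export
print.tnc_result <- function(x, ...) {
  cat("TNC-cost decomposition\n")
  cat(sprintf("  T-cost: %.5f\n  N-cost: %.5f\n  C-cost: %.5f\n",
              x$T, x$N, x$C))
  cat("  per-variable N-cost:\n")
  for (nm in names(x$N_by_variable))
    cat(sprintf("    %s: %.5f\n", nm, x$N_by_variable[[nm]]))
  cat(sprintf("  mean observed error: %.5f (gross misses excluded: %d)\n",
              x$diagnostics$mean_observed, x$diagnostics$n_gross_miss))
  invisible(x)
}
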