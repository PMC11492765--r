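#' Project an execution onto the solution manifold
#'
#' Returns the zero-error execution nearest to `u` in (optionally
#' weighted) Euclidean execution-space distance. Task goal functions built
#' by this package carry parameterized projections (the BA manifold is a
#' single point; the RS and PB manifolds are 1-D curves) which are used by
#' default; the generic method is a multi-start penalized local search
#' seeded from a coarse lattice over the task's search grid, available for
#' arbitrary goal functions and used as a cross-check.
#'
#' @param u Execution vector.
#' @param gf A [goal_function()].
#' @param weights Optional per-variable nonnegative weights for the
#'   distance metric (e.g. `1 / sd` per column to standardize mixed-unit
#'   tasks); `NULL` for plain Euclidean distance in execution-variable
#'   units.
#' @param method `"auto"` (task projection when available), `"task"`, or
#'   `"generic"`.
#' @param grid Lattice used to seed the generic search; default
#'   [default_search_grid()].
#' @param n_starts Number of seeds for the generic search.
#' @param tol Acceptance tolerance on the projected point's error;
#'   defaults to `1e-6 * target_radius`.
#' @return The projected execution vector `u*` with `e(u*) <= tol`.
#' @export
project_to_manifold <- function(u, gf, weights = NULL,
                                method = c("auto", "task", "generic"),
                                grid = NULL, n_starts = 6L, tol = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(gf, "goal_function"))
  u <- as.numeric(as_execution_matrix(u, gf$arity))
  if (is.null(tol)) tol <- 1e-6 * gf$target_radius
  if (!is.null(weights))
    stopifnot(length(weights) == gf$arity, all(weights >= 0))
  if (method != "generic" && !is.null(gf$project_fn)) {
    u_star <- gf$project_fn(u, weights)
    e <- as.numeric(gf$error_fn(matrix(u_star, nrow = 1L)))
    if (is.finite(e) && e <= tol) {
      names(u_star) <- gf$var_names
      return(u_star)
    }
    if (method == "task")
      stop("task projection did not reach the solution manifold",
           call. = FALSE)
  } else if (method == "task") {
    stop("goal function has no task-specific projection", call. = FALSE)
  }
  project_generic(u, gf, weights, grid, n_starts, tol)
}

project_generic <- function(u, gf, weights, grid, n_starts, tol) {
  if (is.null(grid)) grid <- default_search_grid(gf)
  w <- if (is.null(weights)) rep(1, gf$arity) else weights
  rt <- gf$target_radius
  # Coarse lattice: ~12 values per axis, scored once.
  seeds_vals <- lapply(grid$values, function(v) {
    v[unique(round(seq(1L, length(v), length.out = min(12L, length(v)))))]
  })
  lattice <- grid_expand(seeds_vals)
  e_lat <- gf$error_fn(lattice)
  finite <- is.finite(e_lat)
  if (!any(finite))
    stop("no finite-error lattice point to seed the projection", call. = FALSE)
  low <- lattice[finite & e_lat <= stats::quantile(e_lat[finite], 0.05), ,
                 drop = FALSE]
  d2 <- colSums((t(low) - u)^2 * w)
  seeds <- low[order(d2)[seq_len(min(n_starts, nrow(low)))], , drop = FALSE]
  penalized <- function(mu) {
    function(x) {
      e <- as.numeric(gf$error_fn(matrix(x, nrow = 1L)))
      pe <- if (is.finite(e)) e / rt else 1e3
      sum(w * (x - u)^2) + mu * pe^2
    }
  }
  best <- NULL
  best_d2 <- Inf
  for (s in seq_len(nrow(seeds))) {
    x <- seeds[s, ]
    for (mu in c(1e2, 1e4, 1e7)) {
      x <- stats::optim(x, penalized(mu), method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-12))$par
    }
    e <- as.numeric(gf$error_fn(matrix(x, nrow = 1L)))
    if (is.finite(e) && e <= tol) {
      d2x <- sum(w * (x - u)^2)
      if (d2x < best_d2) {
        best <- x
        best_d2 <- d2x
      }
    }
  }
  if (is.null(best))
    stop("projection failed: no zero-error execution found within the ",
         "search bounds", call. = FALSE)
  names(best) <- gf$var_names
  best
}

#' Step 1: velocity scaling constant
#'
#' Finds the smallest scalar `kv >= 1` such that the scaled centroid of
#' the block's velocity-based execution variables meets or exceeds the
#' operating-region bound on every bound axis, each comparison oriented
#' along that axis's reference sign (a forward strike is negative `vz`, so
#' its bound means "at least as negative as"). `kv >= 1` is a floor:
#' velocity scaling never slows the subject down.
#'
#' @param block A [trial_block()] or execution matrix.
#' @param gf The task [goal_function()] (identifies velocity columns).
#' @param v_min Named numeric vector of operating-region bounds over the
#'   *bound* velocity axes only (e.g. `c(vz = -11)` m/s).
#' @param signs Optional named orientation signs (+1 / -1) per bound axis;
#'   defaults to the sign of the bound (and +1 for a zero bound).
#' @return A list with `kv`, `ratios` (per bound axis), and `centroid`.
#' @export
compute_velocity_scale <- function(block, gf, v_min, signs = NULL) {
  stopifnot(inherits(gf, "goal_function"), is.numeric(v_min),
            !is.null(names(v_min)))
  U <- if (inherits(block, "trial_block")) {
    block$U[valid_trials(block), , drop = FALSE]
  } else as_execution_matrix(block, gf$arity, gf$var_names)
  vel_names <- gf$var_names[gf$var_kind == "velocity"]
  if (!all(names(v_min) %in% vel_names))
    stop("v_min names must be velocity-based execution variables",
         call. = FALSE)
  centroid <- colMeans(U)
  if (is.null(signs)) {
    signs <- ifelse(v_min < 0, -1, 1)
    names(signs) <- names(v_min)
  }
  ratios <- numeric(0)
  for (ax in names(v_min)) {
    s <- signs[[ax]]
    c_or <- s * centroid[[ax]]
    b_or <- s * v_min[[ax]]
    if (c_or <= 0) {
      if (b_or > 0)
        stop(sprintf(
          "infeasible: centroid of %s (%.4g) points away from its bound %.4g",
          ax, centroid[[ax]], v_min[[ax]]), call. = FALSE)
      ratios[ax] <- 1
    } else {
      ratios[ax] <- max(1, b_or / c_or)
    }
  }
  list(kv = max(1, ratios), ratios = ratios,
       centroid = centroid[names(v_min)])
}

# Scale the velocity-kind columns of an execution matrix / block by kv.
scale_velocities <- function(block, gf, kv) {
  vel <- gf$var_kind == "velocity"
  if (inherits(block, "trial_block")) {
    block$U[, vel] <- block$U[, vel, drop = FALSE] * kv
    block$error <- rep(NA_real_, n_trials(block))
    block
  } else {
    U <- as_execution_matrix(block, gf$arity, gf$var_names)
    U[, vel] <- U[, vel, drop = FALSE] * kv
    U
  }
}

#' Step 2: resize the target to observed trial-to-trial variability
#'
#' Removes the centroid bias from the (velocity-scaled) block by applying
#' the T-cost optimization, computes the N-cost of the T-adjusted set as
#' the measure of irreducible motor noise, and returns the smallest target
#' radius `rt`, never below the configured baseline radius, with
#' `N / rt < e_max`. The threshold `e_max` is dimensionless (error
#' normalized by target radius); the task error metrics here do not depend
#' on the radius, so the choice is the algebraic one `N / e_max` (nudged
#' up to satisfy the strict inequality).
#'
#' @inheritParams compute_velocity_scale
#' @param grid Search grid for the T-cost step.
#' @param e_max Desired threshold for TTV-related error, dimensionless.
#' @param ... Passed to [t_cost()].
#' @return A list with `rt`, `N` (N-cost of the T-adjusted set),
#'   `baseline_radius`, and `changed`.
#' @export
resize_target <- function(block, gf, e_max, grid = NULL, ...) {
  stopifnot(e_max > 0)
  tc <- t_cost(block, gf, grid, ...)
  nc <- n_cost(tc$U_star, gf)
  rt0 <- gf$target_radius
  needed <- nc$N / e_max
  rt <- if (nc$N / rt0 < e_max) rt0 else max(rt0, needed * (1 + 1e-9))
  list(rt = rt, N = nc$N, baseline_radius = rt0, changed = rt > rt0)
}

#' Eq.-style visual error modification of executions
#'
#' Decomposes each execution into its nearest solution-manifold point `u*`
#' and fluctuation `d = u - u*`, scales the fluctuation componentwise by
#' `c`, and re-adds it: `u_r = u* + c * d`. With `c = 1` this is the
#' identity; with `c = 0` the displayed execution lies on the manifold
#' (zero error). Components of `c` below 1 shrink the corresponding
#' fluctuation component, above 1 amplify it.
#'
#' @param U Execution vector, matrix, or [trial_block()].
#' @param gf A [goal_function()].
#' @param c_vec Nonnegative modification vector of length arity (scalars
#'   are recycled).
#' @param u_star Optional precomputed matrix of projected points (same
#'   shape as the executions) to avoid re-projection.
#' @param weights Passed to [project_to_manifold()].
#' @return Modified executions, same shape as the input.
#' @export
apply_visual_error_modification <- function(U, gf, c_vec, u_star = NULL,
                                            weights = NULL) {
  stopifnot(inherits(gf, "goal_function"))
  c_vec <- rep_len(c_vec, gf$arity)
  if (any(c_vec < 0)) stop("c components must be >= 0", call. = FALSE)
  is_block <- inherits(U, "trial_block")
  M <- if (is_block) U$U else as_execution_matrix(U, gf$arity, gf$var_names)
  if (is.null(u_star)) u_star <- project_block(M, gf, weights)
  D <- M - u_star
  out <- u_star + sweep(D, 2L, c_vec, `*`)
  finish_modified(U, out, is_block)
}

#' Speed-preserving visual error modification
#'
#' As [apply_visual_error_modification()], but with a magnitude
#' constraint: the modified components are rescaled back to the observed
#' magnitude, `u_s = ||u|| * (u* + c * d) / ||u* + c * d||`, the
#' rescaling being applied over the components actually modified
#' (`c != 1`). Components left unmodified (`c = 1`) pass through
#' unchanged, so the full execution norm `||u_s|| = ||u||` holds exactly
#' in every case. For the punching bag with `c = (c1, c1, 1)` the
#' ground-plane strike speed and the hit height are both preserved, hence
#' the bag's angular speed and peak swing amplitude are exactly
#' unchanged while the swing-direction error shrinks: a hit of a given
#' speed always swings the bag to the same height.
#'
#' @inheritParams apply_visual_error_modification
#' @return Modified executions with per-row magnitudes equal to the
#'   observed rows' magnitudes.
#' @export
apply_speed_preserving_modification <- function(U, gf, c_vec, u_star = NULL,
                                                weights = NULL) {
  stopifnot(inherits(gf, "goal_function"))
  c_vec <- rep_len(c_vec, gf$arity)
  if (any(c_vec < 0)) stop("c components must be >= 0", call. = FALSE)
  is_block <- inherits(U, "trial_block")
  M <- if (is_block) U$U else as_execution_matrix(U, gf$arity, gf$var_names)
  g <- which(c_vec != 1)
  if (!length(g)) return(finish_modified(U, M, is_block))
  if (is.null(u_star)) u_star <- project_block(M, gf, weights)
  mid <- u_star + sweep(M - u_star, 2L, c_vec, `*`)
  norm_obs <- sqrt(rowSums(M[, g, drop = FALSE]^2))
  norm_mid <- sqrt(rowSums(mid[, g, drop = FALSE]^2))
  if (any(norm_mid == 0))
    stop("zero-norm intermediate execution; cannot preserve speed",
         call. = FALSE)
  out <- mid
  out[, g] <- mid[, g, drop = FALSE] * (norm_obs / norm_mid)
  finish_modified(U, out, is_block)
}

project_block <- function(M, gf, weights = NULL) {
  t(apply(M, 1L, function(u) project_to_manifold(u, gf, weights)))
}

finish_modified <- function(U, out, is_block) {
  if (is_block) {
    U$U <- out
    U$error <- rep(NA_real_, nrow(out))
    U
  } else if (nrow(out) == 1L && is.null(dim(U))) {
    stats::setNames(as.numeric(out), colnames(out))
  } else out
}

#' Step 3: select the visual error modification vector
#'
#' Grid search over modification magnitudes `c` in `[0, 1]` (step 0.05,
#' largest first) for the largest `c` whose modified block satisfies
#' `mean error / rt <= e_max`. Policies: `"uniform"` scales every
#' fluctuation component by `c`; `"single-axis"` scales only the given
#' axis (component `c`, others 1), which can be infeasible when the error
#' floor set by the unaffected axes exceeds the threshold;
#' `"speed-preserving"` uses the norm-preserving modification with
#' `c = (c, c, 1)` (punching bag swing-direction reduction).
#'
#' @inheritParams resize_target
#' @param rt Target radius used to normalize the mean modified error.
#' @param policy Axis policy, see Details.
#' @param axis Execution-variable index or name for `"single-axis"`.
#' @param c_grid Candidate magnitudes, scanned in the given order
#'   (largest-first by default).
#' @param weights Passed to the per-trial projection.
#' @return A list with `feasible`, `c` (full modification vector, or `NA`
#'   if infeasible), `c_value` (selected magnitude), `mean_error`,
#'   `normalized_error`, and `policy`.
#' @export
select_modification_vector <- function(block, gf, rt, e_max,
                                       policy = c("uniform", "single-axis",
                                                  "speed-preserving"),
                                       axis = NULL,
                                       c_grid = seq(1, 0, by = -0.05),
                                       weights = NULL) {
  policy <- match.arg(policy)
  stopifnot(rt > 0, e_max > 0)
  is_block <- inherits(block, "trial_block")
  M <- if (is_block) block$U[valid_trials(block), , drop = FALSE]
       else as_execution_matrix(block, gf$arity, gf$var_names)
  if (policy == "single-axis") {
    if (is.character(axis)) axis <- match(axis, gf$var_names)
    if (is.null(axis) || is.na(axis) || axis < 1L || axis > gf$arity)
      stop("single-axis policy needs a valid axis", call. = FALSE)
  }
  u_star <- project_block(M, gf, weights)
  apply_fn <- if (policy == "speed-preserving")
    apply_speed_preserving_modification else apply_visual_error_modification
  for (cv in c_grid) {
    c_vec <- switch(policy,
      uniform = rep(cv, gf$arity),
      `single-axis` = {
        v <- rep(1, gf$arity)
        v[axis] <- cv
        v
      },
      `speed-preserving` = {
        v <- rep(cv, gf$arity)
        v[gf$arity] <- 1
        v
      })
    Ur <- apply_fn(M, gf, c_vec, u_star = u_star)
    e <- gf$error_fn(Ur)
    me <- mean(e[is.finite(e)])
    if (is.finite(me) && me / rt <= e_max) {
      return(list(feasible = TRUE, c = c_vec, c_value = cv, mean_error = me,
                  normalized_error = me / rt, policy = policy))
    }
  }
  list(feasible = FALSE, c = rep(NA_real_, gf$arity), c_value = NA_real_,
       mean_error = NA_real_, normalized_error = NA_real_, policy = policy)
}

#' Three-step task adjustment
#'
#' Computes the subject-specific adjustment parameters from one prior
#' block: Step 1 the velocity scaling constant `kv`; Step 2 the target
#' radius `rt` sized to the scaled block's TTV; Step 3 the visual error
#' modification vector `c` satisfying the normalized mean-error
#' constraint. Steps 2 and 3 operate on the velocity-scaled executions,
#' and Step 3 uses the Step-2 radius, mirroring sequential application.
#'
#' @inheritParams select_modification_vector
#' @param v_min Named bound vector for Step 1 (`NULL` skips scaling,
#'   `kv = 1`).
#' @param grid Search grid for the Step-2 T-cost.
#' @param ... Passed to [t_cost()] via [resize_target()].
#' @return An object of class `adjustment_params`: `kv`, `rt`, `c`,
#'   `feasible`, `policy`, `e_max`, `v_min`, and step diagnostics.
#' @export
adjust_task <- function(block, gf, e_max, v_min = NULL,
                        policy = c("uniform", "single-axis",
                                   "speed-preserving"),
                        axis = NULL, grid = NULL, weights = NULL, ...) {
  policy <- match.arg(policy)
  step1 <- if (is.null(v_min)) {
    list(kv = 1, ratios = numeric(0), centroid = NULL)
  } else compute_velocity_scale(block, gf, v_min)
  scaled <- scale_velocities(block, gf, step1$kv)
  step2 <- resize_target(scaled, gf, e_max, grid = grid, ...)
  step3 <- select_modification_vector(scaled, gf, step2$rt, e_max,
                                      policy = policy, axis = axis,
                                      weights = weights)
  structure(
    list(kv = step1$kv, rt = step2$rt, c = step3$c,
         feasible = step3$feasible, policy = policy, axis = axis,
         e_max = e_max, v_min = v_min,
         diagnostics = list(step1 = step1, step2 = step2, step3 = step3)),
    class = "adjustment_params")
}

#' @export
print.adjustment_params <- function(x, ...) {
  cat("Task adjustment parameters\n")
  cat(sprintf("  kv: %.4f\n  rt: %.4f\n", x$kv, x$rt))
  if (x$feasible) {
    cat(sprintf("  c: (%s), policy %s\n",
                paste(sprintf("%.2f", x$c), collapse = ", "), x$policy))
  } else {
    cat(sprintf("  c: infeasible under policy %s\n", x$policy))
  }
  invisible(x)
}

#' Apply stored adjustment parameters to a block
#'
#' Deterministically re-applies a computed [adjust_task()] result to a
#' trial block: velocity columns are scaled by `kv` and, when Step 3 was
#' feasible, the visual error modification is applied per trial.
#'
#' @param block A [trial_block()].
#' @param gf The task [goal_function()].
#' @param params An `adjustment_params` object.
#' @param weights Passed to the per-trial projection.
#' @return The transformed block; attribute `target_radius` carries the
#'   adjusted radius.
#' @export
apply_adjustment <- function(block, gf, params, weights = NULL) {
  stopifnot(inherits(params, "adjustment_params"),
            inherits(block, "trial_block"))
  out <- scale_velocities(block, gf, params$kv)
  if (params$feasible) {
    apply_fn <- if (params$policy == "speed-preserving")
      apply_speed_preserving_modification else apply_visual_error_modification
    out <- apply_fn(out, gf, params$c, weights = weights)
  }
  attr(out, "target_radius") <- params$rt
  out
}
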