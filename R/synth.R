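#' Synthetic execution-data specification
#'
#' Seeded generator settings for execution-space trial blocks: a
#' multivariate normal trial-to-trial noise model around a strategy
#' centroid, truncated to the task's physical domain, with optional
#' misfires, practice drift across blocks, and simple pre-strike
#' trajectories. The noise model emulates unstructured trial-to-trial
#' variability about a motor strategy point; it does not model serial
#' correlation, fatigue, or biomechanical coupling.
#'
#' @param task_id `"BA"`, `"RS"`, or `"PB"`.
#' @param n Trials per block.
#' @param centroid Execution-space centroid (length = task arity).
#' @param covariance m x m symmetric positive-semidefinite trial
#'   covariance, or a vector of per-variable standard deviations.
#' @param misfire_prob Per-trial misfire probability (BA).
#' @param drift_target Centroid the practice drift decays toward (e.g. an
#'   optimal execution); defaults to the centroid (no drift).
#' @param drift_rate Per-block geometric decay factor in `[0, 1]` of the
#'   centroid's offset from `drift_target` (1 = no drift).
#' @param noise_decay Per-block geometric decay factor of the noise SD
#'   (1 = no decay).
#' @param domain Optional list of `c(lower, upper)` truncation bounds per
#'   variable; PB hit heights default to the reference bag extent.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(task_id, n, centroid, covariance,
                       misfire_prob = 0, drift_target = NULL,
                       drift_rate = 1, noise_decay = 1, domain = NULL,
                       seed = 1L) {
  task_id <- match.arg(task_id, c("BA", "RS", "PB"))
  schema <- task_variables(task_id)
  m <- schema$arity
  stopifnot(length(centroid) == m, all(is.finite(centroid)),
            n >= 1L, misfire_prob >= 0, misfire_prob <= 1,
            drift_rate >= 0, drift_rate <= 1, noise_decay >= 0,
            noise_decay <= 1)
  if (is.null(dim(covariance))) {
    stopifnot(length(covariance) == m, all(covariance >= 0))
    covariance <- diag(covariance^2, m)
  }
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == m, ncol(covariance) == m)
  if (max(abs(covariance - t(covariance))) > 1e-10)
    stop("covariance must be symmetric", call. = FALSE)
  if (min(eigen(covariance, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-10)
    stop("covariance must be positive semidefinite", call. = FALSE)
  if (is.null(drift_target)) drift_target <- centroid
  stopifnot(length(drift_target) == m)
  if (is.null(domain) && task_id == "PB")
    domain <- list(vx = c(-Inf, Inf), vz = c(-Inf, Inf),
                   d = c(2.875, 3.75))
  structure(
    list(task_id = task_id, n = as.integer(n),
         centroid = stats::setNames(as.numeric(centroid), schema$names),
         covariance = covariance, misfire_prob = misfire_prob,
         drift_target = as.numeric(drift_target), drift_rate = drift_rate,
         noise_decay = noise_decay, domain = domain,
         seed = as.integer(seed)),
    class = "synth_spec")
}

#' Per-task generator presets
#'
#' Default centroids and noise levels per task, chosen to sit inside the
#' default TNC search grids with moderate bias and spread comparable to a
#' first practice block.
#'
#' @param task_id `"BA"`, `"RS"`, or `"PB"`.
#' @param n Trials per block.
#' @param seed Seed.
#' @return A [synth_spec()].
#' @export
synth_preset <- function(task_id, n = 25L, seed = 1L) {
  task_id <- match.arg(task_id, c("BA", "RS", "PB"))
  switch(task_id,
    BA = synth_spec("BA", n, centroid = c(0.75, 0.60),
                    covariance = c(0.08, 0.07), misfire_prob = 0.04,
                    seed = seed),
    RS = synth_spec("RS", n, centroid = c(-0.4, 4.3, -5.2),
                    covariance = c(0.45, 0.55, 0.8), seed = seed),
    PB = synth_spec("PB", n, centroid = c(-1.35, -2.75, 3.15),
                    covariance = c(0.30, 0.35, 0.10), seed = seed))
}

# Rejection-sampled truncated multivariate normal rows.
rmvnorm_trunc <- function(n, centroid, sigma, domain) {
  draw <- function(k) MASS::mvrnorm(k, mu = centroid, Sigma = sigma)
  U <- matrix(draw(n), nrow = n)
  if (!is.null(domain)) {
    lo <- vapply(domain, `[`, numeric(1), 1L)
    hi <- vapply(domain, `[`, numeric(1), 2L)
    for (iter in seq_len(1000L)) {
      bad <- which(apply(U, 1L, function(r) any(r < lo | r > hi)))
      if (!length(bad)) break
      U[bad, ] <- matrix(draw(length(bad)), nrow = length(bad))
      if (iter == 1000L)
        stop("truncation region appears infeasible for the given centroid",
             call. = FALSE)
    }
  }
  U
}

#' Generate a synthetic trial block
#'
#' Draws `n` executions from the spec's truncated multivariate normal,
#' flags misfires by the spec's probability, and wraps the result as a
#' [trial_block()]. RNG: Mersenne-Twister, seeded per call from the spec
#' seed (plus the block index), so output is fully reproducible.
#'
#' @param spec A [synth_spec()].
#' @param condition Lean/reach condition label.
#' @param block_index Block number (also offsets the seed so successive
#'   blocks of a series are independent).
#' @return A [trial_block()].
#' @export
generate_block <- function(spec, condition = "mid", block_index = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 7919L * (as.integer(block_index) - 1L),
           kind = "Mersenne-Twister")
  U <- rmvnorm_trunc(spec$n, spec$centroid, spec$covariance, spec$domain)
  misfire <- stats::runif(spec$n) < spec$misfire_prob
  trial_block(U, spec$task_id, condition, block_index, misfire = misfire)
}

#' Generate a practice series of blocks
#'
#' Applies the spec's practice structure across blocks: the centroid's
#' offset from `drift_target` decays geometrically by `drift_rate` per
#' block (bias reduction with practice) and the noise SD decays by
#' `noise_decay` per block (TTV reduction). With both factors at 1 the
#' blocks are exchangeable.
#'
#' @param spec A [synth_spec()].
#' @param n_blocks Number of successive blocks.
#' @param condition Condition label for all blocks.
#' @return A list of [trial_block()]s.
#' @export
generate_learning_series <- function(spec, n_blocks, condition = "mid") {
  stopifnot(inherits(spec, "synth_spec"), n_blocks >= 1L)
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    sp <- spec
    lam <- spec$drift_rate^(b - 1L)
    rho <- spec$noise_decay^(b - 1L)
    sp$centroid <- spec$drift_target + lam * (spec$centroid -
                                                spec$drift_target)
    sp$covariance <- spec$covariance * rho^2
    out[[b]] <- generate_block(sp, condition, block_index = b)
  }
  out
}

#' Generate a pre-strike tracker trajectory
#'
#' Builds a synthetic hand trajectory ending exactly at the trial's strike
#' velocity: a sub-threshold bell-shaped wind-up (peak speed 15% of strike
#' speed, below the 20% movement-window threshold) followed by a strike
#' plateau at the strike velocity plus a lateral drift component that
#' decays linearly to zero at the strike. Because the wind-up stays below
#' the threshold, the uninterrupted >20%-speed window is exactly the
#' plateau, giving closed-form ground truth for the movement-window
#' metrics; the terminal sample equals the strike velocity exactly.
#'
#' @param u Strike execution velocity: `c(vx, vy, vz)` (RS) or the PB
#'   ground-plane pair `c(vx, vz)` (vertical component 0).
#' @param rate Sampling rate (Hz).
#' @param duration Total pre-strike duration (s), at least `plateau`.
#' @param plateau Strike-plateau duration (s); the wind-up fills the rest.
#' @param lateral_drift Initial lateral (x) drift velocity added at
#'   plateau start (m/s), decaying linearly to 0 at the strike.
#' @return A [trajectory_series()] ending at the strike (time 0).
#' @export
generate_trajectory <- function(u, rate = 100, duration = 1.6,
                                plateau = 1.1, lateral_drift = 0) {
  stopifnot(duration > plateau, plateau > 0, rate > 0)
  if (length(u) == 2L) u <- c(u[1L], 0, u[2L])
  stopifnot(length(u) == 3L, all(is.finite(u)))
  speed <- sqrt(sum(u^2))
  if (speed <= 0) stop("strike speed must be positive", call. = FALSE)
  tt <- seq(-duration, 0, by = 1 / rate)
  V <- matrix(0, length(tt), 3L)
  windup <- tt < -plateau
  tw <- tt[windup]
  # Bell in speed along the strike direction, peaking at 15% strike speed.
  bump <- sin(pi * (tw + duration) / (duration - plateau))^2
  V[windup, ] <- outer(0.15 * speed * bump, u / speed)
  plat <- !windup
  V[plat, ] <- matrix(u, sum(plat), 3L, byrow = TRUE)
  V[plat, 1L] <- V[plat, 1L] + lateral_drift * (-tt[plat]) / plateau
  trajectory_series(tt, V)
}
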