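#' Trial-log CSV files
#'
#' Trial logs are plain CSV with one row per trial: columns `task_id`,
#' `condition`, `block_index`, the task's execution-variable columns,
#' `misfire`, `excluded`, and `error`. Numeric cells are serialized with
#' full (17 significant digit) precision so a write/read round trip
#' reproduces values bit-exactly. Files may mix tasks and blocks; rows
#' are grouped into separate trial blocks keyed by
#' `(task_id, condition, block_index)`.
#'
#' @param blocks A [trial_block()] or list of them.
#' @param path Output CSV path.
#' @return `write_trial_log()` returns `path` invisibly;
#'   `read_trial_log()` returns a named list of [trial_block()]s (a
#'   single unnamed block if the file holds exactly one).
#' @name trial_log
NULL

ALL_EXEC_COLS <- c("chest_norm", "pull_norm", "vx", "vy", "vz", "d")

#' @rdname trial_log
#' @export
write_trial_log <- function(blocks, path) {
  if (inherits(blocks, "trial_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, TRUE, "trial_block")))
  dfs <- lapply(blocks, as.data.frame)
  cols <- unique(unlist(lapply(dfs, names)))
  exec_cols <- intersect(ALL_EXEC_COLS, cols)
  cols <- c("task_id", "condition", "block_index", exec_cols,
            "misfire", "excluded", "error")
  dfs <- lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA_real_
    d[cols]
  })
  df <- do.call(rbind, dfs)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "block_index"
  for (nm in names(df)[num]) {
    df[[nm]] <- ifelse(is.na(df[[nm]]), "",
                       ifelse(is.infinite(df[[nm]]),
                              ifelse(df[[nm]] > 0, "Inf", "-Inf"),
                              sprintf("%.17g", df[[nm]])))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("task_id", "condition", "block_index", "misfire", "excluded")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("trial log is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"error" %in% names(df)) df$error <- NA_real_
  key <- interaction(df$task_id, df$condition, df$block_index, drop = TRUE)
  blocks <- lapply(split(df, key), function(g) {
    task <- g$task_id[1L]
    if (!task %in% c("BA", "RS", "PB"))
      stop("unknown task_id: ", task, call. = FALSE)
    schema <- task_variables(task)
    miss <- setdiff(schema$names, names(g))
    if (length(miss))
      stop(sprintf("task %s rows are missing column(s): %s", task,
                   paste(miss, collapse = ", ")), call. = FALSE)
    U <- as.matrix(g[schema$names])
    rownames(U) <- NULL
    bad <- which(!is.finite(U), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric or missing execution value at row %d, column %s",
                   bad[1L, 1L], schema$names[bad[1L, 2L]]), call. = FALSE)
    err <- suppressWarnings(as.numeric(g$error))
    trial_block(U, task, g$condition[1L], g$block_index[1L],
                misfire = g$misfire, excluded = g$excluded, error = err)
  })
  if (length(blocks) == 1L) blocks[[1L]] else blocks
}

# Allowed YAML keys per task (constructor formals minus internals).
config_keys <- function(task) {
  switch(task,
    BA = setdiff(names(formals(ba_environment)), ""),
    RS = setdiff(names(formals(rs_environment)), ""),
    PB = setdiff(names(formals(pb_environment)), ""))
}

#' Read a task configuration file
#'
#' YAML with an explicit schema: a `task` key (`BA`, `RS`, `PB`) plus the
#' keyword arguments of the corresponding environment constructor
#' ([ba_environment()], [rs_environment()], [pb_environment()]); angles
#' are given in degrees. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A task environment.
#' @export
read_task_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$task))
    stop("config must name a task (BA, RS, PB)", call. = FALSE)
  task <- match.arg(cfg$task, c("BA", "RS", "PB"))
  args <- cfg[setdiff(names(cfg), "task")]
  unknown <- setdiff(names(args), config_keys(task))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- lapply(args, function(x) if (is.list(x)) unlist(x) else x)
  ctor <- switch(task, BA = ba_environment, RS = rs_environment,
                 PB = pb_environment)
  do.call(ctor, args)
}

#' Serialize a task environment to JSON
#'
#' @param env A task environment.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_environment_json <- function(env, path) {
  stopifnot(inherits(env, "task_environment"))
  x <- unclass(env)
  x <- x[!vapply(x, is.null, TRUE)]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: package
#' version, the subcommand and arguments, the seed, and an MD5 hash of
#' every input file.
#'
#' @param path Manifest path (JSON).
#' @param command Subcommand name.
#' @param args Character vector of raw arguments.
#' @param inputs Character vector of input file paths to hash.
#' @param seed Seed used (or `NA`).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, args, inputs = character(),
                               seed = NA) {
  inputs <- as.character(inputs)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "goalfun",
    version = as.character(utils::packageVersion("goalfun")),
    command = command,
    args = as.list(args),
    seed = seed,
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                     inputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
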