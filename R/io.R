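# File formats: trajectory CSV with a commented metadata block, step-table
# CSV, fit-result JSON, and run manifests. All text, all round-trippable.

.traj_meta_fields <- c("model", "n", "steps", "epsilon", "r", "v",
                       "boundary", "L", "m", "init", "central_side",
                       "seed", "likelihood_floor", "prior_leak",
                       "response_floor")

#' Write / read a trajectory CSV
#'
#' The file starts with a commented metadata block (`# key: value`, one per
#' configuration field) followed by a `t,agent,x,y,d,h` table. Coordinates
#' are serialized with 17 significant digits, so write-then-read reproduces
#' the trajectory exactly.
#'
#' @param traj a `swarm_trajectory`.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the reconstructed `swarm_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  cfg <- traj$config
  meta <- vapply(.traj_meta_fields, function(f)
    sprintf("# %s: %s", f, format(cfg[[f]], digits = 17)), character(1))
  df <- as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("t,agent,x,y,d,h", con)
  writeLines(sprintf("%d,%d,%.17g,%.17g,%d,%d",
                     df$t, df$agent, df$x, df$y, df$d, df$h), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  if (length(meta_lines) == 0)
    stop("not a trajectory file: missing '# key: value' metadata block")
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([a-zA-Z_]+):\\s*(.*)$", meta_lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  missing <- setdiff(.traj_meta_fields, keys)
  if (length(missing))
    stop("metadata block lacks field(s): ", paste(missing, collapse = ", "))
  meta <- setNames(as.list(vals), keys)
  cfg <- swarm_config(
    model = meta$model, n = as.integer(meta$n),
    steps = as.integer(meta$steps), epsilon = as.numeric(meta$epsilon),
    r = as.numeric(meta$r), v = as.numeric(meta$v),
    boundary = meta$boundary, L = as.numeric(meta$L),
    m = as.integer(meta$m),
    init = if (meta$init == "central") "central" else "uniform",
    central_side = as.numeric(meta$central_side),
    seed = as.integer(meta$seed),
    likelihood_floor = as.numeric(meta$likelihood_floor),
    prior_leak = as.numeric(meta$prior_leak),
    response_floor = as.numeric(meta$response_floor))
  body <- lines[!is_meta]
  if (length(body) < 2) stop("trajectory file has no data rows")
  if (body[1] != "t,agent,x,y,d,h")
    stop("unexpected header line: ", body[1])
  df <- tryCatch(
    read.csv(text = body, header = TRUE),
    warning = function(w) stop("malformed trajectory CSV: ",
                               conditionMessage(w)))
  if (!all(c("t", "agent", "x", "y", "d", "h") %in% names(df)))
    stop("trajectory CSV lacks required columns")
  bad <- which(!stats::complete.cases(df[c("t", "agent", "x", "y")]))
  if (length(bad))
    stop("malformed trajectory CSV at data line ", bad[1])
  T_total <- max(df$t)
  n <- max(df$agent)
  if (nrow(df) != T_total * n)
    stop("trajectory CSV is not a full t x agent grid (",
         nrow(df), " rows for ", T_total, " x ", n, ")")
  o <- order(df$agent, df$t)
  df <- df[o, ]
  structure(list(
    x = matrix(df$x, T_total, n), y = matrix(df$y, T_total, n),
    d = matrix(as.integer(df$d), T_total, n),
    h = matrix(as.integer(df$h), T_total, n),
    config = cfg), class = "swarm_trajectory")
}

#' Write / read a step-length table CSV
#'
#' Plain CSV with columns `agent,start_t,end_t,length`.
#'
#' @param steps a `step_table` from [pool_steps()].
#' @param path file path.
#' @export
write_steps <- function(steps, path) {
  write.csv(as.data.frame(steps)[c("agent", "start_t", "end_t", "length")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_steps
#' @export
read_steps <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("agent", "start_t", "end_t", "length") %in% names(df)))
  class(df) <- c("step_table", "data.frame")
  df
}

#' Write a fit result as JSON
#'
#' All scalar fields of a [levy_fit()] object (the tail sample is omitted).
#'
#' @param fit a `levy_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "levy_fit"))
  out <- unclass(fit)
  out$tail <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# run manifest: enough to re-run the command that produced an output file
write_manifest <- function(path, command, params, outputs, elapsed = NA) {
  jsonlite::write_json(list(
    package = "bibswarm",
    version = as.character(utils::packageVersion("bibswarm")),
    command = command, params = params, outputs = outputs,
    elapsed_sec = elapsed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
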