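traj_columns <- c("time_s", "particle_id", "x_um", "y_um", "ux", "uy")

#' Write a trajectory as tab-separated text
#'
#' Deterministic column order (`time_s`, `particle_id`, `x_um`, `y_um`,
#' `ux`, `uy`) and locale-independent float formatting with 17 significant
#' digits, so identical trajectories produce byte-identical files.
#'
#' @param traj A `swim_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  d <- as.data.frame(traj)
  fmt <- function(v) sprintf("%.17g", v)
  lines <- c(paste(traj_columns, collapse = "\t"),
             paste(fmt(d$time_s), d$particle_id, fmt(d$x_um), fmt(d$y_um),
                   fmt(d$ux), fmt(d$uy), sep = "\t"))
  con <- file(path, open = "wb")  # binary mode: fixed LF line endings
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a trajectory from tab-separated text
#'
#' Validates the schema: required columns, finite values, unit-norm
#' headings, and strictly increasing time within each particle.  Errors
#' name the first offending row.
#'
#' @param path File written by [write_trajectory()] (or matching the same
#'   schema).
#' @param params Optional [swimmer_params()] to attach (the TSV carries no
#'   parameters).
#' @return A `swim_trajectory`.
#' @export
read_trajectory <- function(path, params = NULL) {
  d <- tryCatch(read.delim(path, sep = "\t", check.names = FALSE),
                error = function(e) stop("schema error: ", conditionMessage(e)))
  if (nrow(d) == 0) stop("schema error: empty trajectory file")
  missing_cols <- setdiff(traj_columns, names(d))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  for (cl in traj_columns) {
    bad <- which(!is.finite(d[[cl]]))
    if (length(bad) > 0)
      stop(sprintf("schema error: non-finite %s at row %d", cl, bad[1]))
  }
  un <- sqrt(d$ux^2 + d$uy^2)
  bad <- which(abs(un - 1) > 1e-6)
  if (length(bad) > 0)
    stop(sprintf("schema error: heading norm %.4g != 1 at row %d",
                 un[bad[1]], bad[1]))
  ids <- sort(unique(d$particle_id))
  times <- sort(unique(d$time_s))
  for (id in ids) {
    tt <- d$time_s[d$particle_id == id]
    if (any(diff(tt) <= 0)) {
      r <- which(d$particle_id == id)[which(diff(tt) <= 0)[1] + 1]
      stop(sprintf("schema error: non-monotone time for particle %s at row %d",
                   id, r))
    }
    if (length(tt) != length(times))
      stop(sprintf("schema error: particle %s has %d samples, expected %d",
                   id, length(tt), length(times)))
  }
  grab <- function(col) {
    m <- matrix(NA_real_, length(times), length(ids))
    for (k in seq_along(ids))
      m[, k] <- d[[col]][d$particle_id == ids[k]]
    m
  }
  if (is.null(params))
    params <- swimmer_params(delta_t = 0)
  new_trajectory(times, grab("x_um"), grab("y_um"), grab("ux"), grab("uy"),
                 params, NULL)
}

config_keys <- list(
  a = "numeric", v0 = "numeric", D0 = "numeric", delta_t = "numeric",
  instr_delay = "numeric", frame_period = "numeric",
  duration = "numeric", dt = "numeric", n_particles = "numeric",
  seed = "numeric", target_fixed = "logical", interaction = "character",
  k_harmonic = "numeric", start_radius = "numeric",
  sample_every = "numeric", escape_box = "numeric")

#' Load simulation parameters and configuration from a YAML file
#'
#' A minimal file needs only `delta_t` (and typically `v0` and `duration`);
#' everything else is filled with the package defaults (`a = 1.09` um,
#' `D0 = 0.0642` um^2/s, `instr_delay = 0.064` s, ...).  Unknown keys and
#' type mismatches are rejected with the offending key named.
#'
#' @param path YAML file of key-value pairs.
#' @return List with elements `params` ([swimmer_params()]) and `config`
#'   ([sim_config()]).
#' @export
load_config <- function(path) {
  kv <- yaml::read_yaml(path)
  if (is.null(kv) || length(kv) == 0) stop("empty config file")
  unknown <- setdiff(names(kv), names(config_keys))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(kv)) {
    want <- config_keys[[k]]
    ok <- switch(want,
                 numeric = is.numeric(kv[[k]]),
                 logical = is.logical(kv[[k]]),
                 character = is.character(kv[[k]]))
    if (!ok)
      stop(sprintf("config key '%s' must be %s", k, want))
  }
  if (is.null(kv$delta_t)) stop("config must set delta_t")
  pargs <- kv[intersect(names(kv),
                        c("a", "v0", "D0", "delta_t", "instr_delay",
                          "frame_period"))]
  params <- do.call(swimmer_params, pargs)
  cargs <- kv[intersect(names(kv),
                        c("duration", "dt", "n_particles", "seed",
                          "target_fixed", "interaction", "k_harmonic",
                          "start_radius", "sample_every", "escape_box"))]
  if (is.null(cargs$duration)) cargs$duration <- 600
  config <- do.call(sim_config, cargs)
  list(params = params, config = config)
}

#' Write a configuration YAML file
#'
#' Round-trips with [load_config()].
#'
#' @param params A [swimmer_params()].
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, config, path) {
  kv <- c(params[!vapply(params, is.null, TRUE)],
          config[!vapply(config, is.null, TRUE)])
  kv <- kv[names(kv) %in% names(config_keys)]
  yaml::write_yaml(kv, path)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records the configuration snapshot, seed, package version, timestamp and
#' md5 digests of the listed files; deterministic stages re-run from the
#' same configuration and seed reproduce identical digests.
#'
#' @param params A [swimmer_params()].
#' @param config A [sim_config()].
#' @param files Character vector of output file paths to digest.
#' @param path Optional path to also write the manifest as JSON.
#' @return The manifest list, invisibly if `path` is given.
#' @export
run_manifest <- function(params, config, files = character(0), path = NULL) {
  m <- list(
    package = "delayswarm",
    version = as.character(utils::packageVersion("delayswarm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    params = params[!vapply(params, is.null, TRUE)],
    config = config[!vapply(config, is.null, TRUE) &
                      !vapply(config, is.matrix, TRUE)],
    digests = as.list(setNames(unname(tools::md5sum(files)), files)))
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(m))
  }
  m
}
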