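# File formats: plain CSV with a schema comment line, and JSON diagnostics
# with an explicit schema_version field. Readers reject unknown major versions
# and report malformed content with line numbers.

SCHEMA <- list(trajectory = "cfgeom-trajectory/1.0",
               ensemble = "cfgeom-ensemble/1.0",
               diagnostics = "cfgeom-diagnostics/1.0")

schema_major <- function(tag) sub("^.*/(\\d+)\\..*$", "\\1", tag)

check_schema <- function(found, expected, path) {
  if (is.null(found) || !nzchar(found))
    cf_stop(sprintf("%s: missing schema tag", path), "cfgeom_io_error")
  if (sub("/.*$", "", found) != sub("/.*$", "", expected) ||
      schema_major(found) != schema_major(expected))
    cf_stop(sprintf("%s: unsupported schema '%s' (reader expects %s)",
                    path, found, expected), "cfgeom_io_error")
}

read_schema_csv <- function(path, columns) {
  if (!file.exists(path))
    cf_stop(sprintf("%s: no such file", path), "cfgeom_io_error")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    cf_stop(sprintf("%s: truncated file", path), "cfgeom_io_error")
  tag <- if (startsWith(lines[1L], "# schema: "))
    sub("^# schema: ", "", lines[1L]) else ""
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(header, columns))
    cf_stop(sprintf("%s: malformed header '%s' (expected %s)",
                    path, body[1L], paste(columns, collapse = ",")),
            "cfgeom_io_error")
  if (length(body) < 2L)
    cf_stop(sprintf("%s: no data rows", path), "cfgeom_io_error")
  df <- utils::read.csv(text = body, colClasses = "character")
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & nzchar(df[[j]]))
    if (columns[j] != "condition_id" && length(bad) > 0L)
      cf_stop(sprintf("%s: non-numeric value '%s' in column %s, line %d",
                      path, df[[j]][bad[1L]], columns[j],
                      bad[1L] + 1L + sum(startsWith(lines, "#"))),
              "cfgeom_io_error")
    if (columns[j] != "condition_id") df[[j]] <- v
  }
  list(tag = tag, df = df)
}

#' Trajectory CSV input/output
#'
#' Writes a `saddle_trajectory` as CSV with columns
#' `time, p, c1, c2, clipped` at full double precision, preceded by a schema
#' comment line, with the generating parameters in a JSON sidecar
#' (`<path>.json`). `read_trajectory` round-trips losslessly and validates the
#' schema, numeric content and time monotonicity with line-numbered errors.
#'
#' @param traj a `saddle_trajectory` from [integrate_saddle()].
#' @param path output CSV path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `saddle_trajectory` (with `params` restored from the sidecar
#'   when present).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "saddle_trajectory"))
  df <- as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", SCHEMA$trajectory), con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, format_full), list(sep = ","))), con)
  p <- traj$params
  jsonlite::write_json(
    list(schema = SCHEMA$trajectory, params = unclass(p),
         integrator = "rk4-fixed-step"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

format_full <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 17, format = "g") else as.character(x)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  got <- read_schema_csv(path, c("time", "p", "c1", "c2", "clipped"))
  check_schema(got$tag, SCHEMA$trajectory, path)
  df <- got$df
  if (any(diff(df$time) <= 0))
    cf_stop(sprintf("%s: time column not strictly increasing (first violation after line %d)",
                    path, which(diff(df$time) <= 0)[1L] + 2L), "cfgeom_io_error")
  params <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    params <- tryCatch(do.call(minimal_model_params, meta$params[
      c("beta", "lam", "bias", "dt", "steps", "p0", "c0", "noise_sd", "seed")]),
      error = function(e) NULL)
  }
  if (is.null(params))
    params <- minimal_model_params(dt = if (nrow(df) > 1) df$time[2] - df$time[1] else 0.01,
                                   steps = nrow(df) - 1L, p0 = df$p[1])
  structure(list(times = df$time, p = df$p, c1 = df$c1, c2 = df$c2,
                 clipped = df$clipped != 0, params = params),
            class = "saddle_trajectory")
}

#' Ensemble CSV input/output (long format)
#'
#' One row per trial x time point, columns
#' `trial, condition_id, time, u, z`, preceded by a schema comment line.
#'
#' @param ens a [pr_ensemble()].
#' @param path CSV path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble` a
#'   [pr_ensemble()].
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "pr_ensemble"))
  n <- nrow(ens$responses); m <- ncol(ens$responses)
  df <- data.frame(trial = rep(seq_len(n), each = m),
                   condition_id = rep(ens$condition_id, each = m),
                   time = rep(ens$times, n),
                   u = rep(ens$perturbations, each = m),
                   z = as.vector(t(ens$responses)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", SCHEMA$ensemble), con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, format_full), list(sep = ","))), con)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  got <- read_schema_csv(path, c("trial", "condition_id", "time", "u", "z"))
  check_schema(got$tag, SCHEMA$ensemble, path)
  df <- got$df
  trials <- unique(df$trial)
  times <- unique(df$time)
  if (nrow(df) != length(trials) * length(times))
    cf_stop(sprintf("%s: trials do not share a common time grid", path),
            "cfgeom_io_error")
  z <- matrix(NA_real_, length(trials), length(times))
  u <- numeric(length(trials)); cond <- character(length(trials))
  for (i in seq_along(trials)) {
    rows <- df[df$trial == trials[i], ]
    rows <- rows[order(rows$time), ]
    z[i, ] <- rows$z
    u[i] <- rows$u[1L]
    cond[i] <- rows$condition_id[1L]
  }
  pr_ensemble(u, z, times = sort(times), condition_id = cond)
}

#' Diagnostics JSON input/output
#'
#' Serializes `regime_diagnostics`, `regime_call` or `sample_diagnostics`
#' objects (or plain lists) as JSON with an explicit `schema_version`; the
#' reader rejects unknown major versions and restores the class from the
#' recorded `kind`.
#'
#' @param diag the diagnostics object.
#' @param path JSON path.
#' @return `write_diagnostics` returns `path` invisibly; `read_diagnostics`
#'   the restored object.
#' @export
write_diagnostics <- function(diag, path) {
  kind <- class(diag)[1L]
  jsonlite::write_json(list(schema_version = SCHEMA$diagnostics, kind = kind,
                            payload = unclass(diag)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_diagnostics
#' @export
read_diagnostics <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(x$schema_version, SCHEMA$diagnostics, path)
  out <- x$payload
  if (x$kind %in% c("regime_diagnostics", "regime_call", "sample_diagnostics"))
    class(out) <- x$kind
  out
}
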