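# Plain-text configuration, CSV trajectory writers and XPPAUT .dat import.
#
# One flat "key = value" dialect (XPP .par style: `#` comments, blank lines
# ignored) serves parameters, scenario overrides and solver options; it
# diffs cleanly and round-trips losslessly at full double precision.

.parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- numeric(0)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value for '", key, "'")
    if (key %in% names(out)) stop("duplicate key '", key, "'")
    out[key] <- val
  }
  out
}

#' Load a parameter set from a key = value file
#'
#' The file must contain exactly the model's parameter names; missing or
#' unknown keys are fatal and reported by name.
#'
#' @param path file path.
#' @return a [g0_parameters] object.
#' @seealso [write_parameters()], [default_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  g0_parameters(.parse_config(path))
}

#' Write a parameter set as a key = value file
#'
#' @param params a [g0_parameters] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- as_g0_parameters(params)
  hdr <- c("# model parameter set (concentrations in a.u., rates in 1/h)",
           paste0("# sha: ", parameters_hash(params)))
  body <- paste(format(names(params), width = 10), "=",
                formatC(unclass(params), format = "g", digits = 17))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Hash of a parameter set (provenance tag for output headers)
#' @param params a [g0_parameters] object.
#' @return character scalar (first 12 hex digits of a content hash).
#' @export
parameters_hash <- function(params) {
  params <- as_g0_parameters(params)
  txt <- paste(names(params), formatC(unclass(params), format = "g",
                                      digits = 17), collapse = ";")
  # simple 31-bit polynomial rolling hash; a provenance tag, not crypto
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a trajectory as CSV
#'
#' RFC-4180 CSV with a `time` column, one column per species and one per
#' observable. Comment header lines (prefixed `#`) record the parameter
#' hash and applied perturbations.
#'
#' @param traj a `g0_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pr <- attr(traj, "params")
  if (!is.null(pr)) {
    writeLines(paste0("# params_hash=", parameters_hash(pr)), con)
  }
  for (pb in attr(traj, "perturbations")) {
    writeLines(paste0("# perturbation t=", pb$at_time, " ",
                      paste(names(pb$overrides), pb$overrides, sep = "=",
                            collapse = " ")), con)
  }
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path file path.
#' @return data frame with `time`, species and observable columns.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Import an XPPAUT-style .dat trajectory
#'
#' Whitespace-delimited numeric table, time in the first column. Column
#' names for the remaining columns come from `columns` or from a sidecar
#' name-map file (`<path>.names`, one species name per line).
#'
#' @param path file path.
#' @param columns character vector naming the non-time columns; if NULL, a
#'   sidecar `<path>.names` file is consulted, else columns are named V1..Vn.
#' @return data frame with a strictly increasing `time` column.
#' @export
import_xpp_trajectory <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) < 2) stop("expected a time column plus at least one series")
  if (is.null(columns)) {
    sidecar <- paste0(path, ".names")
    if (file.exists(sidecar)) {
      columns <- readLines(sidecar, warn = FALSE)
      columns <- trimws(columns[nzchar(trimws(columns))])
    } else {
      columns <- paste0("V", seq_len(ncol(tab) - 1))
    }
  }
  if (length(columns) != ncol(tab) - 1) {
    stop("column-count mismatch: file has ", ncol(tab) - 1,
         " series but ", length(columns), " names were given")
  }
  names(tab) <- c("time", columns)
  if (any(diff(tab$time) <= 0)) stop("time column is not strictly increasing")
  tab
}

#' Compare a trajectory against a reference, per species
#'
#' Linearly interpolates the model trajectory onto the reference time grid
#' and reports, for each shared column, the maximum absolute deviation as a
#' fraction of that column's dynamic range in the reference.
#'
#' @param traj model trajectory (data frame with `time`).
#' @param ref reference trajectory (data frame with `time`).
#' @param columns columns to compare (default: all shared, minus `time`).
#' @return named numeric vector of fractional max deviations.
#' @export
compare_trajectories <- function(traj, ref, columns = NULL) {
  if (is.null(columns)) {
    columns <- setdiff(intersect(names(traj), names(ref)), "time")
  }
  tt <- ref$time
  keep <- tt >= min(traj$time) & tt <= max(traj$time)
  vapply(columns, function(cn) {
    mi <- stats::approx(traj$time, traj[[cn]], xout = tt[keep])$y
    rg <- diff(range(ref[[cn]]))
    if (rg == 0) rg <- max(abs(ref[[cn]]), 1e-12)
    max(abs(mi - ref[[cn]][keep])) / rg
  }, numeric(1))
}
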