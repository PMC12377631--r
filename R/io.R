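#' Read a tumor-volume series from delimited text
#'
#' Reads a two-column `t, V` file (time in days, volume in cm^3). The
#' separator (comma, semicolon, tab or whitespace) and the presence of a
#' header row are auto-detected; decimals must use a dot. Malformed rows
#' raise an error naming the offending line.
#'
#' @param path file path.
#' @param sep optional separator override.
#' @return An [volume_series].
#' @export
read_volume_series <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  if (is.null(sep)) {
    probe <- lines[min(2L, length(lines))]
    sep <- if (grepl(",", probe, fixed = TRUE)) ","
           else if (grepl(";", probe, fixed = TRUE)) ";"
           else if (grepl("\t", probe, fixed = TRUE)) "\t"
           else ""
  }
  split_row <- function(s) {
    parts <- if (identical(sep, "")) strsplit(trimws(s), "[[:space:]]+")[[1L]]
             else trimws(strsplit(s, sep, fixed = TRUE)[[1L]])
    parts[nzchar(parts)]
  }
  first <- split_row(lines[1L])
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- if (has_header) lines[-1L] else lines
  offset <- if (has_header) 1L else 0L
  tv <- matrix(NA_real_, nrow = length(body), ncol = 2L)
  for (i in seq_along(body)) {
    parts <- split_row(body[i])
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2L || any(is.na(vals[1:2])))
      stop(sprintf("parse error at line %d of %s: '%s'",
                   i + offset, path, body[i]))
    tv[i, ] <- vals[1:2]
  }
  volume_series(tv[, 1L], tv[, 2L])
}

#' Write a tumor-volume series as delimited text
#'
#' @param series an [volume_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(series, path) {
  series <- .as_volume_series(series)
  utils::write.table(as.data.frame(series)[, c("t", "V")], path,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory with a JSON sidecar
#'
#' Writes the trajectory samples as delimited text with header `t,x,y`
#' (original coordinates) or `tau,u,v` (dimensionless), plus a
#' `<path>.json` sidecar recording the parameters, therapy and solver
#' settings.
#'
#' @param traj an `lv_trajectory`.
#' @param path output file path for the samples.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "lv_trajectory"))
  utils::write.table(as.data.frame(traj), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  meta <- list(coordinates = attr(traj, "coordinates"),
               params = unclass(attr(traj, "params")),
               therapy = if (!is.null(attr(traj, "therapy")))
                 unclass(attr(traj, "therapy")),
               solver = attr(traj, "solver"))
  write_results(meta, paste0(path, ".json"))
  invisible(path)
}

#' Read an exported trajectory
#'
#' @param path file written by [write_trajectory()].
#' @return A data frame with the stored columns (sidecar metadata, when
#'   present, in attribute `"meta"`).
#' @export
read_trajectory <- function(path) {
  out <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(out, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  out
}

#' Write results as JSON at full precision
#'
#' Serializes plain lists or classed package results (which are unclassed
#' recursively) with unboxed scalars and no digit rounding, so numeric
#' results round-trip.
#'
#' @param x object to serialize.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  jsonlite::write_json(.jsonable(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       force = TRUE)
  invisible(path)
}

# strip classes/functions and render complex eigenvalues (internal)
.jsonable <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.complex(x)) {
    return(if (all(Im(x) == 0)) Re(x)
           else list(re = Re(x), im = Im(x)))
  }
  if (is.data.frame(x)) return(as.data.frame(lapply(x, .jsonable)))
  if (is.list(x)) {
    out <- lapply(unclass(x), .jsonable)
    return(out[!vapply(out, is.null, logical(1L))])
  }
  if (is.matrix(x)) return(unclass(x))
  x
}
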