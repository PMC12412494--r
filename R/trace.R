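# MultiChannelTrace: the common currency between pipeline stages. A trace is
# a strictly increasing time base plus named channels with unit strings, a
# nominal sample rate and a provenance metadata list. On disk it is a plain
# CSV with "name [unit]" headers and a JSON sidecar for metadata.

#' Multichannel time-series trace
#'
#' Constructs the container used by every pipeline stage: a strictly
#' increasing time vector in seconds and one or more named channels of equal
#' length, each with a unit string. Provenance (simulator seed, stage,
#' configuration) travels in `metadata` and is persisted in the JSON sidecar
#' by [write_trace()].
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param channels named list (or data.frame) of numeric vectors, all the
#'   same length as `time`. `NA` marks masked samples.
#' @param units named character vector of unit strings, one per channel.
#' @param sample_rate nominal sampling rate in Hz; inferred from `time` when
#'   omitted.
#' @param metadata list of provenance values (seed, stage, config, ...).
#' @return an object of class `mc_trace`.
#' @examples
#' tr <- mc_trace(time = 0:9 / 2,
#'                channels = list(icp = rep(0, 10)),
#'                units = c(icp = "mmHg"))
#' tr
#' @export
mc_trace <- function(time, channels, units, sample_rate = NULL,
                     metadata = list()) {
  time <- as.numeric(time)
  channels <- lapply(as.list(channels), as.numeric)
  if (length(time) > 1 && any(diff(time) <= 0))
    abort("time must be strictly increasing", "acs_format_error")
  if (length(channels)) {
    if (is.null(names(channels)) || any(!nzchar(names(channels))))
      abort("all channels must be named", "acs_format_error")
    bad <- vapply(channels, length, 1L) != length(time)
    if (any(bad))
      abort(sprintf("channel length mismatch: %s",
                    paste(names(channels)[bad], collapse = ", ")),
            "acs_format_error")
    if (is.null(names(units)) ||
        !all(names(channels) %in% names(units)) ||
        any(!nzchar(units[names(channels)])))
      abort("every channel needs a nonempty unit string", "acs_format_error")
    units <- units[names(channels)]
  } else units <- stats::setNames(character(0), character(0))
  if (is.null(sample_rate))
    sample_rate <- if (length(time) > 1) 1 / stats::median(diff(time)) else NA_real_
  structure(list(time = time, channels = channels,
                 units = units, sample_rate = sample_rate,
                 metadata = metadata),
            class = "mc_trace")
}

#' @export
print.mc_trace <- function(x, ...) {
  cat(sprintf("<mc_trace> %d samples, %.6g s to %.6g s (~%.4g Hz)\n",
              length(x$time),
              if (length(x$time)) min(x$time) else NA,
              if (length(x$time)) max(x$time) else NA,
              x$sample_rate))
  for (nm in names(x$channels))
    cat(sprintf("  %-14s [%s]\n", nm, x$units[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.mc_trace <- function(x, ...) {
  do.call(data.frame, c(list(time = x$time), x$channels,
                        list(check.names = FALSE)))
}

#' Extract a named channel from a trace
#'
#' @param trace an [mc_trace()].
#' @param name channel name.
#' @return numeric vector of channel values.
#' @export
trace_channel <- function(trace, name) {
  if (!name %in% names(trace$channels))
    abort(sprintf("channel '%s' not present", name), "acs_format_error")
  trace$channels[[name]]
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a trace to CSV with a JSON metadata sidecar
#'
#' Writes a deterministic CSV (`time [s]` first, then channels in their
#' stored order, full double precision) and a `<path>.json` sidecar holding
#' units, nominal sample rate and the metadata list.
#'
#' @param trace an [mc_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "mc_trace"))
  header <- c("time [s]",
              sprintf("%s [%s]", names(trace$channels), trace$units))
  cols <- c(list(trace$time), unname(trace$channels))
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                           sep = ","))
  ok <- tryCatch({
    writeLines(c(paste(header, collapse = ","), if (length(trace$time)) body),
               path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write '%s'", path), "acs_io_error")
  side <- list(units = as.list(trace$units),
               sample_rate = trace$sample_rate,
               metadata = trace$metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' Parses the `name [unit]` CSV header, enforces the trace invariants
#' (strictly increasing time, nonempty units) and restores metadata from the
#' JSON sidecar when present. Missing cells become `NA` (masked samples).
#'
#' @param path CSV path.
#' @return an [mc_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path), "acs_io_error")
  df <- utils::read.csv(path, check.names = FALSE)
  hdr <- names(df)
  m <- regmatches(hdr, regexec("^\\s*(.+?)\\s*\\[(.+)\\]\\s*$", hdr))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    abort(sprintf("header missing '[unit]': %s",
                  paste(hdr[bad], collapse = ", ")), "acs_format_error")
  nm <- vapply(m, `[`, "", 2L)
  un <- vapply(m, `[`, "", 3L)
  if (nm[1] != "time")
    abort("first column must be 'time [s]'", "acs_format_error")
  time <- as.numeric(df[[1]])
  if (anyNA(time) || (length(time) > 1 && any(diff(time) <= 0)))
    abort("time column must be finite and strictly increasing",
          "acs_format_error")
  channels <- stats::setNames(lapply(df[-1], as.numeric), nm[-1])
  units <- stats::setNames(un[-1], nm[-1])
  meta <- list(); sr <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    meta <- as.list(side$metadata)
    if (!is.null(side$sample_rate)) sr <- side$sample_rate
  }
  mc_trace(time, channels, units, sample_rate = sr, metadata = meta)
}
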