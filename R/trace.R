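#' Uniformly sampled trace
#'
#' The unit every analysis operator consumes: a time series of membrane
#' potential (`kind = "voltage"`, mV) or clamp current (`kind = "current"`,
#' pA) on a strictly increasing, uniform time grid, with a metadata snapshot
#' of the protocol/parameters that produced it.
#'
#' @param times Time grid (ms); uniform within 1e-9 relative tolerance.
#' @param values Sample values (mV or pA).
#' @param kind `"voltage"` or `"current"`.
#' @param metadata Arbitrary named list (protocol + parameter snapshot).
#' @return An object of class `trace`.
#' @export
new_trace <- function(times, values, kind = c("voltage", "current"),
                      metadata = list()) {
  kind <- match.arg(kind)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) >= 2) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
    if (max(abs(dt - dt[1])) > 1e-9 * max(1, abs(dt[1]))) {
      stop("times must be uniformly spaced", call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind, metadata = metadata),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  n <- length(x$times)
  unit <- if (x$kind == "voltage") "mV" else "pA"
  cat(sprintf("%s trace: %d samples, %.6g .. %.6g ms, range [%.4g, %.4g] %s\n",
              x$kind, n, x$times[1], x$times[n],
              min(x$values), max(x$values), unit))
  invisible(x)
}

trace_dt <- function(trace) {
  if (length(trace$times) < 2) stop("trace too short", call. = FALSE)
  trace$times[2] - trace$times[1]
}

#' @export
as.data.frame.trace <- function(x, ...) {
  data.frame(time_ms = x$times, value = x$values, kind = x$kind)
}

#' Write or read a trace as CSV with a JSON provenance sidecar
#'
#' The CSV has columns `time_ms, value, kind`; the full metadata snapshot is
#' written next to it as `<path>.json`.
#'
#' @param trace A [new_trace()] object.
#' @param path CSV file path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a `trace`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  jsonlite::write_json(trace$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  new_trace(df$time_ms, df$value, kind = as.character(df$kind[1]),
            metadata = meta)
}

#' Sweep set
#'
#' An ordered collection of current traces from a voltage-clamp family, one
#' per command step, each tagged with its step potential.
#'
#' @param traces List of current `trace` objects.
#' @param step_mv Numeric vector of command potentials (mV), one per trace.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(traces, step_mv) {
  stopifnot(length(traces) == length(step_mv))
  structure(list(traces = traces, step_mv = as.numeric(step_mv)),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("sweep set: %d sweeps, steps %g .. %g mV\n",
              length(x$traces), min(x$step_mv), max(x$step_mv)))
  invisible(x)
}

#' @export
length.sweep_set <- function(x) length(x$traces)

#' Write or read a sweep set as a single tidy CSV
#'
#' Columns: `time_ms, current_pA, step_mV`.
#'
#' @param sweeps A [sweep_set()].
#' @param path CSV file path.
#' @export
write_sweeps_csv <- function(sweeps, path) {
  df <- do.call(rbind, lapply(seq_along(sweeps$traces), function(i) {
    tr <- sweeps$traces[[i]]
    data.frame(time_ms = tr$times, current_pA = tr$values,
               step_mV = sweeps$step_mv[i])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweeps_csv
#' @export
read_sweeps_csv <- function(path) {
  df <- utils::read.csv(path)
  steps <- sort(unique(df$step_mV))
  traces <- lapply(steps, function(s) {
    sub <- df[df$step_mV == s, ]
    new_trace(sub$time_ms, sub$current_pA, kind = "current",
              metadata = list(step_mV = s))
  })
  sweep_set(traces, steps)
}
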