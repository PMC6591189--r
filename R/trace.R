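#' Uniformly sampled waveform trace
#'
#' The basic container for a sampled physiological signal: a start time, a
#' uniform sampling interval and a numeric vector of samples with a unit tag.
#' Everything downstream (beats, flows, simulated records) is built on it.
#'
#' @param values numeric vector of samples; all finite, at least 8 samples.
#' @param dt sampling interval in seconds (> 0).
#' @param t0 time of the first sample in seconds.
#' @param units unit string for the samples, e.g. `"mmHg"`, `"mL/s"`, `"mV"`.
#' @param label channel name.
#'
#' @return An object of class `lv_trace` with fields `t0`, `dt`, `values`,
#'   `units`, `label`.
#' @export
#' @examples
#' tr <- lv_trace(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.001)
#' length(trace_times(tr))
lv_trace <- function(values, dt, t0 = 0, units = "mmHg", label = "signal") {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)")
  if (length(values) < 8L)
    stop("a trace needs at least 8 samples, got ", length(values))
  if (!all(is.finite(values)))
    stop("trace samples must all be finite; first bad index: ",
         which(!is.finite(values))[1L])
  structure(
    list(t0 = as.numeric(t0), dt = dt, values = values,
         units = as.character(units), label = as.character(label)),
    class = "lv_trace")
}

#' Sample times of a trace
#'
#' @param x an [lv_trace].
#' @return Numeric vector `t0 + (0:(n-1)) * dt`.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "lv_trace"))
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

#' @export
print.lv_trace <- function(x, ...) {
  cat(sprintf("<lv_trace> %s [%s]: %d samples @ %.6g s (%.4g s span)\n",
              x$label, x$units, length(x$values), x$dt,
              length(x$values) * x$dt))
  invisible(x)
}

# Known CSV column -> (label, units).  The record format is a plain CSV with a
# `time_s` column and any subset of these channels.
.lv_known_columns <- function() {
  list(p_lv_mmHg  = c(label = "p_lv",  units = "mmHg"),
       q_ao_ml_s  = c(label = "q_ao",  units = "mL/s"),
       ecg_mv     = c(label = "ecg",   units = "mV"))
}

#' Read a waveform record from CSV
#'
#' Reads a record with a `time_s` column (seconds, uniform grid) plus one or
#' more signal columns, and returns one [lv_trace] per mapped column.  The
#' sampling interval is inferred from the median time step; the grid must be
#' uniform to within `1e-6` relative tolerance.
#'
#' @param path path to a CSV file (header row, comma separated).
#' @param column_map named character vector mapping output trace names to CSV
#'   column names, e.g. `c(p_lv = "p_lv_mmHg")`.  By default all recognised
#'   channel columns (`p_lv_mmHg`, `q_ao_ml_s`, `ecg_mv`) present in the file
#'   are read.
#'
#' @return Named list of [lv_trace] objects.
#' @export
read_record <- function(path, column_map = NULL) {
  dat <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(dat))
    stop("record is missing the 'time_s' column: ", path)
  tt <- as.numeric(dat$time_s)
  if (length(tt) < 8L) stop("record too short: ", length(tt), " rows")
  steps <- diff(tt)
  dt <- stats::median(steps)
  if (dt <= 0) stop("non-increasing time grid at index ",
                    which(steps <= 0)[1L])
  bad <- which(abs(steps - dt) > 1e-6 * dt)
  if (length(bad))
    stop("non-uniform time grid: step ", bad[1L], " is ",
         format(steps[bad[1L]]), " s but median step is ", format(dt), " s")

  known <- .lv_known_columns()
  if (is.null(column_map)) {
    present <- intersect(names(known), names(dat))
    if (!length(present)) stop("no recognised signal columns in ", path)
    column_map <- stats::setNames(present,
                                  vapply(known[present], `[[`, "", "label"))
  }
  out <- list()
  for (nm in names(column_map)) {
    col <- column_map[[nm]]
    if (!col %in% names(dat)) stop("missing column '", col, "' in ", path)
    units <- if (col %in% names(known)) known[[col]][["units"]] else "a.u."
    out[[nm]] <- lv_trace(as.numeric(dat[[col]]), dt = dt, t0 = tt[1L],
                          units = units, label = nm)
  }
  out
}

#' Write traces to a CSV record
#'
#' Inverse of [read_record()]: all traces must share `t0`, `dt` and length.
#' Column names follow the record convention (`time_s` plus the names of
#' `traces`).
#'
#' @param traces named list of [lv_trace] objects on a common grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_record <- function(traces, path) {
  stopifnot(is.list(traces), length(traces) >= 1L, !is.null(names(traces)))
  ref <- traces[[1L]]
  for (tr in traces) {
    stopifnot(inherits(tr, "lv_trace"))
    if (abs(tr$t0 - ref$t0) > 1e-12 || abs(tr$dt - ref$dt) > 1e-15 ||
        length(tr$values) != length(ref$values))
      stop("all traces must share one time grid")
  }
  dat <- data.frame(time_s = trace_times(ref), check.names = FALSE)
  for (nm in names(traces)) dat[[nm]] <- traces[[nm]]$values
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
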