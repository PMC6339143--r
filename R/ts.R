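#' Uniformly sampled single-channel trace
#'
#' Basic container for a uniformly sampled extracellular trace. Current
#' traces are carried in picoampere (pA), the natural scale of large-area
#' MEA recordings; voltage traces are carried in volt (V). The unit tag
#' decides which interpretation applies and is checked by every operation
#' that consumes a trace.
#'
#' @param values Numeric vector of samples (pA for `unit = "current"`,
#'   V for `unit = "voltage"`). Length must be at least 2.
#' @param dt Sampling interval in seconds (positive scalar).
#' @param t0 Time of the first sample in seconds.
#' @param unit Either `"current"` or `"voltage"`.
#'
#' @return An object of class `mea_ts`: a list with elements `values`,
#'   `dt`, `t0` and `unit`.
#' @examples
#' ts <- mea_ts(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.01)
#' ts_duration(ts)
#' @export
mea_ts <- function(values, dt, t0 = 0, unit = c("current", "voltage")) {
  unit <- match.arg(unit)
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector with at least 2 samples",
         call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive sampling interval in seconds",
         call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite start time in seconds", call. = FALSE)
  structure(
    list(values = as.numeric(values), dt = as.numeric(dt),
         t0 = as.numeric(t0), unit = unit),
    class = "mea_ts"
  )
}

.assert_ts <- function(x, unit = NULL, arg = deparse(substitute(x))) {
  if (!inherits(x, "mea_ts"))
    stop(sprintf("`%s` must be an `mea_ts` object", arg), call. = FALSE)
  if (!is.null(unit) && x$unit != unit)
    stop(sprintf("`%s` must carry unit tag '%s', got '%s'", arg, unit,
                 x$unit), call. = FALSE)
  invisible(x)
}

#' Sample times of a trace
#'
#' @param x An [mea_ts] object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(x) {
  .assert_ts(x)
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

#' Duration of a trace
#'
#' @param x An [mea_ts] object.
#' @return Time span covered by the samples, in seconds.
#' @export
ts_duration <- function(x) {
  .assert_ts(x)
  (length(x$values) - 1L) * x$dt
}

#' Extract a time window from a trace
#'
#' Returns the samples whose times fall in the half-open interval
#' `[start, end)`.
#'
#' @param x An [mea_ts] object.
#' @param start,end Window bounds in seconds.
#' @return An [mea_ts] covering the window.
#' @export
ts_window <- function(x, start, end) {
  .assert_ts(x)
  if (end <= start) stop("`end` must exceed `start`", call. = FALSE)
  tt <- ts_time(x)
  keep <- tt >= start & tt < end
  if (sum(keep) < 2L)
    stop("window contains fewer than 2 samples", call. = FALSE)
  mea_ts(x$values[keep], dt = x$dt, t0 = tt[keep][1L], unit = x$unit)
}

#' @export
print.mea_ts <- function(x, ...) {
  cat(sprintf("<mea_ts> %s trace: %d samples @ %.6g Hz, %.6g s, range [%.4g, %.4g] %s\n",
              x$unit, length(x$values), 1 / x$dt, ts_duration(x),
              min(x$values), max(x$values),
              if (x$unit == "current") "pA" else "V"))
  invisible(x)
}

#' @export
as.data.frame.mea_ts <- function(x, ...) {
  if (x$unit == "current")
    data.frame(time_s = ts_time(x), current_pA = x$values)
  else
    data.frame(time_s = ts_time(x), voltage_V = x$values)
}

#' @export
plot.mea_ts <- function(x, ..., xlab = "time (s)",
                        ylab = if (x$unit == "current") "current (pA)" else "voltage (V)",
                        type = "l") {
  graphics::plot(ts_time(x), x$values, type = type, xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}
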