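#' Construct a uniformly sampled time series
#'
#' The unit of analysis for XT data: one channel of a recording, sampled on a
#' strictly increasing, uniform time grid.  Image stacks are decomposed into
#' one such series per pixel.
#'
#' @param times Numeric vector of sample times, strictly increasing with a
#'   uniform step (checked to a relative tolerance of 1e-6 on the step).
#' @param values Numeric vector of signal values, same length as `times`.
#'   All values must be finite; recordings with missing samples are rejected
#'   at load time rather than carried through the analysis.
#' @param label Free-text channel name.
#' @param unit Time unit tag carried through all outputs (default `"ms"`);
#'   values are never converted between units.
#' @return An object of class `time_series`: a list with elements `times`,
#'   `values`, `dt`, `label` and `unit`.
#' @examples
#' ts <- time_series(seq(0, 99, by = 1), sin(seq(0, 99) / 5), label = "demo")
#' ts$dt
#' @export
time_series <- function(times, values, label = "", unit = "ms") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 3L)
    pm_input_error("a time series needs at least 3 samples, got ", length(times))
  if (length(values) != length(times))
    pm_input_error("times and values differ in length (", length(times),
                   " vs ", length(values), ")")
  if (anyNA(times) || any(!is.finite(times)))
    pm_input_error("time axis contains non-finite values")
  steps <- diff(times)
  dt <- stats::median(steps)
  if (dt <= 0)
    pm_input_error("time axis is not strictly increasing")
  bad <- which(abs(steps - dt) > 1e-6 * dt)
  if (length(bad))
    pm_input_error("non-uniform time step at row ", bad[1L] + 1L,
                   " (step ", format(steps[bad[1L]]), ", expected ", format(dt), ")")
  if (anyNA(values) || any(!is.finite(values)))
    pm_input_error("signal contains non-finite values (first at sample ",
                   which(!is.finite(values))[1L], ")")
  structure(
    list(times = times, values = values, dt = dt,
         label = as.character(label)[1L], unit = as.character(unit)[1L]),
    class = "time_series"
  )
}

#' Build a time series from values and a sampling step
#'
#' Convenience constructor when only the sampling interval is known: the time
#' axis is `0, dt, 2*dt, ...`.
#'
#' @param values Numeric signal vector (length >= 3, finite).
#' @param dt Sampling interval, > 0.
#' @inheritParams time_series
#' @return A [time_series()] object.
#' @export
as_time_series <- function(values, dt, label = "", unit = "ms") {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    pm_input_error("dt must be a single positive number")
  time_series(seq(0, by = dt, length.out = length(values)), values,
              label = label, unit = unit)
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d samples, dt = %g %s, range [%g, %g]\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              length(x$values), x$dt, x$unit,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

is_time_series <- function(x) inherits(x, "time_series")

check_time_series <- function(x) {
  if (!is_time_series(x))
    pm_input_error("expected a time_series object")
  invisible(x)
}
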