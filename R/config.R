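#' Detection and parameterization settings
#'
#' Bundles every tunable of the peak analyzer.  The central control is
#' `sensitivity_percent`: a peak is kept only if its topographic prominence
#' exceeds this percentage of the whole-trace range (global maximum minus
#' global minimum), so higher values exclude noise and small deflections.
#'
#' @param sensitivity_percent Prominence threshold as a percentage of the
#'   global signal range, in (0, 100].  Default 20.
#' @param polarity `"positive"`, `"negative"` or `"both"`.  Negative peaks are
#'   detected by running the identical procedure on the negated trace; their
#'   amplitude, area and rise slope are reported positive by convention.
#' @param min_separation Minimum time between successive apexes (same unit as
#'   the series).  Events closer than this are merged, keeping the apex with
#'   the larger prominence.  Default 0 (no merging).
#' @param smooth_window Optional boxcar width in samples for a detection-only
#'   smoothed copy of the trace; apexes, boundaries and all parameters are
#'   always measured on the raw trace.  Default `NULL` (off).
#' @param threshold_fraction Fraction of the peak amplitude above baseline that
#'   defines the event threshold (onset marker); time-to-peak is measured from
#'   this crossing.  Default 0.10.
#' @param decay_fit_range Two amplitude fractions, strictly decreasing, that
#'   bound the window of the mono-exponential decay fit.  Default `c(0.9, 0.1)`:
#'   the fit uses the part of the decay between 90% and 10% of the amplitude.
#' @param apex_refine If `TRUE` (default), `apex_time` is refined to
#'   sub-sample precision by the vertex of a local quadratic fit around the
#'   apex sample (standard peak interpolation; counters the sample-noise
#'   wander of the raw argmax on flat peak tops).  `apex_index` and
#'   `apex_value` always remain the raw extremum sample.  Plateau apexes
#'   (tied samples) are never refined and keep their first sample.
#' @param spatial_sigma Optional Gaussian sigma (pixels) for stack-wide spatial
#'   pre-smoothing in [analyze_stack()].  Default `NULL` (off).
#' @param temporal_window Optional boxcar width (frames) for temporal
#'   pre-smoothing in [analyze_stack()].  Default `NULL` (off).
#' @return An object of class `detection_config`.
#' @examples
#' detection_config(sensitivity_percent = 30, polarity = "both")
#' @export
detection_config <- function(sensitivity_percent = 20,
                             polarity = c("positive", "negative", "both"),
                             min_separation = 0,
                             smooth_window = NULL,
                             threshold_fraction = 0.10,
                             decay_fit_range = c(0.9, 0.1),
                             apex_refine = TRUE,
                             spatial_sigma = NULL,
                             temporal_window = NULL) {
  polarity <- match.arg(polarity)
  if (!is.numeric(sensitivity_percent) || length(sensitivity_percent) != 1L ||
      !is.finite(sensitivity_percent) ||
      sensitivity_percent <= 0 || sensitivity_percent > 100)
    pm_input_error("sensitivity_percent must be in (0, 100]")
  if (!is.numeric(min_separation) || min_separation < 0)
    pm_input_error("min_separation must be >= 0")
  if (!is.null(smooth_window)) {
    smooth_window <- as.integer(smooth_window)
    if (smooth_window < 1L)
      pm_input_error("smooth_window must be a positive number of samples")
  }
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    pm_input_error("threshold_fraction must be in (0, 1)")
  if (length(decay_fit_range) != 2L ||
      any(decay_fit_range <= 0) || any(decay_fit_range >= 1) ||
      decay_fit_range[1L] <= decay_fit_range[2L])
    pm_input_error("decay_fit_range must be two strictly decreasing fractions in (0, 1)")
  structure(
    list(sensitivity_percent = sensitivity_percent,
         polarity = polarity,
         min_separation = min_separation,
         smooth_window = smooth_window,
         threshold_fraction = threshold_fraction,
         decay_fit_range = as.numeric(decay_fit_range),
         apex_refine = isTRUE(apex_refine),
         spatial_sigma = spatial_sigma,
         temporal_window = temporal_window),
    class = "detection_config"
  )
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<detection_config> sensitivity %g%%, polarity %s, min_separation %g,\n",
    "  smooth_window %s, threshold_fraction %g, decay_fit_range [%g, %g]\n"),
    x$sensitivity_percent, x$polarity, x$min_separation,
    if (is.null(x$smooth_window)) "off" else x$smooth_window,
    x$threshold_fraction, x$decay_fit_range[1L], x$decay_fit_range[2L]))
  invisible(x)
}

check_config <- function(config) {
  if (!inherits(config, "detection_config"))
    pm_input_error("expected a detection_config object (see detection_config())")
  invisible(config)
}
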