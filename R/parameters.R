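# Per-event parameters.  All measurements are done on a sign-adjusted working
# trace w = polarity * values, so a negative-going event is parameterized
# exactly like a positive one; amplitude, area and the rising slope of a
# negative event are therefore positive by convention.  Sub-sample level
# crossings are located by linear interpolation between bracketing samples,
# which makes widths and the threshold time independent of the sampling step
# to first order.

#' Estimate the baseline of a detected event
#'
#' The baseline is the median of the raw signal over the quiet segment that
#' precedes the event: the samples between the previous event's right
#' boundary (or the trace start for the first event) and this event's left
#' boundary.  If that segment is shorter than 3 samples -- as happens for
#' closely packed events -- the fall-back is the signal minimum between the
#' left boundary and the apex (maximum for negative-polarity events).
#'
#' @param series A [time_series()].
#' @param event A `peak_event` from [detect_peaks()].
#' @param all_events The full event list the event came from (used to locate
#'   the preceding event).  Defaults to just the event itself.
#' @return The baseline value, in signal units (original sign).
#' @export
estimate_baseline <- function(series, event, all_events = list(event)) {
  check_time_series(series)
  v <- series$values
  prev_rb <- 1L
  for (e in all_events) {
    if (e$apex_time < event$apex_time && e$right_bound > prev_rb)
      prev_rb <- e$right_bound
  }
  seg <- seq.int(prev_rb, event$left_bound)
  # use the later half of the quiet segment: it is closest to the event's
  # onset and least contaminated by the previous event's decay tail
  if (length(seg) >= 6L) seg <- seg[seq.int(ceiling(length(seg) / 2), length(seg))]
  if (length(seg) >= 3L) return(stats::median(v[seg]))
  w <- v * event$polarity
  event$polarity * min(w[event$left_bound:event$apex_index])
}

# Monotone trend of the event's two phases: the rise (left bound to apex) is
# replaced by its isotonic non-decreasing fit, the decay (apex to right
# bound) by its isotonic non-increasing fit.  On noiseless data this is the
# identity; on noisy data level crossings of the trend estimate the phase
# crossing instead of the first noise excursion, which would otherwise bias
# widths low.  Samples outside the two phases are left untouched.
phase_trend <- function(w, lb, apex, rb) {
  wt <- w
  if (apex > lb) {
    seg <- lb:apex
    wt[seg] <- stats::isoreg(seq_along(seg), w[seg])$yf
  }
  if (rb > apex) {
    seg <- apex:rb
    wt[seg] <- -stats::isoreg(seq_along(seg), -w[seg])$yf
  }
  wt
}

# interpolated time of the last upward crossing of `level` on w before idx_hi,
# searching [idx_lo, idx_hi]; NA if w never crosses upward in the window
cross_up_last <- function(times, w, level, idx_lo, idx_hi) {
  if (idx_hi <= idx_lo) return(NA_real_)
  seg <- idx_lo:(idx_hi - 1L)
  hit <- seg[w[seg] < level & w[seg + 1L] >= level]
  if (!length(hit)) return(NA_real_)
  i <- hit[length(hit)]
  frac <- (level - w[i]) / (w[i + 1L] - w[i])
  times[i] + frac * (times[i + 1L] - times[i])
}

# interpolated time of the first downward crossing of `level` after idx_lo
cross_down_first <- function(times, w, level, idx_lo, idx_hi) {
  if (idx_hi <= idx_lo) return(NA_real_)
  seg <- idx_lo:(idx_hi - 1L)
  hit <- seg[w[seg] >= level & w[seg + 1L] < level]
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  frac <- (w[i] - level) / (w[i] - w[i + 1L])
  times[i] + frac * (times[i + 1L] - times[i])
}

#' Width of an event at a fraction of its amplitude
#'
#' Measures the duration between the last upward crossing of
#' `baseline + fraction * amplitude` before the apex and the first downward
#' crossing after it, both located by linear interpolation.  Crossings are
#' taken on the monotone (isotonic) trend of each phase -- the identity for
#' noiseless data -- so that sample noise at shallow crossings does not bias
#' widths towards the first noise excursion.  `fraction = 0.5`
#' gives the full width at half maximum (FWHM; for action potentials this is
#' APD50) and `fraction = 0.1` the width at 10% amplitude (FW10 / APD90).
#'
#' @inheritParams estimate_baseline
#' @param fraction Amplitude fraction in (0, 1).
#' @param baseline Optional precomputed baseline; estimated if missing.
#' @return A list with `width`, `t_rise`, `t_fall` and `valid`.  `valid` is
#'   `FALSE` (and the values `NA`) when the level is never crossed inside the
#'   event boundaries, e.g. for events truncated by the trace ends.
#' @export
fractional_width <- function(series, event, fraction,
                             baseline = NULL, all_events = list(event)) {
  check_time_series(series)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    pm_input_error("fraction must be in (0, 1)")
  if (is.null(baseline))
    baseline <- estimate_baseline(series, event, all_events)
  w <- series$values * event$polarity
  b <- baseline * event$polarity
  amp <- w[event$apex_index] - b
  if (amp <= 0)
    return(list(width = NA_real_, t_rise = NA_real_, t_fall = NA_real_,
                valid = FALSE))
  level <- b + fraction * amp
  wt <- phase_trend(w, event$left_bound, event$apex_index, event$right_bound)
  t_rise <- cross_up_last(series$times, wt, level, event$left_bound, event$apex_index)
  t_fall <- cross_down_first(series$times, wt, level, event$apex_index, event$right_bound)
  valid <- is.finite(t_rise) && is.finite(t_fall)
  list(width = if (valid) t_fall - t_rise else NA_real_,
       t_rise = t_rise, t_fall = t_fall, valid = valid)
}

#' Maximal slope of the rising or decaying phase
#'
#' The extremal two-point finite difference `(v[i+1] - v[i]) / dt` over the
#' rising segment (left boundary to apex; maximum) or the decay segment (apex
#' to right boundary; minimum), with the first extremal pair winning ties.
#' For negative-polarity events the trace is sign-flipped first, so the
#' "rise" is the approach to the trough and its slope is reported positive.
#'
#' @inheritParams estimate_baseline
#' @param phase `"rise"` or `"decay"`.
#' @return A list with `slope` (signal units per time unit), `time` (midpoint
#'   of the winning sample pair) and `valid` (`FALSE` when the segment has
#'   fewer than 2 samples).
#' @export
max_slope <- function(series, event, phase = c("rise", "decay")) {
  check_time_series(series)
  phase <- match.arg(phase)
  w <- series$values * event$polarity
  idx <- if (phase == "rise") event$left_bound:event$apex_index
         else event$apex_index:event$right_bound
  if (length(idx) < 2L)
    return(list(slope = NA_real_, time = NA_real_, valid = FALSE))
  d <- diff(w[idx]) / series$dt
  i <- if (phase == "rise") which.max(d) else which.min(d)
  list(slope = d[i],
       time = (series$times[idx[i]] + series$times[idx[i] + 1L]) / 2,
       valid = TRUE)
}

#' Mono-exponential decay constant of an event
#'
#' Fits `value(t) = baseline + A * exp(-(t - t0) / tau)` to the decay phase,
#' restricted to samples whose baseline-subtracted amplitude lies between the
#' two fractions of `config$decay_fit_range` (default 90% down to 10% of the
#' peak amplitude).  A log-linear regression of `log(value - baseline)`
#' against time provides the initial estimate, which is then refined by
#' Levenberg-Marquardt nonlinear least squares; if the refinement fails to
#' converge the log-linear estimate is returned.
#'
#' @inheritParams estimate_baseline
#' @param config A [detection_config()] (supplies `decay_fit_range`).
#' @param baseline Optional precomputed baseline.
#' @return A list with `tau` (> 0 time units, or `NA`), `valid`, and `reason`
#'   (`""` when valid; otherwise why the fit was not possible, e.g. fewer
#'   than 5 usable samples in the fit window).
#' @export
fit_decay_tau <- function(series, event, config = detection_config(),
                          baseline = NULL, all_events = list(event)) {
  check_time_series(series)
  check_config(config)
  if (is.null(baseline))
    baseline <- estimate_baseline(series, event, all_events)
  w <- series$values * event$polarity
  b <- baseline * event$polarity
  amp <- w[event$apex_index] - b
  if (amp <= 0)
    return(list(tau = NA_real_, valid = FALSE, reason = "non-positive amplitude"))
  hi <- config$decay_fit_range[1L]
  lo <- config$decay_fit_range[2L]
  idx <- event$apex_index:event$right_bound
  rel <- (w[idx] - b) / amp
  first <- which(rel <= hi)
  if (!length(first))
    return(list(tau = NA_real_, valid = FALSE, reason = "decay never drops into fit window"))
  start <- first[1L]
  below <- which(rel < lo)
  below <- below[below >= start]
  end <- if (length(below)) below[1L] - 1L else length(idx)
  if (end - start + 1L < 5L)
    return(list(tau = NA_real_, valid = FALSE, reason = "fewer than 5 samples in fit window"))
  sel <- idx[start:end]
  resid <- w[sel] - b
  if (any(resid <= 0))
    return(list(tau = NA_real_, valid = FALSE,
                reason = "non-positive residual amplitude in fit window"))
  tt <- series$times[sel] - series$times[sel[1L]]
  fit0 <- stats::lm.fit(cbind(1, tt), log(resid))
  slope <- fit0$coefficients[2L]
  if (!is.finite(slope) || slope >= 0)
    return(list(tau = NA_real_, valid = FALSE, reason = "non-decaying segment"))
  tau0 <- -1 / slope
  a0 <- exp(fit0$coefficients[1L])
  tau <- tau0
  refined <- tryCatch({
    df <- data.frame(tt = tt, y = resid)
    fit <- minpack.lm::nlsLM(y ~ A * exp(-tt / tau), data = df,
                             start = list(A = a0, tau = tau0),
                             lower = c(A = 0, tau = .Machine$double.eps),
                             control = minpack.lm::nls.lm.control(maxiter = 50))
    stats::coef(fit)[["tau"]]
  }, error = function(e) NA_real_)
  if (is.finite(refined) && refined > 0) tau <- refined
  list(tau = tau, valid = TRUE, reason = "")
}

#' Compute the full parameter set of one detected event
#'
#' Assembles every per-event parameter: peak-to-peak amplitude, threshold
#' crossing (at `threshold_fraction` of the amplitude above baseline, on the
#' rising phase), time to peak measured from that crossing, FWHM and FW10,
#' baseline-subtracted area between the threshold crossing and the symmetric
#' downward crossing (trapezoidal rule with interpolated end points), maximal
#' rise and decay slopes with their times, and the exponential decay constant.
#' Individual sub-parameters that cannot be measured (level never re-crossed,
#' too-short segments, failed fit) are returned as `NA`; the record itself is
#' always returned.
#'
#' @inheritParams fit_decay_tau
#' @return A one-row `data.frame` with columns `apex_time`, `apex_value`,
#'   `polarity`, `prominence`, `baseline`, `amplitude_pk2pk`,
#'   `threshold_value`, `threshold_time`, `time_to_peak`, `fwhm`, `fw10`,
#'   `area`, `max_rise_slope`, `max_rise_time`, `max_decay_slope`,
#'   `max_decay_time`, `decay_tau`.
#' @export
compute_parameters <- function(series, event, config = detection_config(),
                               all_events = list(event)) {
  check_time_series(series)
  check_config(config)
  baseline <- estimate_baseline(series, event, all_events)
  w <- series$values * event$polarity
  b <- baseline * event$polarity
  amp <- w[event$apex_index] - b

  thr <- fractional_width(series, event, config$threshold_fraction,
                          baseline = baseline, all_events = all_events)
  f50 <- fractional_width(series, event, 0.5, baseline = baseline,
                          all_events = all_events)
  f10 <- fractional_width(series, event, 0.1, baseline = baseline,
                          all_events = all_events)
  rise <- max_slope(series, event, "rise")
  decay <- max_slope(series, event, "decay")
  tau <- fit_decay_tau(series, event, config, baseline = baseline,
                       all_events = all_events)

  level <- b + config$threshold_fraction * amp
  area <- NA_real_
  if (thr$valid) {
    # trapezoid of (w - b) between the two interpolated threshold crossings
    inside <- which(series$times > thr$t_rise & series$times < thr$t_fall)
    xs <- c(thr$t_rise, series$times[inside], thr$t_fall)
    ys <- c(level - b, w[inside] - b, level - b)
    area <- sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)
  }

  data.frame(
    apex_time = event$apex_time,
    apex_value = event$apex_value,
    polarity = event$polarity,
    prominence = event$prominence,
    baseline = baseline,
    amplitude_pk2pk = amp,
    threshold_value = event$polarity * level,
    threshold_time = thr$t_rise,
    time_to_peak = if (is.finite(thr$t_rise)) event$apex_time - thr$t_rise else NA_real_,
    fwhm = f50$width,
    fw10 = f10$width,
    area = area,
    max_rise_slope = rise$slope,
    max_rise_time = rise$time,
    max_decay_slope = decay$slope,
    max_decay_time = decay$time,
    decay_tau = tau$tau
  )
}

event_table_columns <- c(
  "apex_time", "apex_value", "polarity", "prominence", "baseline",
  "amplitude_pk2pk", "threshold_value", "threshold_time", "time_to_peak",
  "fwhm", "fw10", "area", "max_rise_slope", "max_rise_time",
  "max_decay_slope", "max_decay_time", "decay_tau")

empty_event_table <- function() {
  df <- as.data.frame(lapply(event_table_columns, function(x) numeric(0)))
  names(df) <- event_table_columns
  df
}

#' Detect and parameterize every event of a trace
#'
#' Runs [detect_peaks()] and [compute_parameters()] and assembles one row per
#' detected event, in temporal order.  The result is deterministic for a
#' fixed input and configuration.
#'
#' @inheritParams detect_peaks
#' @return An `event_table`: a `data.frame` with one row per event and one
#'   column per parameter (see [compute_parameters()]), carrying the source
#'   label, sampling step, time unit and configuration as attributes
#'   `label`, `dt`, `unit` and `config`.  Zero detections give a table with
#'   0 rows and the full set of columns.
#' @examples
#' tr <- simulate_train(train_spec(n_peaks = 3, seed = 1))
#' analyze_xt(tr$series, detection_config(sensitivity_percent = 30))
#' @export
analyze_xt <- function(series, config = detection_config()) {
  check_time_series(series)
  check_config(config)
  events <- detect_peaks(series, config)
  tab <- if (length(events)) {
    do.call(rbind, lapply(events, function(e)
      compute_parameters(series, e, config, all_events = events)))
  } else {
    empty_event_table()
  }
  rownames(tab) <- NULL
  structure(tab,
            label = series$label, dt = series$dt, unit = series$unit,
            config = config,
            class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d event(s)%s, dt = %g %s\n",
              nrow(x),
              if (nzchar(attr(x, "label") %||% "")) paste0(" in '", attr(x, "label"), "'") else "",
              attr(x, "dt"), attr(x, "unit")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
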