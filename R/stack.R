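# XYT analysis: an image stack is a bundle of per-pixel time series, each
# analyzed with the identical XT engine.  Pixels where nothing is detected
# are marked invalid and never interpolated.

#' Construct an image stack
#'
#' @param frames Numeric array `T x H x W` (frame, row, column).
#' @param dt Frame interval (time units), > 0.
#' @param pixel_pitch Optional physical size of one pixel (length units);
#'   when given, vector-map speeds are reported in length per time unit
#'   instead of pixels per time unit.
#' @param mask Optional `H x W` logical (or 0/1) region-of-interest matrix;
#'   out-of-mask pixels are skipped entirely.
#' @param unit Time unit tag (default `"ms"`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, dt, pixel_pitch = NULL, mask = NULL,
                        unit = "ms") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    pm_input_error("frames must be a T x H x W array")
  d <- dim(frames)
  if (d[1L] < 3L) pm_input_error("a stack needs at least 3 frames")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    pm_input_error("dt must be a single positive number")
  if (anyNA(frames) || any(!is.finite(frames)))
    pm_input_error("stack contains non-finite values")
  if (!is.null(mask)) {
    mask <- matrix(as.logical(mask), d[2L], d[3L])
    if (!any(mask)) pm_input_error("mask selects no pixels")
  }
  structure(
    list(frames = frames, dt = dt, pixel_pitch = pixel_pitch,
         mask = mask, unit = unit,
         n_frames = d[1L], height = d[2L], width = d[3L]),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frames of %d x %d, dt = %g %s%s\n",
              x$n_frames, x$height, x$width, x$dt, x$unit,
              if (is.null(x$pixel_pitch)) "" else
                sprintf(", pitch = %g", x$pixel_pitch)))
  invisible(x)
}

#' Activation time of an event
#'
#' The moment the signal "appears" at a pixel, used to build isochronal maps.
#' Two definitions are offered: `fraction_upstroke` (default) takes the
#' upstroke's crossing of `baseline + fraction * amplitude`, located by
#' linear interpolation (robust to noise at `fraction = 0.5`); `max_dvdt`
#' takes the time of the maximal rising slope.
#'
#' @inheritParams estimate_baseline
#' @param method `"fraction_upstroke"` or `"max_dvdt"`.
#' @param fraction Upstroke amplitude fraction (default 0.5).
#' @param baseline Optional precomputed baseline.
#' @return Activation time (time units), or `NA` if it cannot be located.
#' @export
activation_time <- function(series, event,
                            method = c("fraction_upstroke", "max_dvdt"),
                            fraction = 0.5, baseline = NULL,
                            all_events = list(event)) {
  method <- match.arg(method)
  if (method == "max_dvdt") {
    s <- max_slope(series, event, "rise")
    return(if (s$valid) s$time else NA_real_)
  }
  fw <- fractional_width(series, event, fraction, baseline = baseline,
                         all_events = all_events)
  fw$t_rise
}

# Gaussian spatial smoothing of each frame (separable kernel, replicated
# edges).  sigma in pixels.
smooth_spatial <- function(frames, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    # pad by edge replication, convolve along one dimension
    if (along_rows) m <- t(m)
    n <- ncol(m)
    idx <- pmin(pmax(seq_len(n + 2L * half) - half, 1L), n)
    padded <- m[, idx, drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (s in seq_along(k))
      out <- out + k[s] * padded[, s:(s + n - 1L), drop = FALSE]
    if (along_rows) t(out) else out
  }
  for (f in seq_len(dim(frames)[1L])) {
    m <- frames[f, , ]
    frames[f, , ] <- conv1(conv1(m, FALSE), TRUE)
  }
  frames
}

#' Analyze every pixel of an image stack
#'
#' Runs the XT detection and parameterization on every in-mask pixel trace.
#' Optional detection-stage pre-smoothing (spatial Gaussian and/or temporal
#' boxcar, both off by default) is applied to the whole stack before
#' analysis.  Pixels with zero detections are marked invalid and are never
#' interpolated.
#'
#' @param stack An [image_stack()].
#' @param config A [detection_config()]; its `spatial_sigma` and
#'   `temporal_window` fields control pre-smoothing.
#' @param parameters Character vector of per-event parameters to compute at
#'   every pixel, from: `amplitude_pk2pk`, `baseline`, `prominence`, `fwhm`,
#'   `fw10`, `area`, `time_to_peak`, `max_rise_slope`, `max_decay_slope`,
#'   `decay_tau`.  Restricting this list (e.g. dropping `decay_tau`, which
#'   requires a nonlinear fit per event) speeds up large stacks.
#' @param activation_method,activation_fraction Passed to
#'   [activation_time()], evaluated at every event.
#' @return An object of class `stack_analysis`: a list with `events` (long
#'   data.frame: `row`, `col`, `event`, `apex_time`, `activation`, one
#'   column per requested parameter), `valid` (H x W logical), `n_events`
#'   (H x W counts) and metadata (`dt`, `pixel_pitch`, `unit`, `config`).
#' @examples
#' wv <- simulate_wave(wave_spec(width = 8, height = 8, seed = 1))
#' an <- analyze_stack(wv$stack, detection_config(sensitivity_percent = 30))
#' all(an$valid)
#' @export
analyze_stack <- function(stack, config = detection_config(),
                          parameters = c("amplitude_pk2pk", "fwhm", "fw10"),
                          activation_method = c("fraction_upstroke", "max_dvdt"),
                          activation_fraction = 0.5) {
  if (!inherits(stack, "image_stack")) pm_input_error("expected an image_stack")
  check_config(config)
  activation_method <- match.arg(activation_method)
  known <- c("amplitude_pk2pk", "baseline", "prominence", "fwhm", "fw10",
             "area", "time_to_peak", "max_rise_slope", "max_decay_slope",
             "decay_tau")
  bad <- setdiff(parameters, known)
  if (length(bad))
    pm_input_error("unknown parameter(s): ", paste(bad, collapse = ", "),
                   "; available: ", paste(known, collapse = ", "))
  frames <- stack$frames
  if (!is.null(config$spatial_sigma) && config$spatial_sigma > 0)
    frames <- smooth_spatial(frames, config$spatial_sigma)
  if (!is.null(config$temporal_window) && config$temporal_window > 1) {
    flat <- matrix(frames, dim(frames)[1L])
    for (j in seq_len(ncol(flat))) flat[, j] <- boxcar_smooth(flat[, j], config$temporal_window)
    frames <- array(flat, dim(frames))
  }
  H <- stack$height; W <- stack$width
  mask <- stack$mask
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  if (!any(mask)) pm_input_error("mask selects no pixels")
  times <- (0:(stack$n_frames - 1L)) * stack$dt

  valid <- matrix(FALSE, H, W)
  n_events <- matrix(0L, H, W)
  rows <- vector("list", sum(mask))
  slot <- 0L
  full <- compute_px_columns(parameters)
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      if (!mask[i, j]) next
      ts <- structure(list(times = times, values = frames[, i, j],
                           dt = stack$dt, label = sprintf("px_%d_%d", i, j),
                           unit = stack$unit),
                      class = "time_series")
      events <- detect_peaks(ts, config)
      if (!length(events)) next
      valid[i, j] <- TRUE
      n_events[i, j] <- length(events)
      slot <- slot + 1L
      rows[[slot]] <- px_event_rows(ts, events, config, parameters,
                                    activation_method, activation_fraction,
                                    i, j)
    }
  }
  events_df <- if (slot) {
    df <- as.data.frame(do.call(rbind, rows[seq_len(slot)]))
    names(df) <- full
    df
  } else {
    df <- as.data.frame(matrix(numeric(0), 0L, length(full)))
    names(df) <- full
    df
  }
  structure(
    list(events = events_df, valid = valid, n_events = n_events,
         height = H, width = W, dt = stack$dt,
         pixel_pitch = stack$pixel_pitch, unit = stack$unit,
         mask = stack$mask, config = config, parameters = parameters,
         activation_method = activation_method,
         activation_fraction = activation_fraction),
    class = "stack_analysis")
}

compute_px_columns <- function(parameters) {
  c("row", "col", "event", "apex_time", "activation", parameters)
}

# numeric matrix, one row per event, for a single pixel trace
px_event_rows <- function(ts, events, config, parameters,
                          activation_method, activation_fraction, i, j) {
  out <- matrix(NA_real_, length(events), 5L + length(parameters))
  for (k in seq_along(events)) {
    e <- events[[k]]
    b <- estimate_baseline(ts, e, events)
    act <- activation_time(ts, e, activation_method, activation_fraction,
                           baseline = b, all_events = events)
    vals <- numeric(length(parameters))
    w_apex <- ts$values[e$apex_index] * e$polarity
    amp <- w_apex - b * e$polarity
    for (p in seq_along(parameters)) {
      vals[p] <- switch(parameters[p],
        amplitude_pk2pk = amp,
        baseline = b,
        prominence = e$prominence,
        fwhm = fractional_width(ts, e, 0.5, baseline = b,
                                all_events = events)$width,
        fw10 = fractional_width(ts, e, 0.1, baseline = b,
                                all_events = events)$width,
        area = compute_parameters(ts, e, config, all_events = events)$area,
        time_to_peak = {
          fw <- fractional_width(ts, e, config$threshold_fraction,
                                 baseline = b, all_events = events)
          if (is.finite(fw$t_rise)) e$apex_time - fw$t_rise else NA_real_
        },
        max_rise_slope = max_slope(ts, e, "rise")$slope,
        max_decay_slope = max_slope(ts, e, "decay")$slope,
        decay_tau = fit_decay_tau(ts, e, config, baseline = b,
                                  all_events = events)$tau)
    }
    out[k, ] <- c(i, j, k, e$apex_time, act, vals)
  }
  out
}

#' @export
print.stack_analysis <- function(x, ...) {
  cat(sprintf("<stack_analysis> %d x %d pixels, %d valid, %d event(s) total\n",
              x$height, x$width, sum(x$valid), nrow(x$events)))
  invisible(x)
}
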