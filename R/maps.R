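# Map assembly from a per-pixel stack analysis.
#
# Coordinate convention (documented in the CLI help as well): row-major,
# origin at the top-left pixel, x increases rightward (columns), y increases
# downward (rows).  Velocity vectors are reported in this frame; rendering
# flips the y axis only at display time.

#' Build an isochronal activation map
#'
#' Collects one activation time per valid pixel -- by default from the first
#' detected event -- and subtracts the earliest valid activation time, so the
#' earliest activated pixel has delay exactly 0.
#'
#' @param analysis A [stack_analysis()] from [analyze_stack()].
#' @param event_selector Which event to use at pixels with several detections:
#'   `"first"` (default), `"largest"` (largest amplitude; requires
#'   `amplitude_pk2pk` among the computed parameters), or an integer event
#'   index.
#' @return An object of class `activation_map`: list with `delay` (H x W,
#'   time units, `NA` at invalid pixels), `valid`, `t0` (the subtracted
#'   earliest activation time), `dt`, `pixel_pitch`, `unit`.
#' @export
build_isochronal_map <- function(analysis, event_selector = "first") {
  if (!inherits(analysis, "stack_analysis"))
    pm_input_error("expected a stack_analysis")
  ev <- analysis$events
  H <- analysis$height; W <- analysis$width
  delay <- matrix(NA_real_, H, W)
  if (nrow(ev)) {
    sel <- select_events(ev, event_selector)
    delay[cbind(sel$row, sel$col)] <- sel$activation
  }
  valid <- is.finite(delay)
  if (!any(valid)) pm_input_error("no valid pixels: nothing was detected")
  t0 <- min(delay[valid])
  delay <- delay - t0
  delay[!valid] <- NA_real_
  structure(
    list(delay = delay, valid = valid, t0 = t0, dt = analysis$dt,
         pixel_pitch = analysis$pixel_pitch, unit = analysis$unit,
         event_selector = event_selector),
    class = "activation_map")
}

select_events <- function(ev, event_selector) {
  if (identical(event_selector, "first")) {
    ev[ev$event == 1, , drop = FALSE]
  } else if (identical(event_selector, "largest")) {
    if (!"amplitude_pk2pk" %in% names(ev))
      pm_input_error("event_selector 'largest' needs amplitude_pk2pk among the computed parameters")
    key <- paste(ev$row, ev$col)
    picked <- unlist(lapply(split(seq_len(nrow(ev)), key), function(idx)
      idx[which.max(ev$amplitude_pk2pk[idx])]), use.names = FALSE)
    ev[picked, , drop = FALSE]
  } else if (is.numeric(event_selector)) {
    ev[ev$event == as.integer(event_selector), , drop = FALSE]
  } else {
    pm_input_error("event_selector must be 'first', 'largest' or an event index")
  }
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d x %d, %d valid, delays [0, %g] %s\n",
              nrow(x$delay), ncol(x$delay), sum(x$valid),
              max(x$delay[x$valid]), x$unit))
  invisible(x)
}

#' Build a conduction-velocity vector field from an activation map
#'
#' For every pixel, the activation times of the surrounding
#' `(2r+1) x (2r+1)` window are fitted with a plane
#' `t(x, y) = a + gx * x + gy * y` by least squares; the local velocity is
#' `g / |g|^2`, the standard construction that inverts the activation-time
#' gradient (the wave advances fastest where isochrones are far apart).
#' Windows are invalid when fewer than `min_valid_frac` of their pixels (or
#' fewer than 3) carry an activation time, when the gradient magnitude falls
#' below `min_gradient` (quasi-simultaneous activation, no finite velocity),
#' or when the RMS plane-fit residual exceeds `residual_cap`.
#'
#' @param map An [build_isochronal_map()] result (class `activation_map`).
#' @param window_radius Window half-size r in pixels (default 2, i.e. 5 x 5).
#' @param pitch Optional physical pixel size; overrides the map's
#'   `pixel_pitch`.  When available, `vx`, `vy`, `speed` are in length per
#'   time unit, otherwise in pixels per time unit.
#' @param min_valid_frac Minimum fraction of valid pixels per window
#'   (default 0.6).
#' @param min_gradient Gradient-magnitude floor in time units per pixel
#'   (default 1e-9); windows flatter than this are invalid.
#' @param residual_cap Maximum RMS residual of the plane fit, in time units
#'   (default `Inf`).
#' @return An object of class `vector_field`: list of H x W matrices `vx`,
#'   `vy`, `speed`, `residual` and logical `valid`, plus `units` (speed
#'   denominator/numerator tags) and the fit settings.
#' @export
build_vector_map <- function(map, window_radius = 2, pitch = NULL,
                             min_valid_frac = 0.6, min_gradient = 1e-9,
                             residual_cap = Inf) {
  if (!inherits(map, "activation_map")) pm_input_error("expected an activation_map")
  r <- as.integer(window_radius)
  if (r < 1L) pm_input_error("window_radius must be >= 1")
  if (is.null(pitch)) pitch <- map$pixel_pitch
  D <- map$delay
  H <- nrow(D); W <- ncol(D)
  vx <- vy <- speed <- resid <- matrix(NA_real_, H, W)
  valid <- matrix(FALSE, H, W)
  full_n <- (2L * r + 1L)^2
  min_n <- max(3L, ceiling(min_valid_frac * full_n))
  for (j in seq_len(W)) {
    cols <- max(1L, j - r):min(W, j + r)
    for (i in seq_len(H)) {
      rows <- max(1L, i - r):min(H, i + r)
      sub <- D[rows, cols, drop = FALSE]
      ok <- is.finite(sub)
      n_ok <- sum(ok)
      if (n_ok < min_n) next
      dx <- rep(cols - j, each = length(rows))[ok]   # x = columns
      dy <- rep(rows - i, times = length(cols))[ok]  # y = rows
      tv <- sub[ok]
      X <- cbind(1, dx, dy)
      fit <- tryCatch(stats::lm.fit(X, tv), error = function(e) NULL)
      if (is.null(fit) || any(is.na(fit$coefficients))) next
      g <- fit$coefficients[2:3]
      g2 <- sum(g^2)
      if (sqrt(g2) < min_gradient) next
      rms <- sqrt(mean(fit$residuals^2))
      if (rms > residual_cap) next
      v <- g / g2                      # pixels per time unit
      if (!is.null(pitch)) v <- v * pitch
      vx[i, j] <- v[1L]; vy[i, j] <- v[2L]
      speed[i, j] <- sqrt(sum(v^2))
      resid[i, j] <- rms
      valid[i, j] <- TRUE
    }
  }
  structure(
    list(vx = vx, vy = vy, speed = speed, residual = resid, valid = valid,
         window_radius = r, pitch = pitch,
         units = if (is.null(pitch)) paste0("px/", map$unit)
                 else paste0("length/", map$unit),
         min_valid_frac = min_valid_frac, min_gradient = min_gradient,
         residual_cap = residual_cap),
    class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  ok <- x$valid
  cat(sprintf("<vector_field> %d x %d windows (radius %d), %d valid, median speed %g %s\n",
              nrow(x$speed), ncol(x$speed), x$window_radius, sum(ok),
              if (any(ok)) stats::median(x$speed[ok]) else NA, x$units))
  invisible(x)
}

#' Build a per-pixel parameter map
#'
#' For every valid pixel, the arithmetic mean of the chosen parameter over
#' that pixel's detected events, skipping events where the parameter could
#' not be measured.  Pixels whose only events carry invalid (NA) values are
#' marked invalid.
#'
#' @param analysis A [stack_analysis()].
#' @param parameter Name of a parameter computed by [analyze_stack()] (must
#'   be among its `parameters`).
#' @return An object of class `parameter_map`: list with `value` (H x W),
#'   `n_events` (events averaged per pixel), `valid`, `parameter`, `unit`.
#' @export
build_parameter_map <- function(analysis, parameter) {
  if (!inherits(analysis, "stack_analysis"))
    pm_input_error("expected a stack_analysis")
  if (!parameter %in% names(analysis$events) ||
      parameter %in% c("row", "col", "event", "apex_time", "activation"))
    pm_input_error("parameter '", parameter, "' was not computed; available: ",
                   paste(analysis$parameters, collapse = ", "))
  ev <- analysis$events
  H <- analysis$height; W <- analysis$width
  value <- matrix(NA_real_, H, W)
  n_used <- matrix(0L, H, W)
  ok <- is.finite(ev[[parameter]])
  if (any(ok)) {
    sub <- ev[ok, c("row", "col", parameter)]
    lin <- (sub$col - 1L) * H + sub$row
    sums <- rowsum(sub[[parameter]], lin)
    counts <- rowsum(rep(1L, nrow(sub)), lin)
    lin_u <- as.integer(rownames(sums))
    value[lin_u] <- sums / counts
    n_used[lin_u] <- counts
  }
  structure(
    list(value = value, n_events = n_used, valid = is.finite(value),
         parameter = parameter, unit = analysis$unit),
    class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  ok <- x$valid
  cat(sprintf("<parameter_map> %s: %d x %d, %d valid, range [%g, %g]\n",
              x$parameter, nrow(x$value), ncol(x$value), sum(ok),
              if (any(ok)) min(x$value[ok]) else NA,
              if (any(ok)) max(x$value[ok]) else NA))
  invisible(x)
}

# matrix payload of any map-like object
map_values <- function(map) {
  if (inherits(map, "activation_map")) map$delay
  else if (inherits(map, "parameter_map")) map$value
  else if (inherits(map, "vector_field")) map$speed
  else if (is.matrix(map)) map
  else pm_input_error("not a map object")
}
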