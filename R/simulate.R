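# Synthetic signal generator with analytic ground truth.
#
# Two waveform families cover everything the analyzer measures:
#   * transient  -- double exponential A*(exp(-t/tau_decay) - exp(-t/tau_rise)),
#     normalized so its maximum is exactly A; the shape of a calcium transient
#     or contraction twitch.
#   * ap_plateau -- sigmoidal upstroke (time constant tau_rise), sustained
#     plateau, exponential repolarization (tau_decay); an action-potential-like
#     waveform whose FWHM/FW10 play the role of APD50/APD90.
# Ground-truth widths are obtained on the noiseless continuous waveform by
# root-finding, never from the sampled signal.

run_seeded <- function(seed, code) {
  if (is.null(seed)) pm_input_error("a seed is mandatory for simulation")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Describe a synthetic peak waveform
#'
#' @param model `"transient"` (double-exponential, e.g. a calcium transient)
#'   or `"ap_plateau"` (sigmoid upstroke, plateau, exponential repolarization).
#' @param amplitude Peak amplitude in signal units (for `transient` the exact
#'   maximum; for `ap_plateau` the plateau level, the realized maximum is
#'   marginally below it).
#' @param tau_rise Rise time constant (time units).  Must be smaller than
#'   `tau_decay` for the transient model.
#' @param tau_decay Decay time constant (time units).
#' @param plateau Plateau duration (time units), `ap_plateau` only.
#' @param polarity `"positive"` or `"negative"` (waveform negated).
#' @return An object of class `peak_shape`.
#' @examples
#' sh <- peak_shape("transient", amplitude = 1, tau_rise = 5, tau_decay = 50)
#' shape_ground_truth(sh)$t_apex  # closed-form apex of the double exponential
#' @export
peak_shape <- function(model = c("transient", "ap_plateau"),
                       amplitude = 1, tau_rise = 5, tau_decay = 50,
                       plateau = 0,
                       polarity = c("positive", "negative")) {
  model <- match.arg(model)
  polarity <- match.arg(polarity)
  if (tau_rise <= 0 || tau_decay <= 0)
    pm_input_error("time constants must be positive")
  if (model == "transient" && tau_rise >= tau_decay)
    pm_input_error("transient model requires tau_rise < tau_decay")
  if (plateau < 0) pm_input_error("plateau must be >= 0")
  structure(
    list(model = model, amplitude = amplitude, tau_rise = tau_rise,
         tau_decay = tau_decay, plateau = plateau, polarity = polarity),
    class = "peak_shape")
}

#' Evaluate a waveform at given times
#'
#' Times are relative to the event onset (`t = 0`).  The transient model is
#' exactly zero for `t <= 0`; the plateau model's sigmoid upstroke is centred
#' at `5 * tau_rise` so its pedestal at `t = 0` is below 1% of amplitude.
#'
#' @param shape A [peak_shape()].
#' @param t Numeric vector of times.
#' @return Signal values (negated for negative polarity).
#' @export
shape_value <- function(shape, t) {
  A <- shape$amplitude
  tr <- shape$tau_rise
  td <- shape$tau_decay
  v <- if (shape$model == "transient") {
    tp <- tr * td / (td - tr) * log(td / tr)
    norm <- exp(-tp / td) - exp(-tp / tr)
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- A * (exp(-t[pos] / td) - exp(-t[pos] / tr)) / norm
    out
  } else {
    t0 <- 5 * tr
    t_dec <- t0 + shape$plateau
    up <- stats::plogis((t - t0) / tr)
    dec <- ifelse(t > t_dec, exp(-(t - t_dec) / td), 1)
    A * up * dec
  }
  if (shape$polarity == "negative") -v else v
}

shape_horizon <- function(shape) {
  if (shape$model == "transient") {
    tp <- shape$tau_rise * shape$tau_decay /
      (shape$tau_decay - shape$tau_rise) * log(shape$tau_decay / shape$tau_rise)
    tp + 15 * shape$tau_decay
  } else {
    5 * shape$tau_rise + shape$plateau + 15 * shape$tau_decay
  }
}

#' Analytic ground truth of a waveform
#'
#' Apex time and value (closed form for the transient, numerical optimization
#' for the plateau model) and widths at amplitude fractions obtained by
#' root-finding on the continuous waveform.
#'
#' @param shape A [peak_shape()].
#' @param fractions Amplitude fractions at which widths are reported
#'   (defaults cover FWHM, FW10 and the 1% footprint used to flag
#'   overlapping peaks in a train).
#' @return A list with `t_apex`, `peak_value` (absolute value of the
#'   extremum), `tau` (= `tau_decay`), and `widths`, a data.frame with
#'   columns `fraction`, `t_rise`, `t_fall`, `width` (times relative to
#'   onset).
#' @export
shape_ground_truth <- function(shape, fractions = c(0.5, 0.1, 0.01)) {
  f_abs <- function(t) abs(shape_value(shape, t))
  horizon <- shape_horizon(shape)
  if (shape$model == "transient") {
    tr <- shape$tau_rise; td <- shape$tau_decay
    t_apex <- tr * td / (td - tr) * log(td / tr)
    peak <- f_abs(t_apex)
  } else {
    opt <- stats::optimize(f_abs, c(0, horizon), maximum = TRUE,
                           tol = 1e-10)
    t_apex <- opt$maximum
    peak <- opt$objective
  }
  lower <- if (shape$model == "transient") 0 else 5 * shape$tau_rise - 12 * shape$tau_rise
  widths <- do.call(rbind, lapply(fractions, function(fr) {
    level <- fr * peak
    t_rise <- stats::uniroot(function(t) f_abs(t) - level,
                             c(lower, t_apex), tol = 1e-10)$root
    t_fall <- stats::uniroot(function(t) f_abs(t) - level,
                             c(t_apex, horizon), tol = 1e-10)$root
    data.frame(fraction = fr, t_rise = t_rise, t_fall = t_fall,
               width = t_fall - t_rise)
  }))
  list(t_apex = t_apex, peak_value = peak, tau = shape$tau_decay,
       widths = widths)
}

#' Specify a synthetic peak train
#'
#' @param shape A [peak_shape()].
#' @param n_peaks Number of peaks.
#' @param period Inter-peak interval (time units).
#' @param timing_jitter_sd SD of Gaussian jitter added to each onset.
#' @param amplitude_jitter_sd SD of Gaussian jitter added to each amplitude
#'   (signal units).
#' @param baseline_level Constant baseline offset.
#' @param drift_slope Linear baseline drift (signal units per time unit).
#' @param noise_sd SD of iid Gaussian sample noise.
#' @param dt Sampling interval.
#' @param duration Total duration; must be at least `n_peaks * period`
#'   (the default).
#' @param t_start Onset of the first peak (default `period / 4`).
#' @param seed Mandatory RNG seed; the output is bit-identical for a fixed
#'   spec and seed.
#' @param unit,label Passed to the generated [time_series()].
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(shape = peak_shape(), n_peaks = 10, period = 500,
                       timing_jitter_sd = 0, amplitude_jitter_sd = 0,
                       baseline_level = 0, drift_slope = 0, noise_sd = 0,
                       dt = 1, duration = NULL, t_start = NULL,
                       seed = NULL, unit = "ms", label = "simulated") {
  if (!inherits(shape, "peak_shape")) pm_input_error("shape must be a peak_shape")
  if (n_peaks < 1) pm_input_error("n_peaks must be >= 1")
  if (period <= 0 || dt <= 0) pm_input_error("period and dt must be positive")
  if (is.null(duration)) duration <- n_peaks * period
  if (duration < n_peaks * period)
    pm_input_error("duration must be >= n_peaks * period")
  if (is.null(t_start)) t_start <- period / 4
  if (is.null(seed)) pm_input_error("a seed is mandatory in train_spec")
  structure(
    list(shape = shape, n_peaks = as.integer(n_peaks), period = period,
         timing_jitter_sd = timing_jitter_sd,
         amplitude_jitter_sd = amplitude_jitter_sd,
         baseline_level = baseline_level, drift_slope = drift_slope,
         noise_sd = noise_sd, dt = dt, duration = duration,
         t_start = t_start, seed = as.integer(seed), unit = unit,
         label = label),
    class = "train_spec")
}

#' Simulate a peak train with known ground truth
#'
#' Generates a uniformly sampled trace of `n_peaks` waveforms on a (possibly
#' drifting) baseline with optional timing jitter, amplitude jitter and iid
#' Gaussian noise, together with a ground-truth table holding the analytic
#' apex time, amplitude, FWHM, FW10 and decay constant of every event.
#' Widths are computed on the noiseless continuous waveform by root-finding,
#' so they are independent of the sampling step.
#'
#' @param spec A [train_spec()].
#' @return A list with `series` (a [time_series()]), `truth` (a data.frame
#'   with columns `onset`, `apex_time`, `amplitude`, `fwhm`, `fw10`,
#'   `decay_tau`, `polarity`) and `spec`.  If consecutive peaks overlap at
#'   the 1% level (period shorter than the waveform's 1% footprint) the truth
#'   table carries the attribute `overlap_warning = TRUE`.
#' @examples
#' tr <- simulate_train(train_spec(n_peaks = 3, seed = 42))
#' tr$truth$apex_time
#' @export
simulate_train <- function(spec) {
  if (!inherits(spec, "train_spec")) pm_input_error("spec must be a train_spec")
  gt <- shape_ground_truth(spec$shape)
  run_seeded(spec$seed, {
    times <- seq(0, spec$duration, by = spec$dt)
    onset <- spec$t_start + (seq_len(spec$n_peaks) - 1L) * spec$period +
      if (spec$timing_jitter_sd > 0)
        stats::rnorm(spec$n_peaks, 0, spec$timing_jitter_sd) else
        numeric(spec$n_peaks)
    amp <- spec$shape$amplitude +
      if (spec$amplitude_jitter_sd > 0)
        stats::rnorm(spec$n_peaks, 0, spec$amplitude_jitter_sd) else
        numeric(spec$n_peaks)
    v <- spec$baseline_level + spec$drift_slope * times
    for (k in seq_len(spec$n_peaks)) {
      scale <- amp[k] / spec$shape$amplitude
      v <- v + scale * shape_value(spec$shape, times - onset[k])
    }
    if (spec$noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, spec$noise_sd)
    series <- time_series(times, v, label = spec$label, unit = spec$unit)
    w <- gt$widths
    truth <- data.frame(
      onset = onset,
      apex_time = onset + gt$t_apex,
      amplitude = abs(amp) * gt$peak_value / abs(spec$shape$amplitude),
      fwhm = w$width[w$fraction == 0.5],
      fw10 = w$width[w$fraction == 0.1],
      decay_tau = gt$tau,
      polarity = if (spec$shape$polarity == "negative") -1L else 1L)
    footprint <- w$width[w$fraction == 0.01]
    attr(truth, "overlap_warning") <- footprint > spec$period
    list(series = series, truth = truth, spec = spec)
  })
}

#' Specify a propagating-wave video
#'
#' Every pixel carries the same waveform, delayed by the analytic activation
#' time of the chosen geometry: `planar` -- a plane wavefront travelling at
#' `speed` pixels/frame along `angle_deg` (0 = rightward, measured towards
#' increasing row index, i.e. clockwise on screen); `radial` -- a circular
#' wavefront expanding from `origin` (x, y in 0-based pixel coordinates).
#'
#' @param shape A [peak_shape()].
#' @param geometry `"planar"` or `"radial"`.
#' @param angle_deg Propagation direction in degrees (planar only).
#' @param origin Numeric `c(x, y)` wave origin in 0-based pixels (radial only).
#' @param speed Wave speed in pixels per frame (> 0).
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames; default covers the full activation span
#'   plus one waveform duration.
#' @param dt Frame interval (time units).
#' @param noise_sd SD of iid Gaussian noise per sample.
#' @param t_lead Time before the earliest activation (default `3 * dt`).
#' @param param_gradients Optional named list of linear parameter gradients
#'   along x, e.g. `list(tau_decay = c(40, 80))`: column 0 uses the first
#'   value, the last column the second.  Supported names: `amplitude`,
#'   `tau_rise`, `tau_decay`, `plateau`.
#' @param pixel_pitch Optional physical pixel size, carried into the stack.
#' @param seed Mandatory RNG seed.
#' @param unit Time unit tag.
#' @return An object of class `wave_spec`.
#' @export
wave_spec <- function(shape = peak_shape(), geometry = c("planar", "radial"),
                      angle_deg = 0, origin = c(0, 0), speed = 1,
                      width = 64, height = 64, n_frames = NULL, dt = 1,
                      noise_sd = 0, t_lead = NULL, param_gradients = NULL,
                      pixel_pitch = NULL, seed = NULL, unit = "ms") {
  geometry <- match.arg(geometry)
  if (!inherits(shape, "peak_shape")) pm_input_error("shape must be a peak_shape")
  if (speed <= 0) pm_input_error("speed must be positive (pixels per frame)")
  if (width < 2 || height < 2) pm_input_error("frame must be at least 2x2")
  if (dt <= 0) pm_input_error("dt must be positive")
  if (is.null(t_lead)) t_lead <- 3 * dt
  if (!is.null(param_gradients)) {
    ok <- c("amplitude", "tau_rise", "tau_decay", "plateau")
    if (is.null(names(param_gradients)) || !all(names(param_gradients) %in% ok))
      pm_input_error("param_gradients names must be among: ",
                     paste(ok, collapse = ", "))
  }
  if (is.null(seed)) pm_input_error("a seed is mandatory in wave_spec")
  structure(
    list(shape = shape, geometry = geometry, angle_deg = angle_deg,
         origin = as.numeric(origin), speed = speed,
         width = as.integer(width), height = as.integer(height),
         n_frames = n_frames, dt = dt, noise_sd = noise_sd,
         t_lead = t_lead, param_gradients = param_gradients,
         pixel_pitch = pixel_pitch, seed = as.integer(seed), unit = unit),
    class = "wave_spec")
}

wave_activation_truth <- function(spec) {
  x <- matrix(rep(0:(spec$width - 1L), each = spec$height),
              spec$height, spec$width)
  y <- matrix(rep(0:(spec$height - 1L), times = spec$width),
              spec$height, spec$width)
  if (spec$geometry == "planar") {
    th <- spec$angle_deg * pi / 180
    proj <- x * cos(th) + y * sin(th)
    t_act <- spec$t_lead + (proj - min(proj)) / spec$speed * spec$dt
  } else {
    d <- sqrt((x - spec$origin[1L])^2 + (y - spec$origin[2L])^2)
    t_act <- spec$t_lead + d / spec$speed * spec$dt
  }
  t_act
}

column_shape <- function(spec, col_index) {
  # col_index 0-based; interpolate any gradient parameters along x
  sh <- spec$shape
  if (is.null(spec$param_gradients)) return(sh)
  frac <- if (spec$width > 1L) col_index / (spec$width - 1L) else 0
  for (nm in names(spec$param_gradients)) {
    g <- spec$param_gradients[[nm]]
    sh[[nm]] <- g[1L] + frac * (g[2L] - g[1L])
  }
  do.call(peak_shape, sh[c("model", "amplitude", "tau_rise", "tau_decay",
                           "plateau", "polarity")])
}

#' Simulate a propagating-wave image stack with known ground truth
#'
#' Each pixel's trace is the waveform evaluated at `t - t_act(x, y)` plus
#' optional iid Gaussian noise.  The returned ground truth bundles the
#' analytic activation-time map, the constant (or gradient-specified)
#' per-pixel parameter maps, and the analytic propagation velocity.
#'
#' @param spec A [wave_spec()].
#' @return A list with `stack` (an [image_stack()]), `truth` (list with
#'   `t_act` H x W matrix, `speed` in px/frame, `angle_deg` or `origin`,
#'   and `params`, per-pixel matrices for `amplitude`, `fwhm`, `fw10`,
#'   `decay_tau`), and `spec`.
#' @examples
#' wv <- simulate_wave(wave_spec(speed = 1, width = 16, height = 16, seed = 3))
#' dim(wv$stack$frames)
#' @export
simulate_wave <- function(spec) {
  if (!inherits(spec, "wave_spec")) pm_input_error("spec must be a wave_spec")
  t_act <- wave_activation_truth(spec)
  span_frames <- (max(t_act) - min(t_act)) / spec$dt
  if (span_frames < 2)
    pm_input_error("propagation unresolvable: activation spans fewer than ",
                   "2 frames across the image (speed too high)")
  # per-column shapes and their analytic ground truth
  shapes <- lapply(0:(spec$width - 1L), function(j) column_shape(spec, j))
  gts <- if (is.null(spec$param_gradients)) {
    g <- shape_ground_truth(shapes[[1L]])
    rep(list(g), spec$width)
  } else {
    lapply(shapes, shape_ground_truth)
  }
  t_apex1 <- gts[[1L]]$t_apex
  if (t_apex1 / spec$dt < 3)
    warning("upstroke sampled by fewer than 3 frames; activation times will be coarse")
  n_frames <- spec$n_frames
  if (is.null(n_frames)) {
    horizon <- max(vapply(gts, function(g)
      g$widths$t_fall[g$widths$fraction == 0.01], numeric(1L)))
    n_frames <- ceiling((max(t_act) + horizon) / spec$dt) + 1L
  }
  n_frames <- as.integer(n_frames)
  if (n_frames < 3L) pm_input_error("n_frames must be >= 3")
  run_seeded(spec$seed, {
    tvec <- (0:(n_frames - 1L)) * spec$dt
    frames <- array(0, dim = c(n_frames, spec$height, spec$width))
    for (j in seq_len(spec$width)) {
      sh <- shapes[[j]]
      for (i in seq_len(spec$height)) {
        frames[, i, j] <- shape_value(sh, tvec - t_act[i, j])
      }
    }
    if (spec$noise_sd > 0)
      frames <- frames + stats::rnorm(length(frames), 0, spec$noise_sd)
    stack <- image_stack(frames, dt = spec$dt, pixel_pitch = spec$pixel_pitch,
                         unit = spec$unit)
    pick <- function(fr) matrix(
      rep(vapply(gts, function(g) g$widths$width[g$widths$fraction == fr],
                 numeric(1L)), each = spec$height),
      spec$height, spec$width)
    params <- list(
      amplitude = matrix(rep(vapply(gts, `[[`, numeric(1L), "peak_value"),
                             each = spec$height), spec$height, spec$width),
      fwhm = pick(0.5),
      fw10 = pick(0.1),
      decay_tau = matrix(rep(vapply(gts, `[[`, numeric(1L), "tau"),
                             each = spec$height), spec$height, spec$width))
    truth <- list(t_act = t_act, speed = spec$speed,
                  angle_deg = spec$angle_deg, origin = spec$origin,
                  geometry = spec$geometry, params = params)
    list(stack = stack, truth = truth, spec = spec)
  })
}
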