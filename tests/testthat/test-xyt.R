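cfg30 <- detection_config(sensitivity_percent = 30)

uniform_stack <- function(h = 6, w = 8, seed = 4) {
  tr <- simulate_train(train_spec(n_peaks = 1, period = 400, seed = seed))
  n <- length(tr$series$values)
  frames <- array(rep(tr$series$values, times = h * w), dim = c(n, h, w))
  list(stack = image_stack(frames, dt = tr$series$dt), trace = tr)
}

test_that("a uniform stack gives identical parameters at every pixel", {
  u <- uniform_stack()
  an <- analyze_stack(u$stack, cfg30, parameters = c("amplitude_pk2pk", "fwhm"))
  expect_true(all(an$valid))
  expect_true(all(an$n_events == 1L))
  pm <- build_parameter_map(an, "fwhm")
  expect_true(all(pm$valid))
  expect_equal(max(pm$value) - min(pm$value), 0, tolerance = 1e-12)
  # spatially constant and equal to the single-trace value
  ref <- analyze_xt(u$trace$series, cfg30)
  expect_equal(pm$value[1, 1], ref$fwhm[1], tolerance = 1e-9)
  expect_true(all(pm$n_events == 1L))
})

test_that("pure noise at sensitivity 100 yields no valid pixels", {
  set.seed(1)
  frames <- array(rnorm(40 * 5 * 5), dim = c(40, 5, 5))
  an <- analyze_stack(image_stack(frames, dt = 1), detection_config(100))
  expect_false(any(an$valid))
  expect_error(build_isochronal_map(an), class = "peakmap_input_error")
})

test_that("planar-wave apex times shift linearly along the propagation axis", {
  wv <- simulate_wave(wave_spec(speed = 1, angle_deg = 0, width = 30,
                                height = 6, dt = 1, seed = 2))
  an <- analyze_stack(wv$stack, cfg30, parameters = "amplitude_pk2pk")
  ev1 <- an$events[an$events$event == 1, ]
  for (r in c(1L, 4L)) {
    rowev <- ev1[ev1$row == r, ]
    rowev <- rowev[order(rowev$col), ]
    steps <- diff(rowev$apex_time)
    expect_equal(steps, rep(1, length(steps)), tolerance = 0.25)
  }
})

test_that("a tau gradient along x is recovered by the decay-constant map", {
  wg <- simulate_wave(wave_spec(peak_shape(tau_rise = 3, tau_decay = 40),
                                speed = 1, width = 24, height = 8, dt = 1,
                                seed = 4,
                                param_gradients = list(tau_decay = c(30, 60))))
  an <- analyze_stack(wg$stack, cfg30, parameters = "decay_tau")
  pm <- build_parameter_map(an, "decay_tau")
  err <- abs(pm$value - wg$truth$params$decay_tau) / wg$truth$params$decay_tau
  expect_lt(stats::median(err, na.rm = TRUE), 0.05)
  # the map increases along x like the generating gradient
  expect_gt(stats::cor(as.vector(pm$value),
                       as.vector(wg$truth$params$decay_tau)), 0.99)
})

test_that("activation time of an ideal step is the step time for both methods", {
  t0_idx <- 41L                                     # first high sample
  v <- c(rep(0, t0_idx - 1L), rep(1, 40), rep(0, 10))
  ts <- as_time_series(v, dt = 1)
  ev <- detect_peaks(ts, cfg30)
  t_step <- ts$times[t0_idx]
  for (m in c("fraction_upstroke", "max_dvdt")) {
    at <- activation_time(ts, ev[[1L]], method = m, all_events = ev)
    expect_lte(abs(at - t_step), 1, label = m)      # within one dt
  }
})

test_that("delaying a trace shifts the activation time by exactly that delay", {
  tr <- simulate_train(train_spec(n_peaks = 1, period = 400, seed = 13))
  v <- tr$series$values
  k <- 17L
  delayed <- c(rep(v[1L], k), v[seq_len(length(v) - k)])
  ts0 <- as_time_series(v, dt = 1); ts1 <- as_time_series(delayed, dt = 1)
  e0 <- detect_peaks(ts0, cfg30); e1 <- detect_peaks(ts1, cfg30)
  for (m in c("fraction_upstroke", "max_dvdt")) {
    a0 <- activation_time(ts0, e0[[1L]], method = m, all_events = e0)
    a1 <- activation_time(ts1, e1[[1L]], method = m, all_events = e1)
    expect_equal(a1 - a0, k, tolerance = 1e-9, label = m)
  }
})

test_that("simultaneous activation gives an all-zero delay map and no vectors", {
  u <- uniform_stack(h = 7, w = 7)
  an <- analyze_stack(u$stack, cfg30, parameters = "amplitude_pk2pk")
  iso <- build_isochronal_map(an)
  expect_true(all(iso$delay == 0))
  vf <- build_vector_map(iso, window_radius = 2)
  expect_false(any(vf$valid))   # no finite velocity on a flat map
})

test_that("planar-wave vectors recover speed and direction", {
  th <- 215; v_true <- 0.5
  wv <- simulate_wave(wave_spec(speed = v_true, angle_deg = th, width = 24,
                                height = 24, dt = 1, seed = 31))
  an <- analyze_stack(wv$stack, cfg30, parameters = "amplitude_pk2pk")
  vf <- build_vector_map(build_isochronal_map(an), window_radius = 2)
  ok <- vf$valid
  expect_gt(sum(ok), 0.8 * 24 * 24 * 0.5)
  sp_err <- abs(vf$speed[ok] - v_true) / v_true
  ang <- atan2(vf$vy[ok], vf$vx[ok]) * 180 / pi
  ang_err <- abs(((ang - th + 180) %% 360) - 180)
  expect_lt(stats::median(sp_err), 0.05)
  expect_lt(stats::median(ang_err), 5)
})

test_that("physical pitch rescales vector speeds", {
  wv <- simulate_wave(wave_spec(speed = 1, angle_deg = 0, width = 16,
                                height = 8, dt = 1, seed = 6))
  an <- analyze_stack(wv$stack, cfg30, parameters = "amplitude_pk2pk")
  iso <- build_isochronal_map(an)
  vf_px <- build_vector_map(iso, window_radius = 2)
  vf_mm <- build_vector_map(iso, window_radius = 2, pitch = 0.25)
  ok <- vf_px$valid & vf_mm$valid
  expect_equal(vf_mm$speed[ok], 0.25 * vf_px$speed[ok], tolerance = 1e-12)
})

test_that("parameter maps average the events of each pixel", {
  # one pixel trace carrying two Gaussian events whose FWHM are 50 and 70 ms
  s1 <- 50 / (2 * sqrt(2 * log(2))); s2 <- 70 / (2 * sqrt(2 * log(2)))
  t <- seq(0, 1000, by = 1)
  v <- exp(-((t - 250) / s1)^2 / 2) + exp(-((t - 700) / s2)^2 / 2)
  frames <- array(rep(v, times = 4), dim = c(length(v), 2, 2))
  an <- analyze_stack(image_stack(frames, dt = 1), detection_config(20),
                      parameters = "fwhm")
  expect_true(all(an$n_events == 2L))
  pm <- build_parameter_map(an, "fwhm")
  ev <- an$events[an$events$row == 1 & an$events$col == 1, ]
  expect_equal(pm$value[1, 1], mean(ev$fwhm), tolerance = 1e-12)
  expect_equal(pm$value[1, 1], 60, tolerance = 0.01)
  expect_true(all(pm$n_events == 2L))
})

test_that("no output assigns values outside the mask", {
  u <- uniform_stack(h = 8, w = 8)
  mask <- matrix(FALSE, 8, 8); mask[3:6, 2:5] <- TRUE
  st <- image_stack(u$stack$frames, dt = 1, mask = mask)
  an <- analyze_stack(st, cfg30, parameters = "fwhm")
  expect_true(all(!an$valid[!mask]))
  pm <- build_parameter_map(an, "fwhm")
  expect_true(all(is.na(pm$value[!mask])))
  iso <- build_isochronal_map(an)
  expect_true(all(is.na(iso$delay[!mask])))
})

test_that("stack analysis is deterministic", {
  wv <- simulate_wave(wave_spec(speed = 1, width = 10, height = 6,
                                noise_sd = 0.02, seed = 5))
  a1 <- analyze_stack(wv$stack, cfg30, parameters = c("fwhm", "amplitude_pk2pk"))
  a2 <- analyze_stack(wv$stack, cfg30, parameters = c("fwhm", "amplitude_pk2pk"))
  expect_identical(a1$events, a2$events)
  expect_identical(build_isochronal_map(a1)$delay, build_isochronal_map(a2)$delay)
})

test_that("temporal downsampling changes recovered speeds only mildly", {
  sh <- peak_shape(tau_rise = 6, tau_decay = 40)
  wv <- simulate_wave(wave_spec(sh, speed = 0.4, angle_deg = 0, width = 20,
                                height = 10, dt = 1, seed = 14))
  full <- wv$stack$frames
  half <- full[seq(1, dim(full)[1L], by = 2), , ]
  sp_of <- function(frames, dt) {
    an <- analyze_stack(image_stack(frames, dt = dt), cfg30,
                        parameters = "amplitude_pk2pk")
    vf <- build_vector_map(build_isochronal_map(an), window_radius = 2)
    stats::median(vf$speed[vf$valid])
  }
  s1 <- sp_of(full, 1)
  s2 <- sp_of(half, 2)   # physical time units preserved
  expect_lt(abs(s2 - s1) / s1, 0.05)
})
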