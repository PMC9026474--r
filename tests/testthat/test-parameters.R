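cfg <- detection_config(sensitivity_percent = 20)

first_event <- function(series, config = cfg) {
  ev <- detect_peaks(series, config)
  expect_gt(length(ev), 0L)
  list(series = series, events = ev, e = ev[[1L]])
}

test_that("baseline recovers flat levels and additive offsets", {
  b0 <- gaussian_bump_series(center = 120, sigma = 10, dt = 1, span = 100)
  x <- first_event(b0)
  expect_equal(estimate_baseline(x$series, x$e, x$events), 0, tolerance = 1e-3)
  b7 <- gaussian_bump_series(center = 120, sigma = 10, dt = 1, span = 100,
                             baseline = 7)
  y <- first_event(b7)
  expect_equal(estimate_baseline(y$series, y$e, y$events), 7, tolerance = 1e-3)
})

test_that("baselines of a train on a linear drift track the drift", {
  m <- 5e-4   # units per ms; total drift stays below the peak amplitude
  tr <- simulate_train(train_spec(n_peaks = 5, period = 400, drift_slope = m,
                                  seed = 2))
  ev <- detect_peaks(tr$series, detection_config(10))
  expect_length(ev, 5L)
  b <- vapply(seq_along(ev), function(k)
    estimate_baseline(tr$series, ev[[k]], ev), numeric(1L))
  incr <- diff(b)
  expect_equal(incr, rep(m * 400, 4L), tolerance = m * 400 * 0.35)
})

test_that("fractional widths of a rectangular pulse equal its width", {
  w <- 40
  v <- c(rep(0, 50), rep(1, w), rep(0, 60))
  x <- first_event(as_time_series(v, dt = 1), detection_config(30))
  for (f in c(0.1, 0.5, 0.9)) {
    fw <- fractional_width(x$series, x$e, f, all_events = x$events)
    expect_true(fw$valid)
    expect_equal(fw$width, w, tolerance = 1)   # within one dt
  }
})

test_that("Gaussian FWHM matches the closed form 2*sqrt(2 ln 2)*sigma", {
  sigma <- 10   # ms
  ts <- gaussian_bump_series(center = 80, sigma = sigma, dt = 0.1)
  x <- first_event(ts)
  fw <- fractional_width(x$series, x$e, 0.5, all_events = x$events)
  expect_equal(fw$width, 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.005 * 2 * sqrt(2 * log(2)) * sigma)
})

test_that("fractional width is non-increasing in the fraction", {
  for (seed in c(4, 9)) {
    tr <- simulate_train(train_spec(n_peaks = 3, noise_sd = 0.02, seed = seed))
    ev <- detect_peaks(tr$series, detection_config(20, smooth_window = 5))
    for (e in ev) {
      widths <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(f)
        fractional_width(tr$series, e, f, all_events = ev)$width, numeric(1L))
      widths <- widths[is.finite(widths)]
      expect_true(all(diff(widths) <= 1e-9))
    }
  }
})

test_that("fraction outside (0,1) is rejected", {
  x <- first_event(gaussian_bump_series(50, 5, 1))
  expect_error(fractional_width(x$series, x$e, 0), class = "peakmap_input_error")
  expect_error(fractional_width(x$series, x$e, 1.2), class = "peakmap_input_error")
})

test_that("max slope of a sawtooth equals its rise rate", {
  m <- 0.05
  v <- c(rep(0, 20), seq(0, 1, by = m), rep(0, 30))
  x <- first_event(as_time_series(v, dt = 1), detection_config(30))
  s <- max_slope(x$series, x$e, "rise")
  expect_true(s$valid)
  expect_equal(s$slope, m, tolerance = 1e-9)
})

test_that("a time-mirrored peak has opposite extremal slopes", {
  sigma <- 8
  ts <- gaussian_bump_series(center = 60, sigma = sigma, dt = 1)
  x <- first_event(ts)
  r <- max_slope(x$series, x$e, "rise")
  d <- max_slope(x$series, x$e, "decay")
  expect_equal(d$slope, -r$slope, tolerance = 1e-9)
})

test_that("sigmoid upstroke rate is recovered from the simulator waveform", {
  tau_r <- 5
  sh <- peak_shape("ap_plateau", amplitude = 1, tau_rise = tau_r,
                   tau_decay = 60, plateau = 80)
  tr <- simulate_train(train_spec(sh, n_peaks = 1, period = 600,
                                  dt = tau_r / 10, seed = 1))
  ev <- detect_peaks(tr$series, cfg)
  s <- max_slope(tr$series, ev[[1L]], "rise")
  # analytic maximum derivative of A * plogis((t - t0)/tau) is A / (4 tau)
  expect_equal(s$slope, 1 / (4 * tau_r), tolerance = 0.02 / (4 * tau_r))
})

test_that("decay constant is recovered from a clean exponential", {
  sh <- peak_shape("transient", tau_rise = 4, tau_decay = 100)
  tr <- simulate_train(train_spec(sh, n_peaks = 1, period = 1500, dt = 1,
                                  seed = 1))
  ev <- detect_peaks(tr$series, cfg)
  fit <- fit_decay_tau(tr$series, ev[[1L]], cfg, all_events = ev)
  expect_true(fit$valid)
  expect_gte(fit$tau, 99)
  expect_lte(fit$tau, 101)
})

test_that("tau is invariant to amplitude scaling", {
  sh <- peak_shape("transient", tau_rise = 4, tau_decay = 100)
  tr <- simulate_train(train_spec(sh, n_peaks = 1, period = 1500, dt = 1,
                                  seed = 1))
  t1 <- fit_decay_tau(tr$series, detect_peaks(tr$series, cfg)[[1L]], cfg)
  ts10 <- time_series(tr$series$times, 10 * tr$series$values)
  t10 <- fit_decay_tau(ts10, detect_peaks(ts10, cfg)[[1L]], cfg)
  expect_equal(t1$tau, t10$tau, tolerance = 1e-6)
})

test_that("tau stays accurate under 5% noise (Monte Carlo)", {
  sh <- peak_shape("transient", tau_rise = 4, tau_decay = 100)
  errs <- vapply(1:50, function(seed) {
    tr <- simulate_train(train_spec(sh, n_peaks = 1, period = 1500, dt = 1,
                                    noise_sd = 0.05, seed = seed))
    ev <- detect_peaks(tr$series, detection_config(20, smooth_window = 7))
    if (!length(ev)) return(NA_real_)
    abs(fit_decay_tau(tr$series, ev[[1L]], cfg, all_events = ev)$tau - 100) / 100
  }, numeric(1L))
  expect_lte(stats::median(errs, na.rm = TRUE), 0.05)
})

test_that("too-short decay segments are flagged, not fitted", {
  v <- c(rep(0, 30), 1, 0.5, rep(0, 30))   # near-instant collapse
  ts <- as_time_series(v, dt = 1)
  ev <- detect_peaks(ts, detection_config(30))
  fit <- fit_decay_tau(ts, ev[[1L]], cfg, all_events = ev)
  expect_false(fit$valid)
  expect_true(is.na(fit$tau))
  expect_match(fit$reason, "samples")
})

test_that("rectangular pulse area is amplitude times width", {
  A <- 2.5; w <- 40
  v <- c(rep(0, 50), rep(A, w), rep(0, 60))
  ts <- as_time_series(v, dt = 1)
  ev <- detect_peaks(ts, detection_config(30))
  p <- compute_parameters(ts, ev[[1L]], cfg, all_events = ev)
  expect_equal(p$area, A * w, tolerance = A * 1)   # within one dt * A
})

test_that("time shift moves times and leaves every duration unchanged", {
  tr <- simulate_train(train_spec(n_peaks = 2, period = 400, noise_sd = 0.01,
                                  seed = 3))
  shift <- 250
  t1 <- analyze_xt(tr$series, cfg)
  t2 <- analyze_xt(time_series(tr$series$times + shift, tr$series$values), cfg)
  expect_equal(t2$apex_time, t1$apex_time + shift, tolerance = 1e-9)
  expect_equal(t2$threshold_time, t1$threshold_time + shift, tolerance = 1e-9)
  for (col in c("fwhm", "fw10", "time_to_peak", "decay_tau", "area",
                "amplitude_pk2pk", "max_rise_slope", "max_decay_slope"))
    expect_equal(t2[[col]], t1[[col]], tolerance = 1e-9, info = col)
})

test_that("value scaling scales amplitudes and slopes, not durations", {
  tr <- simulate_train(train_spec(n_peaks = 2, period = 400, noise_sd = 0.01,
                                  seed = 3))
  c0 <- 3.7
  t1 <- analyze_xt(tr$series, cfg)
  t2 <- analyze_xt(time_series(tr$series$times, c0 * tr$series$values), cfg)
  for (col in c("amplitude_pk2pk", "area", "max_rise_slope", "max_decay_slope"))
    expect_equal(t2[[col]], c0 * t1[[col]], tolerance = 1e-9, info = col)
  for (col in c("fwhm", "fw10", "time_to_peak", "decay_tau", "apex_time"))
    expect_equal(t2[[col]], t1[[col]], tolerance = 1e-9, info = col)
})
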