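test_that("the same spec and seed reproduce bit-identical outputs", {
  sp <- train_spec(n_peaks = 4, noise_sd = 0.05, timing_jitter_sd = 3,
                   amplitude_jitter_sd = 0.05, seed = 123)
  a <- simulate_train(sp)
  b <- simulate_train(sp)
  expect_identical(a$series$values, b$series$values)
  expect_identical(a$truth, b$truth)
  ws <- wave_spec(width = 12, height = 10, noise_sd = 0.02, seed = 42)
  expect_identical(simulate_wave(ws)$stack$frames,
                   simulate_wave(ws)$stack$frames)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- rnorm(3)
  set.seed(77)
  invisible(simulate_train(train_spec(n_peaks = 2, seed = 1, noise_sd = 0.1)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noise-free trains have exactly periodic analytic apexes", {
  tr <- simulate_train(train_spec(n_peaks = 3, period = 350, seed = 5))
  expect_equal(diff(tr$truth$apex_time), rep(350, 2L), tolerance = 1e-12)
  expect_identical(attr(tr$truth, "overlap_warning"), FALSE)
})

test_that("the double-exponential apex matches its closed form", {
  tr_c <- 5; td <- 50
  gt <- shape_ground_truth(peak_shape("transient", tau_rise = tr_c,
                                      tau_decay = td))
  expect_equal(gt$t_apex, tr_c * td / (td - tr_c) * log(td / tr_c),
               tolerance = 1e-12)
  expect_equal(gt$peak_value, 1, tolerance = 1e-12)   # normalized maximum
})

test_that("analytic widths agree with dense numeric widths of the waveform", {
  shapes <- list(
    peak_shape("transient", amplitude = 2, tau_rise = 5, tau_decay = 50),
    peak_shape("transient", amplitude = 1, tau_rise = 2, tau_decay = 120),
    peak_shape("ap_plateau", amplitude = 1, tau_rise = 3, tau_decay = 40,
               plateau = 100))
  for (sh in shapes) {
    gt <- shape_ground_truth(sh)
    t_dense <- seq(0, gt$widths$t_fall[gt$widths$fraction == 0.01] * 1.2,
                   by = gt$t_apex / 100 / 10)
    v <- abs(shape_value(sh, t_dense))
    for (fr in c(0.5, 0.1)) {
      lev <- fr * gt$peak_value
      above <- which(v >= lev)
      numeric_width <- t_dense[max(above)] - t_dense[min(above)]
      analytic <- gt$widths$width[gt$widths$fraction == fr]
      expect_equal(analytic, numeric_width, tolerance = 1e-3)
    }
  }
})

test_that("overlapping peaks raise the overlap flag", {
  sh <- peak_shape("transient", tau_rise = 5, tau_decay = 80)
  tr <- simulate_train(train_spec(sh, n_peaks = 3, period = 100, seed = 1))
  expect_true(attr(tr$truth, "overlap_warning"))
})

test_that("planar-wave activation spans the expected number of frames", {
  wv <- simulate_wave(wave_spec(speed = 1, angle_deg = 0, width = 100,
                                height = 4, dt = 1, seed = 9))
  span <- max(wv$truth$t_act) - min(wv$truth$t_act)
  expect_equal(span, 99, tolerance = 1e-12)   # 99 frames corner to corner
})

test_that("radial ground-truth isochrones are concentric circles", {
  spec <- wave_spec(geometry = "radial", origin = c(10, 8), speed = 0.5,
                    width = 21, height = 17, dt = 2, seed = 3)
  wv <- simulate_wave(spec)
  x <- matrix(rep(0:20, each = 17), 17); y <- matrix(rep(0:16, 21), 17)
  d <- sqrt((x - 10)^2 + (y - 8)^2)
  expect_equal(wv$truth$t_act, spec$t_lead + d / 0.5 * 2, tolerance = 1e-12)
})

test_that("unresolvable propagation is rejected", {
  expect_error(
    simulate_wave(wave_spec(speed = 500, width = 16, height = 16, seed = 1)),
    class = "peakmap_input_error")
})

test_that("a noise-free wave analyzed end-to-end reproduces its own ground truth", {
  wv <- simulate_wave(wave_spec(speed = 0.8, angle_deg = 60, width = 20,
                                height = 14, dt = 1, seed = 21))
  an <- analyze_stack(wv$stack, detection_config(30),
                      parameters = "amplitude_pk2pk")
  iso <- build_isochronal_map(an)
  tru <- wv$truth$t_act - min(wv$truth$t_act)
  expect_true(all(iso$valid))
  expect_lt(max(abs(iso$delay - tru)), 0.5)   # within dt / 2 per pixel
})
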