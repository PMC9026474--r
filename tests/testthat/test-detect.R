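test_that("flat and degenerate traces yield no events", {
  flat <- as_time_series(rep(3.2, 100), dt = 1)
  expect_identical(detect_peaks(flat, detection_config(5)), list())
  expect_identical(detect_peaks(flat, detection_config(100)), list())
})

test_that("well-separated bumps are all found at their centers", {
  bt <- bump_train_series(rep(1, 5), period = 200, sigma = 10, dt = 1)
  ev <- detect_peaks(bt$series, detection_config(sensitivity_percent = 20))
  expect_length(ev, 5L)
  apex_t <- vapply(ev, `[[`, numeric(1L), "apex_time")
  expect_equal(apex_t, bt$centers, tolerance = 1e-6)
  # matches the independent exhaustive oracle
  expect_identical(vapply(ev, `[[`, integer(1L), "apex_index"),
                   oracle_detect(bt$series$values, 20))
})

test_that("negative polarity mirrors positive detection exactly", {
  v <- random_signal(101, n = 600)
  pos <- detect_peaks(as_time_series(v, dt = 1),
                      detection_config(15, polarity = "positive"))
  neg <- detect_peaks(as_time_series(-v, dt = 1),
                      detection_config(15, polarity = "negative"))
  expect_identical(vapply(pos, `[[`, integer(1L), "apex_index"),
                   vapply(neg, `[[`, integer(1L), "apex_index"))
  expect_equal(vapply(pos, `[[`, numeric(1L), "prominence"),
               vapply(neg, `[[`, numeric(1L), "prominence"))
  expect_true(all(vapply(neg, `[[`, integer(1L), "polarity") == -1L))
})

test_that("detection agrees with the brute-force oracle on random signals", {
  for (seed in 1:40) {
    v <- random_signal(seed)
    got <- detect_peaks(as_time_series(v, dt = 1),
                        detection_config(20, apex_refine = FALSE))
    expect_identical(vapply(got, `[[`, integer(1L), "apex_index"),
                     oracle_detect(v, 20), info = paste("seed", seed))
  }
})

test_that("raising the sensitivity never increases the event count", {
  for (seed in c(7, 21, 33)) {
    v <- random_signal(seed, n = 800)
    ts <- as_time_series(v, dt = 1)
    counts <- vapply(c(5, 10, 20, 40, 80),
                     function(p) length(detect_peaks(ts, detection_config(p))),
                     integer(1L))
    expect_true(all(diff(counts) <= 0), info = paste("seed", seed))
  }
})

test_that("every reported prominence respects the sensitivity threshold", {
  for (seed in c(3, 12)) {
    v <- random_signal(seed, n = 1000)
    ts <- as_time_series(v, dt = 1)
    thr <- 25 / 100 * diff(range(v))
    ev <- detect_peaks(ts, detection_config(25, polarity = "both"))
    expect_true(all(vapply(ev, `[[`, numeric(1L), "prominence") >= thr))
    for (e in ev) {
      expect_lt(e$left_bound, e$apex_index)
      expect_gt(e$right_bound, e$apex_index)
    }
  }
})

test_that("min_separation merges close apexes keeping the larger prominence", {
  bt <- bump_train_series(c(1, 0.6), period = 50, sigma = 8, dt = 1)
  cfg_all <- detection_config(10)
  ev_all <- detect_peaks(bt$series, cfg_all)
  expect_length(ev_all, 2L)
  ev_merged <- detect_peaks(bt$series, detection_config(10, min_separation = 80))
  expect_length(ev_merged, 1L)
  expect_equal(ev_merged[[1L]]$apex_time, bt$centers[1L], tolerance = 1e-6)
})

test_that("a plateau apex takes its first sample", {
  v <- c(rep(0, 10), seq(0, 1, length.out = 5), rep(1, 6),
         seq(1, 0, length.out = 5), rep(0, 10))
  ev <- detect_peaks(as_time_series(v, dt = 1), detection_config(30))
  expect_length(ev, 1L)
  expect_identical(ev[[1L]]$apex_index, 15L)   # first sample at the maximum
  expect_equal(ev[[1L]]$apex_time, 14)         # plateaus are never refined
})

test_that("detection-only smoothing rejects noise spikes but keeps raw apexes", {
  tr <- simulate_train(train_spec(n_peaks = 4, period = 400, noise_sd = 0.05,
                                  seed = 5))
  cfg <- detection_config(20, smooth_window = 7, min_separation = 100)
  ev <- detect_peaks(tr$series, cfg)
  expect_length(ev, 4L)
  # apex indices are raw-trace local maxima
  raw_max <- which(diff(sign(diff(tr$series$values))) < 0) + 1L
  expect_true(all(vapply(ev, `[[`, integer(1L), "apex_index") %in% raw_max))
})
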