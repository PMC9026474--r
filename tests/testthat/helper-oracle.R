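# Independent brute-force detection oracle and signal generators shared by
# the unit and acceptance tests.  The oracle deliberately uses a different
# construction from the package: plateaus are found on the run-length
# compressed signal, and each candidate's prominence is computed by an
# exhaustive whole-trace scan for higher terrain.

# indices of local maxima (first sample of a plateau) by run-length encoding
oracle_local_maxima <- function(v) {
  r <- rle(v)
  m <- length(r$values)
  if (m < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inner <- 2:(m - 1L)
  is_max <- r$values[inner] > r$values[inner - 1L] &
            r$values[inner] > r$values[inner + 1L]
  starts[inner][is_max]
}

# exhaustive prominence: nearest strictly higher sample on each side bounds
# the key-saddle search; a side without higher terrain uses the whole side
oracle_prominence <- function(v, i) {
  n <- length(v)
  left <- if (i > 1L) {
    higher <- which(v[seq_len(i - 1L)] > v[i])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(v[lo:(i - 1L)])
  } else v[i]
  right <- if (i < n) {
    higher <- which(v[(i + 1L):n] > v[i])
    hi <- if (length(higher)) i + min(higher) - 1L else n
    min(v[(i + 1L):hi])
  } else v[i]
  v[i] - max(left, right)
}

# full oracle: apex indices of peaks with prominence >= pct% of global range
oracle_detect <- function(v, sensitivity_percent, polarity = "positive") {
  rng <- max(v) - min(v)
  if (rng == 0) return(integer(0))
  w <- if (polarity == "negative") -v else v
  cand <- oracle_local_maxima(w)
  thr <- sensitivity_percent / 100 * rng
  cand[vapply(cand, function(i) oracle_prominence(w, i), numeric(1L)) >= thr]
}

# random test signal: a few smooth bumps on noise, fixed seed
random_signal <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(50:2000, 1L)
  t <- seq_len(n)
  v <- rnorm(n, 0, runif(1, 0.01, 0.2))
  for (b in seq_len(sample(0:6, 1L))) {
    c0 <- runif(1, 1, n)
    sg <- runif(1, 2, n / 8)
    v <- v + runif(1, -1.5, 1.5) * exp(-((t - c0) / sg)^2 / 2)
  }
  v
}

gaussian_bump_series <- function(center, sigma, dt, span = 6 * sigma,
                                 amplitude = 1, baseline = 0) {
  t <- seq(center - span, center + span, by = dt)
  as_time_series(baseline + amplitude * exp(-((t - center) / sigma)^2 / 2),
                 dt = dt)
}

# a train of Gaussian bumps with chosen per-peak amplitudes on a flat trace
bump_train_series <- function(amplitudes, period = 200, sigma = 10, dt = 1) {
  n <- length(amplitudes)
  t <- seq(0, (n + 0.5) * period, by = dt)
  v <- numeric(length(t))
  centers <- period / 2 + (seq_len(n) - 1L) * period
  for (k in seq_len(n))
    v <- v + amplitudes[k] * exp(-((t - centers[k]) / sigma)^2 / 2)
  list(series = as_time_series(v, dt = dt), centers = centers)
}
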