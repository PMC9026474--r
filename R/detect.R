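# Peak detection: local extrema filtered by topographic prominence.
#
# A sample is an apex candidate if it is strictly higher than its neighbours
# (a plateau of equal samples bounded by lower samples counts once, at its
# first sample).  A candidate is kept when its prominence -- its height above
# the higher of the two key saddles separating it from higher terrain, with
# trace ends acting as open terrain -- exceeds the user sensitivity expressed
# as a percentage of the global signal range.

# indices of local maxima of v; plateaus yield their first index
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# topographic prominence of the local maximum at index i of v
peak_prominence_at <- function(v, i) {
  n <- length(v)
  vi <- v[i]
  lo_l <- vi
  j <- i - 1L
  while (j >= 1L && v[j] <= vi) {
    if (v[j] < lo_l) lo_l <- v[j]
    j <- j - 1L
  }
  lo_r <- vi
  j <- i + 1L
  while (j <= n && v[j] <= vi) {
    if (v[j] < lo_r) lo_r <- v[j]
    j <- j + 1L
  }
  vi - max(lo_l, lo_r)
}

boxcar_smooth <- function(v, width) {
  width <- as.integer(width)
  if (width <= 1L) return(v)
  k <- rep(1 / width, width)
  sm <- stats::filter(v, k, sides = 2L)
  sm <- as.numeric(sm)
  # edges: shrink the window rather than dropping samples
  nas <- which(is.na(sm))
  half <- width %/% 2L
  n <- length(v)
  for (i in nas) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(v[lo:hi])
  }
  sm
}

# Core single-polarity candidate scan on a working (sign-adjusted) trace.
# Returns apex indices and raw prominences above `thr`.
scan_candidates <- function(w_det, w_raw, thr, smooth_window) {
  cand <- local_maxima(w_det)
  if (!length(cand)) return(list(apex = integer(0), prominence = numeric(0)))
  # the sensitivity decision is taken on the detection copy, so smoothing
  # genuinely suppresses noise spikes whose raw prominence would pass
  prom_det <- vapply(cand, function(i) peak_prominence_at(w_det, i), numeric(1L))
  keep_det <- prom_det >= thr
  cand <- cand[keep_det]
  if (!length(cand)) return(list(apex = integer(0), prominence = numeric(0)))
  if (is.null(smooth_window))
    return(list(apex = cand, prominence = prom_det[keep_det]))
  # relocate each apex onto the raw maximum of the smoothed peak's own top
  # (where the detection copy stays within half its prominence of the apex);
  # that region always contains the event's raw apex, and the reported
  # prominence is then re-measured on the raw trace
  prom_det <- prom_det[keep_det]
  n <- length(w_raw)
  cand <- vapply(seq_along(cand), function(k) {
    i <- cand[k]
    lim <- w_det[i] - 0.5 * prom_det[k]
    lo <- i; while (lo > 1L && w_det[lo - 1L] > lim) lo <- lo - 1L
    hi <- i; while (hi < n && w_det[hi + 1L] > lim) hi <- hi + 1L
    lo - 1L + which.max(w_raw[lo:hi])
  }, integer(1L))
  cand <- sort(unique(cand))
  if (!length(cand)) return(list(apex = integer(0), prominence = numeric(0)))
  prom <- vapply(cand, function(i) peak_prominence_at(w_raw, i), numeric(1L))
  keep <- prom >= thr
  list(apex = cand[keep], prominence = prom[keep])
}

# greedy merge of apexes closer than min_separation, keeping larger prominence
merge_close <- function(apex_time, prominence, min_separation) {
  keep <- rep(TRUE, length(apex_time))
  if (min_separation <= 0 || length(apex_time) < 2L) return(keep)
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) break
    gaps <- diff(apex_time[idx])
    bad <- which(gaps < min_separation)
    if (!length(bad)) break
    b <- bad[1L]
    pair <- idx[c(b, b + 1L)]
    drop <- pair[which.min(prominence[pair])]
    keep[drop] <- FALSE
  }
  keep
}

#' Detect peaks in a time series
#'
#' Finds positive and/or negative peaks: local extrema whose topographic
#' prominence exceeds `sensitivity_percent` percent of the global range
#' (trace maximum minus minimum).  Negative peaks are found by running the
#' identical procedure on the negated trace.  When a detection-only smoothed
#' copy is configured, candidate apexes found on the smoothed trace are
#' relocated onto the raw trace, and prominences and all downstream
#' parameters are measured on the raw trace.
#'
#' Event boundaries are the valleys (signal extrema of opposite sense)
#' between adjacent apexes; trace ends bound the first and last event.
#' Apexes closer in time than `min_separation` are merged, keeping the one
#' with the larger prominence.
#'
#' @param series A [time_series()].
#' @param config A [detection_config()].
#' @return A list of `peak_event` objects ordered by apex time.  Each has
#'   fields `apex_index`, `apex_time`, `apex_value`, `polarity` (+1 or -1),
#'   `left_bound`, `right_bound` (sample indices) and `prominence` (signal
#'   units, always positive).  A flat trace, or one where nothing exceeds the
#'   sensitivity, yields an empty list.
#' @examples
#' ts <- as_time_series(dnorm(seq(-5, 5, by = 0.05)), dt = 1)
#' ev <- detect_peaks(ts, detection_config(sensitivity_percent = 20))
#' length(ev)
#' @export
detect_peaks <- function(series, config = detection_config()) {
  check_time_series(series)
  check_config(config)
  v <- series$values
  rng <- max(v) - min(v)
  if (rng == 0) return(list())
  thr <- config$sensitivity_percent / 100 * rng

  v_det <- if (is.null(config$smooth_window)) v else
    boxcar_smooth(v, config$smooth_window)

  apex <- integer(0); prom <- numeric(0); pol <- integer(0)
  if (config$polarity %in% c("positive", "both")) {
    s <- scan_candidates(v_det, v, thr, config$smooth_window)
    apex <- c(apex, s$apex); prom <- c(prom, s$prominence)
    pol <- c(pol, rep(1L, length(s$apex)))
  }
  if (config$polarity %in% c("negative", "both")) {
    s <- scan_candidates(-v_det, -v, thr, config$smooth_window)
    apex <- c(apex, s$apex); prom <- c(prom, s$prominence)
    pol <- c(pol, rep(-1L, length(s$apex)))
  }
  if (!length(apex)) return(list())

  o <- order(apex)
  apex <- apex[o]; prom <- prom[o]; pol <- pol[o]
  keep <- merge_close(series$times[apex], prom, config$min_separation)
  apex <- apex[keep]; prom <- prom[keep]; pol <- pol[keep]

  n <- length(v)
  m <- length(apex)
  events <- vector("list", m)
  for (k in seq_len(m)) {
    i <- apex[k]
    # next-event boundary: midpoint between adjacent apexes; trace ends cap
    # the terminal events
    seg_lo <- if (k > 1L) as.integer((apex[k - 1L] + i) %/% 2L) else 1L
    rb <- if (k < m) as.integer((i + apex[k + 1L]) %/% 2L) else n
    # onset search: last sample before the apex within 5% (of the local
    # rise) of the segment floor -- lands at the foot of the upstroke, is
    # always defined (the argmin qualifies), and leaves the quiet segment
    # to its left for the baseline estimate
    w <- v * pol[k]
    lb <- seg_lo
    if (seg_lo < i - 1L) {
      seg <- seg_lo:(i - 1L)
      wmin <- min(w[seg])
      foot <- wmin + 0.05 * (w[i] - wmin)
      below <- which(w[seg] <= foot)
      lb <- seg_lo - 1L + below[length(below)]
    }
    if (lb >= i) lb <- i - 1L
    if (rb <= i) rb <- min(n, i + 1L)
    apex_t <- series$times[i]
    if (config$apex_refine)
      apex_t <- refine_apex_time(w, series$times, i, lb, rb)
    events[[k]] <- structure(
      list(apex_index = i,
           apex_time = apex_t,
           apex_value = v[i],
           polarity = pol[k],
           left_bound = lb,
           right_bound = rb,
           prominence = prom[k]),
      class = "peak_event")
  }
  events
}

# Sub-sample apex time: vertex of a quadratic fitted to the samples around
# the apex.  Refinement is skipped (sample time kept) for plateau apexes --
# a tied neighbour means the extremum is a region, and the first-sample
# tie-break must stand -- and whenever the fit is degenerate (non-negative
# curvature) or the vertex leaves the fit window.
# `half` balances the cubic-term bias on asymmetric peaks (grows with the
# window) against noise variance of the vertex (shrinks with it)
refine_apex_time <- function(w, times, i, lb, rb, half = 4L) {
  n <- length(w)
  if (i <= 1L || i >= n) return(times[i])
  if (w[i - 1L] >= w[i] || w[i + 1L] >= w[i]) return(times[i])  # plateau/tie
  lo <- max(lb, i - half); hi <- min(rb, i + half)
  if (hi - lo + 1L < 5L) return(times[i])
  tt <- times[lo:hi] - times[i]
  fit <- tryCatch(stats::lm.fit(cbind(1, tt, tt * tt), w[lo:hi])$coefficients,
                  error = function(e) NULL)
  if (is.null(fit) || anyNA(fit) || fit[3L] >= 0) return(times[i])
  v <- as.numeric(-fit[2L] / (2 * fit[3L]))
  if (!is.finite(v) || abs(v) > (times[hi] - times[lo]) / 2) return(times[i])
  times[i] + v
}

#' @export
print.peak_event <- function(x, ...) {
  cat(sprintf("<peak_event> %s apex at t = %g (index %d), value %g, prominence %g, bounds [%d, %d]\n",
              if (x$polarity > 0) "positive" else "negative",
              x$apex_time, x$apex_index, x$apex_value, x$prominence,
              x$left_bound, x$right_bound))
  invisible(x)
}
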