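# Validation studies: run the analyzer against the simulator's analytic
# ground truth over a grid of conditions.  These drive the package's own
# acceptance checks and let users probe their experimental conditions
# (sampling rate, noise level, kinetics) before trusting an analysis.

#' Parameter-recovery study on simulated peak trains
#'
#' Simulates trains over a grid of amplitudes, decay constants and relative
#' noise levels, analyzes each with the supplied configuration, matches
#' detected events to the ground truth by apex time, and returns one row per
#' matched event with truth, measurement and error for amplitude, FWHM,
#' FW10, decay tau and apex time.
#'
#' @param amplitudes,tau_decays Numeric grids (signal units / time units).
#' @param noise_fracs Noise SD as a fraction of the amplitude.
#' @param n_seeds Replicates per grid cell.
#' @param base_seed Offset added to every replicate seed.
#' @param config [detection_config()] used for the analysis; the default
#'   adds detection smoothing and apex merging suited to the noisy cells.
#' @param n_peaks,period,dt,tau_rise Train layout (time units).
#' @return A data.frame with columns `amplitude_true`, `tau_true`,
#'   `noise_frac`, `seed`, `n_detected`, `n_true`, and per-event
#'   `apex_err` (absolute, time units) plus `amp_rel`, `fwhm_rel`,
#'   `fw10_rel`, `tau_rel` (absolute relative errors).
#' @export
recovery_study <- function(amplitudes = c(0.5, 1, 2),
                           tau_decays = c(25, 50, 100),
                           noise_fracs = c(0, 0.02, 0.05),
                           n_seeds = 20, base_seed = 0,
                           config = detection_config(
                             sensitivity_percent = 20, smooth_window = 7,
                             min_separation = 125),
                           n_peaks = 5, period = 500, dt = 1, tau_rise = 5) {
  out <- list()
  for (A in amplitudes) for (td in tau_decays) for (nf in noise_fracs) {
    sh <- peak_shape("transient", amplitude = A, tau_rise = tau_rise,
                     tau_decay = td)
    for (s in seq_len(n_seeds)) {
      seed <- (base_seed + length(out) * 131L + s) %% 2147483647L
      tr <- simulate_train(train_spec(sh, n_peaks = n_peaks, period = period,
                                      dt = dt, noise_sd = nf * A, seed = seed))
      tab <- analyze_xt(tr$series, config)
      if (!nrow(tab)) {
        out[[length(out) + 1L]] <- data.frame(
          amplitude_true = A, tau_true = td, noise_frac = nf, seed = seed,
          n_detected = 0L, n_true = n_peaks, apex_err = NA_real_,
          amp_rel = NA_real_, fwhm_rel = NA_real_, fw10_rel = NA_real_,
          tau_rel = NA_real_)
        next
      }
      # match each true event to the nearest detected apex
      idx <- vapply(tr$truth$apex_time, function(t0)
        which.min(abs(tab$apex_time - t0)), integer(1L))
      keep <- abs(tab$apex_time[idx] - tr$truth$apex_time) < period / 2
      out[[length(out) + 1L]] <- data.frame(
        amplitude_true = A, tau_true = td, noise_frac = nf, seed = seed,
        n_detected = nrow(tab), n_true = n_peaks,
        apex_err = ifelse(keep, abs(tab$apex_time[idx] - tr$truth$apex_time), NA),
        amp_rel = ifelse(keep, abs(tab$amplitude_pk2pk[idx] - tr$truth$amplitude) /
                           tr$truth$amplitude, NA),
        fwhm_rel = ifelse(keep, abs(tab$fwhm[idx] - tr$truth$fwhm) /
                            tr$truth$fwhm, NA),
        fw10_rel = ifelse(keep, abs(tab$fw10[idx] - tr$truth$fw10) /
                            tr$truth$fw10, NA),
        tau_rel = ifelse(keep, abs(tab$decay_tau[idx] - tr$truth$decay_tau) /
                           tr$truth$decay_tau, NA))
    }
  }
  do.call(rbind, out)
}

#' Conduction-velocity recovery study on simulated planar waves
#'
#' Simulates planar waves over a grid of speeds and directions, runs the
#' full per-pixel analysis, builds the isochronal map and vector field, and
#' summarizes the speed and direction errors of every wave.
#'
#' @param speeds Wave speeds in pixels per frame.
#' @param angles_deg Propagation directions in degrees.
#' @param noise_sd Noise SD in signal units (waveform amplitude is 1).
#' @param size Frame edge length in pixels (square frames).
#' @param base_seed Offset added to each wave's seed.
#' @param config [detection_config()] for the per-pixel analysis.
#' @param window_radius Plane-fit window half-size for [build_vector_map()].
#' @param shape Waveform; the default has fast kinetics so that slow waves
#'   stay within a manageable number of frames.
#' @return A data.frame with one row per wave: `speed_true`, `angle_true`,
#'   `median_speed_err_rel`, `median_angle_err_deg`, `n_valid_windows`.
#' @export
velocity_study <- function(speeds = c(0.1, 0.3, 1.0),
                           angles_deg = c(0, 30, 90, 215),
                           noise_sd = 0.05, size = 64, base_seed = 0,
                           config = detection_config(
                             sensitivity_percent = 30, smooth_window = 5),
                           window_radius = 2,
                           shape = peak_shape("transient", tau_rise = 3,
                                              tau_decay = 25)) {
  out <- list()
  for (v in speeds) for (th in angles_deg) {
    seed <- (base_seed + round(1000 * v) * 7L + th) %% 2147483647L
    wv <- simulate_wave(wave_spec(shape, geometry = "planar", angle_deg = th,
                                  speed = v, width = size, height = size,
                                  dt = 1, noise_sd = noise_sd, seed = seed))
    an <- analyze_stack(wv$stack, config, parameters = character(0))
    vf <- build_vector_map(build_isochronal_map(an),
                           window_radius = window_radius)
    ok <- vf$valid
    sp_err <- abs(vf$speed[ok] - v) / v
    ang <- atan2(vf$vy[ok], vf$vx[ok]) * 180 / pi
    ang_err <- abs(((ang - th + 180) %% 360) - 180)
    out[[length(out) + 1L]] <- data.frame(
      speed_true = v, angle_true = th,
      median_speed_err_rel = stats::median(sp_err),
      median_angle_err_deg = stats::median(ang_err),
      n_valid_windows = sum(ok))
  }
  do.call(rbind, out)
}
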