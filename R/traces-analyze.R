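# End-to-end quantification of a treatment/washout recording.

#' Extract a time window from a trace
#'
#' @param trace a `circadian_trace`.
#' @param from_h,to_h window bounds in hours (inclusive).
#' @return a `circadian_trace` restricted to the window.
#' @export
subset_trace <- function(trace, from_h = -Inf, to_h = Inf) {
  sel <- trace$time_h >= from_h & trace$time_h <= to_h
  stop_if_not(sum(sel) >= 2, "window contains fewer than 2 samples")
  out <- trace
  out$time_h <- trace$time_h[sel]
  out$value <- trace$value[sel]
  out
}

#' Full cycle-metric quantification of a treatment recording
#'
#' Smooths the trace, detects alternating peaks and troughs, and computes
#' the complete metric set for a recording with baseline, treatment and
#' (optionally) washout intervals: per-interval period and their difference,
#' cycle amplitudes normalized to the last baseline cycle, the phase shift
#' at the second post-treatment peak, per-cycle B/A ratios with the
#' steady-state value at the second post-washout peak, and RAE for the
#' baseline and treatment intervals from FFT-initialized cosine fits.
#'
#' @param trace a `circadian_trace`.
#' @param treatment_start_h,treatment_end_h treatment window in hours;
#'   default taken from the trace's first epoch.
#' @param smooth_points moving-average width (samples) used before peak
#'   detection.
#' @param min_separation_h,min_prominence_frac peak-detection parameters
#'   (see [find_peaks_troughs()]); lower the prominence fraction for
#'   recordings whose treatment interval strongly suppresses amplitude.
#' @param period_window_h admissible period range for the cosine fits.
#' @return object of class `cycle_metrics`: list with `period_baseline_h`,
#'   `period_treatment_h`, `delta_period_h`, `amplitudes` (data frame),
#'   `norm_amplitude_treatment` (mean normalized amplitude of treatment
#'   cycles), `phase_shift_h`, `ba` (data frame), `steady_state_ba`,
#'   `rae_baseline`, `rae_treatment`, `rae_normalized`, `peaks`.
#' @export
cycle_metrics <- function(trace, treatment_start_h = NULL,
                          treatment_end_h = NULL, smooth_points = 5,
                          min_separation_h = 16, min_prominence_frac = 0.2,
                          period_window_h = c(18, 30)) {
  if (is.null(treatment_start_h) || is.null(treatment_end_h)) {
    win <- trace_treatment_window(trace)
    treatment_start_h <- treatment_start_h %||% win[["start"]]
    treatment_end_h <- treatment_end_h %||% win[["end"]]
  }
  sm <- smooth_trace(trace, smooth_points)
  peaks <- find_peaks_troughs(sm, min_separation_h = min_separation_h,
                              min_prominence_frac = min_prominence_frac)

  t_max <- max(trace$time_h)
  base_iv <- c(min(trace$time_h), treatment_start_h)
  treat_iv <- c(treatment_start_h, treatment_end_h)

  period_base <- compute_period(peaks, base_iv)
  period_treat <- suppressWarnings(compute_period(peaks, treat_iv))

  amps <- cycle_amplitudes(peaks, treatment_start_h)
  # complete treatment cycles only: the preceding trough must also fall
  # inside the window, which excludes the transition cycle
  in_treat <- amps$peak_time_h >= treatment_start_h &
    amps$peak_time_h < treatment_end_h &
    amps$trough_time_h >= treatment_start_h
  norm_amp <- if (any(in_treat)) mean(amps$norm_amplitude[in_treat]) else NA_real_

  shift <- suppressWarnings(phase_shift(peaks, period_base, treatment_start_h))

  ba_tab <- ba_ratio(peaks)
  ss_ba <- if (treatment_end_h < t_max)
    tryCatch(steady_state_ba(peaks, treatment_end_h), error = function(e) NA_real_)
  else NA_real_

  fit_base <- fit_fft_nlls(subset_trace(trace, base_iv[1], base_iv[2]),
                           period_window_h)
  rae_base <- rae(fit_base)
  rae_treat <- if (diff(treat_iv) >= 2 * period_window_h[1]) {
    rae(fit_fft_nlls(subset_trace(trace, treat_iv[1], treat_iv[2]),
                     period_window_h))
  } else NA_real_

  structure(list(period_baseline_h = period_base,
                 period_treatment_h = period_treat,
                 delta_period_h = period_treat - period_base,
                 amplitudes = amps,
                 norm_amplitude_treatment = norm_amp,
                 phase_shift_h = shift,
                 ba = ba_tab,
                 steady_state_ba = ss_ba,
                 rae_baseline = rae_base,
                 rae_treatment = rae_treat,
                 rae_normalized = if (is.na(rae_treat)) NA_real_ else
                   rae_normalized(rae_treat, rae_base),
                 peaks = peaks),
            class = "cycle_metrics")
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat("<cycle_metrics>\n")
  cat(sprintf("  period: baseline %.2f h, treatment %.2f h (delta %+.2f h)\n",
              x$period_baseline_h, x$period_treatment_h, x$delta_period_h))
  cat(sprintf("  normalized treatment amplitude: %.3f\n",
              x$norm_amplitude_treatment))
  cat(sprintf("  phase shift: %+.2f h (advance positive)\n", x$phase_shift_h))
  cat(sprintf("  steady-state B/A: %.3f\n", x$steady_state_ba))
  cat(sprintf("  RAE: baseline %.3f, treatment %.3f (normalized %.2f)\n",
              x$rae_baseline, x$rae_treatment, x$rae_normalized))
  invisible(x)
}
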