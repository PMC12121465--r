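# Cycle-level trace metrics: period, period change, normalized cycle
# amplitudes, phase shift, B/A washout ratio, circadian-time assignment,
# 24-h signal integration and cohort pseudo-alignment.

#' Peak-to-peak period over an interval
#'
#' Mean time difference between consecutive peaks whose times fall inside
#' `interval_h`.
#'
#' @param peaks a `peak_set`.
#' @param interval_h length-2 numeric `c(start, end)` in hours; default
#'   spans all peaks.
#' @return period in hours, or `NA` (with a warning) when fewer than 2 peaks
#'   fall in the interval.
#' @export
compute_period <- function(peaks, interval_h = NULL) {
  pt <- peaks$peak_times_h
  if (!is.null(interval_h))
    pt <- pt[pt >= interval_h[1] & pt <= interval_h[2]]
  if (length(pt) < 2) {
    warning("fewer than 2 peaks in interval; period undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(diff(pt))
}

#' Change in period between baseline and treatment intervals
#'
#' @param peaks a `peak_set`.
#' @param baseline_interval_h,treatment_interval_h length-2 `c(start, end)`
#'   windows in hours.
#' @return `treatment mean period - baseline mean period` in hours.
#' @export
delta_period <- function(peaks, baseline_interval_h, treatment_interval_h) {
  compute_period(peaks, treatment_interval_h) -
    compute_period(peaks, baseline_interval_h)
}

#' Cycle amplitudes normalized to the last pre-treatment cycle
#'
#' Cycle amplitude is the absolute difference between each peak and its
#' preceding trough; amplitudes are normalized to the last cycle before
#' `treatment_start_h` (the reference cycle).
#'
#' @param peaks a `peak_set`.
#' @param treatment_start_h treatment onset in hours.
#' @return data frame: `peak_time_h`, `amplitude`, `norm_amplitude`.
#' @export
cycle_amplitudes <- function(peaks, treatment_start_h) {
  amp <- cycle_amplitude_table(peaks)
  ref <- amp$amplitude[amp$peak_time_h < treatment_start_h]
  stop_if_not(length(ref) > 0,
              "no complete pre-treatment cycle to use as reference")
  amp$norm_amplitude <- amp$amplitude / ref[length(ref)]
  amp
}

# per-peak |peak - preceding trough|
cycle_amplitude_table <- function(peaks) {
  rows <- lapply(seq_along(peaks$peak_times_h), function(i) {
    pt <- peaks$peak_times_h[i]
    before <- which(peaks$trough_times_h < pt)
    if (!length(before)) return(NULL)
    j <- before[length(before)]
    data.frame(peak_time_h = pt, trough_time_h = peaks$trough_times_h[j],
               amplitude = abs(peaks$peak_values[i] - peaks$trough_values[j]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(peak_time_h = numeric(0),
                                      trough_time_h = numeric(0),
                                      amplitude = numeric(0))
  out
}

#' Phase shift from the second post-treatment peak
#'
#' The predicted second post-treatment peak is extrapolated from the last
#' pre-treatment peak and the baseline period; the shift is
#' `predicted - observed`, so an advance (peak earlier than predicted) is
#' positive and a delay negative. Using the second cycle post-treatment
#' absorbs first-cycle waveform transients.
#'
#' @param peaks a `peak_set`.
#' @param baseline_period_h baseline period in hours.
#' @param treatment_start_h treatment onset in hours.
#' @return shift in hours, or `NA` (with a warning) when peaks are missing.
#' @export
phase_shift <- function(peaks, baseline_period_h, treatment_start_h) {
  pre <- peaks$peak_times_h[peaks$peak_times_h < treatment_start_h]
  post <- peaks$peak_times_h[peaks$peak_times_h >= treatment_start_h]
  if (!length(pre) || length(post) < 2) {
    warning("need >= 1 pre-treatment and >= 2 post-treatment peaks",
            call. = FALSE)
    return(NA_real_)
  }
  predicted <- pre[length(pre)] + 2 * baseline_period_h
  predicted - post[2]
}

#' B/A ratio per cycle and its steady-state value post-washout
#'
#' For every peak flanked by troughs, B is the rising amplitude (preceding
#' trough to peak) and A the falling amplitude (peak to following trough);
#' the B/A ratio is 1 for a stationary oscillation and below 1 while an
#' oscillation grows back after washout. Peaks without both flanking troughs
#' are skipped.
#'
#' @param peaks a `peak_set`.
#' @return data frame: `peak_time_h`, `b`, `a`, `ba_ratio`.
#' @export
ba_ratio <- function(peaks) {
  rows <- lapply(seq_along(peaks$peak_times_h), function(i) {
    pt <- peaks$peak_times_h[i]
    before <- which(peaks$trough_times_h < pt)
    after <- which(peaks$trough_times_h > pt)
    if (!length(before) || !length(after)) return(NULL)
    b <- peaks$peak_values[i] - peaks$trough_values[before[length(before)]]
    a <- peaks$peak_values[i] - peaks$trough_values[after[1]]
    data.frame(peak_time_h = pt, b = b, a = a, ba_ratio = b / a)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(peak_time_h = numeric(0), b = numeric(0),
                                      a = numeric(0), ba_ratio = numeric(0))
  out
}

#' @rdname ba_ratio
#' @param washout_start_h washout onset in hours; the steady-state B/A is
#'   read at the second peak post-washout.
#' @export
steady_state_ba <- function(peaks, washout_start_h) {
  tab <- ba_ratio(peaks)
  post <- tab[tab$peak_time_h >= washout_start_h, , drop = FALSE]
  stop_if_not(nrow(post) >= 2, "need >= 2 complete post-washout cycles")
  post$ba_ratio[2]
}

#' Map recording time to circadian time via a reference peak
#'
#' `CT(t) = (reference_ct + (t - reference_peak_time) * 24 / period) mod 24`;
#' by convention the neuronal calcium peak anchors CT6.
#'
#' @param time_h recording times (hours).
#' @param reference_peak_time_h time of the reference peak.
#' @param reference_ct CT assigned to the reference peak (default 6).
#' @param period_h the rhythm's period.
#' @return CT values in \[0, 24).
#' @export
assign_ct <- function(time_h, reference_peak_time_h, reference_ct = 6,
                      period_h = 24) {
  (reference_ct + (time_h - reference_peak_time_h) * 24 / period_h) %% 24
}

#' Trapezoidal integrals of a signal over consecutive 24-h windows
#'
#' @param trace a `circadian_trace` (normalize the signal first if desired).
#' @param start_h start of the first window.
#' @return data frame: `window_start_h`, `window_end_h`, `integral`.
#'   Partial trailing windows are dropped; an error is raised when no
#'   complete window fits.
#' @export
integrate_24h <- function(trace, start_h = min(trace$time_h)) {
  t_end <- max(trace$time_h)
  stop_if_not(t_end - start_h >= 24, "no complete 24-h window in the trace")
  starts <- seq(start_h, t_end - 24, by = 24)
  rows <- lapply(starts, function(s) {
    sel <- trace$time_h >= s & trace$time_h <= s + 24
    data.frame(window_start_h = s, window_end_h = s + 24,
               integral = pracma::trapz(trace$time_h[sel], trace$value[sel]))
  })
  do.call(rbind, rows)
}

#' Pseudo-align a cohort of traces on per-trace reference peaks
#'
#' Shifts each trace so its reference peak sits at t = 0, resamples all
#' traces onto a common grid (step = the coarsest input sampling interval,
#' linear interpolation) and returns the pointwise mean and SEM. Grid points
#' listed in `exclude_windows_h` (e.g. treatment-artifact intervals) are
#' emitted as gaps (`NA`).
#'
#' @param traces list of `circadian_trace` objects.
#' @param reference_peak_h numeric vector, one reference peak time per
#'   trace; traces with `NA` are excluded with a warning.
#' @param exclude_windows_h optional data frame (`start_h`, `end_h`) of
#'   aligned-time windows to blank out.
#' @return data frame: `time_h` (aligned), `mean`, `sem`, `n`.
#' @export
pseudo_align <- function(traces, reference_peak_h, exclude_windows_h = NULL) {
  stop_if_not(length(traces) == length(reference_peak_h),
              "one reference peak per trace required")
  ok <- !is.na(reference_peak_h)
  if (any(!ok))
    warning(sum(!ok), " trace(s) without a reference peak excluded",
            call. = FALSE)
  traces <- traces[ok]
  reference_peak_h <- reference_peak_h[ok]
  stop_if_not(length(traces) >= 2, "need >= 2 traces with reference peaks")

  shifted <- Map(function(tr, ref) {
    list(time = tr$time_h - ref, value = tr$value)
  }, traces, reference_peak_h)
  dt <- max(vapply(traces, function(tr) stats::median(diff(tr$time_h)),
                   numeric(1)))
  lo <- max(vapply(shifted, function(s) min(s$time), numeric(1)))
  hi <- min(vapply(shifted, function(s) max(s$time), numeric(1)))
  stop_if_not(hi > lo, "traces do not overlap after alignment")
  grid <- seq(lo, hi, by = dt)
  vals <- vapply(shifted, function(s) {
    stats::approx(s$time, s$value, xout = grid)$y
  }, numeric(length(grid)))
  out <- data.frame(time_h = grid,
                    mean = rowMeans(vals),
                    sem = apply(vals, 1, stats::sd) / sqrt(ncol(vals)),
                    n = ncol(vals))
  if (!is.null(exclude_windows_h) && nrow(exclude_windows_h)) {
    for (i in seq_len(nrow(exclude_windows_h))) {
      gap <- out$time_h >= exclude_windows_h$start_h[i] &
        out$time_h <= exclude_windows_h$end_h[i]
      out$mean[gap] <- NA_real_
      out$sem[gap] <- NA_real_
    }
  }
  out
}
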