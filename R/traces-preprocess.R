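# Trace preprocessing: baseline detrending and moving-average smoothing.

# epoch lookup helpers: baseline/treatment/washout boundaries from the
# trace's epoch table (first epoch = treatment unless named)
trace_treatment_window <- function(trace) {
  ep <- trace$epochs
  stop_if_not(!is.null(ep) && nrow(ep) >= 1, "trace has no epochs")
  c(start = ep$start_h[1], end = ep$end_h[1])
}

#' Detrend a trace against its baseline interval
#'
#' Fits a least-squares line to the last `baseline_fit_window_h` hours of the
#' baseline interval (the part of the recording before `baseline_end_h`) and
#' subtracts its projection from the trace from the window start onward.
#' Samples before the fit window are left untouched.
#'
#' @param trace a `circadian_trace`.
#' @param baseline_fit_window_h fit window length in hours (default 72).
#' @param baseline_end_h end of the baseline interval; defaults to the start
#'   of the first epoch, or the end of the recording if there are none.
#' @return detrended `circadian_trace`.
#' @export
detrend <- function(trace, baseline_fit_window_h = 72, baseline_end_h = NULL) {
  if (is.null(baseline_end_h)) {
    baseline_end_h <- if (!is.null(trace$epochs) && nrow(trace$epochs))
      min(trace$epochs$start_h) else max(trace$time_h)
  }
  baseline_end_h <- min(baseline_end_h, max(trace$time_h))
  win_start <- baseline_end_h - baseline_fit_window_h
  stop_if_not(win_start >= min(trace$time_h) - 1e-9,
              "baseline interval shorter than the fit window")
  in_win <- trace$time_h >= win_start & trace$time_h <= baseline_end_h
  fit <- stats::lm(v ~ t, data = data.frame(t = trace$time_h[in_win],
                                            v = trace$value[in_win]))
  value <- trace$value
  fwd <- trace$time_h >= win_start
  value[fwd] <- value[fwd] -
    stats::predict(fit, data.frame(t = trace$time_h[fwd]))
  out <- trace
  out$value <- value
  out$detrend_fit <- stats::coef(fit)
  out
}

#' Moving-average smoothing
#'
#' Centered moving average of odd width; the ends use symmetric shrinking
#' windows. At the default imaging interval of 0.5 h, `window_points = 5`
#' corresponds to a 2.5 h average.
#'
#' @param trace a `circadian_trace`.
#' @param window_points odd window width in samples.
#' @return smoothed `circadian_trace`.
#' @export
smooth_trace <- function(trace, window_points = 5) {
  stop_if_not(window_points >= 1 && window_points %% 2 == 1,
              "window_points must be odd and >= 1")
  n <- length(trace$value)
  stop_if_not(window_points <= n, "window longer than the trace")
  half <- (window_points - 1) / 2
  v <- trace$value
  out_v <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)       # shrink symmetrically at the ends
    mean(v[(i - h):(i + h)])
  }, numeric(1))
  out <- trace
  out$value <- out_v
  out
}
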