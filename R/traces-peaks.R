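# Peak/trough detection on oscillatory traces.
#
# Local extrema are screened by topographic prominence (as a fraction of the
# trace's interquartile range) and by a minimum separation; peaks and troughs
# are then interleaved, dropping the lesser of two same-kind neighbours so
# that the final set strictly alternates.

# prominence of local maxima at positions idx in v: height above the higher
# of the two bases (minimum between the peak and the nearest higher sample
# on each side, or the trace end)
peak_prominence <- function(v, idx) {
  vapply(idx, function(i) {
    left <- v[seq_len(i - 1)]
    higher_l <- which(left > v[i])
    lo_l <- min(v[(if (length(higher_l)) max(higher_l) else 1):i])
    right <- v[(i + 1):length(v)]
    higher_r <- which(right > v[i])
    hi_r <- if (length(higher_r)) i + min(higher_r) else length(v)
    lo_r <- min(v[i:hi_r])
    v[i] - max(lo_l, lo_r)
  }, numeric(1))
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# greedy separation filter: keep extrema by decreasing strength, reject any
# within min_sep of an already kept one
enforce_separation <- function(times, strength, min_sep) {
  keep <- logical(length(times))
  for (i in order(strength, decreasing = TRUE)) {
    if (!any(keep & abs(times - times[i]) < min_sep)) keep[i] <- TRUE
  }
  which(keep)
}

#' Detect alternating peaks and troughs
#'
#' @param trace a `circadian_trace` (detect on a smoothed trace for noisy
#'   imaging data; values at the extrema can be re-read from the raw trace).
#' @param min_separation_h minimum spacing between same-kind extrema (hours).
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   trace's interquartile range.
#' @param refine_window_h half-width in hours of the local quadratic fit
#'   used to refine each extremum's time and value (0 disables refinement).
#' @return object of class `peak_set`: list with `peak_times_h`,
#'   `peak_values`, `trough_times_h`, `trough_values` (strictly alternating
#'   in time). Empty with a warning when nothing qualifies.
#' @export
find_peaks_troughs <- function(trace, min_separation_h = 16,
                               min_prominence_frac = 0.2,
                               refine_window_h = 3) {
  v <- trace$value
  t <- trace$time_h
  thr <- min_prominence_frac * stats::IQR(v)

  pk <- local_maxima(v)
  pk <- pk[peak_prominence(v, pk) >= thr]
  tr <- local_maxima(-v)
  tr <- tr[peak_prominence(-v, tr) >= thr]

  if (length(pk))
    pk <- pk[enforce_separation(t[pk], v[pk], min_separation_h)]
  if (length(tr))
    tr <- tr[enforce_separation(t[tr], -v[tr], min_separation_h)]

  if (!length(pk)) {
    warning("no qualifying peak found", call. = FALSE)
    return(structure(list(peak_times_h = numeric(0), peak_values = numeric(0),
                          trough_times_h = numeric(0),
                          trough_values = numeric(0)),
                     class = "peak_set"))
  }

  # enforce alternation: walk the merged event sequence, and of two adjacent
  # same-kind events drop the lesser (lower peak / higher trough)
  ev <- rbind(data.frame(time = t[pk], value = v[pk], kind = "peak"),
              data.frame(time = t[tr], value = v[tr], kind = "trough"))
  ev <- ev[order(ev$time), ]
  repeat {
    same <- which(ev$kind[-1] == ev$kind[-nrow(ev)])
    if (!length(same)) break
    i <- same[1]
    drop <- if (ev$kind[i] == "peak") {
      if (ev$value[i] >= ev$value[i + 1]) i + 1 else i
    } else {
      if (ev$value[i] <= ev$value[i + 1]) i + 1 else i
    }
    ev <- ev[-drop, ]
  }
  if (refine_window_h > 0) {
    ref <- refine_extrema(t, v, ev$time, refine_window_h)
    ev$time <- ref$time
    ev$value <- ref$value
    ev <- ev[order(ev$time), ]
  }
  structure(list(peak_times_h = ev$time[ev$kind == "peak"],
                 peak_values = ev$value[ev$kind == "peak"],
                 trough_times_h = ev$time[ev$kind == "trough"],
                 trough_values = ev$value[ev$kind == "trough"]),
            class = "peak_set")
}

# sub-sample extremum localization: least-squares parabola over a window
# around each detected extremum; the vertex gives the refined time/value.
# Falls back to the grid extremum when the window is degenerate or the
# vertex escapes it.
refine_extrema <- function(t, v, times, half_window_h) {
  out_t <- times
  out_v <- v[vapply(times, function(tt) which.min(abs(t - tt)), integer(1))]
  for (i in seq_along(times)) {
    sel <- abs(t - times[i]) <= half_window_h
    if (sum(sel) < 5) next
    tc <- t[sel] - times[i]
    fit <- stats::lm.fit(cbind(1, tc, tc^2), v[sel])
    a <- fit$coefficients[3]
    if (!is.finite(a) || a == 0) next
    vertex <- -fit$coefficients[2] / (2 * a)
    if (abs(vertex) <= half_window_h) {
      out_t[i] <- times[i] + vertex
      out_v[i] <- fit$coefficients[1] - fit$coefficients[2]^2 / (4 * a)
    }
  }
  list(time = out_t, value = out_v)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks, %d troughs\n",
              length(x$peak_times_h), length(x$trough_times_h)))
  invisible(x)
}

#' Re-read extremum values from another (e.g. raw) trace
#'
#' Keeps the detected extremum times but replaces the stored values with the
#' given trace's values at the nearest samples — used to compute amplitude
#' metrics on the raw signal using smoothed-trace extremum locations.
#'
#' @param peaks a `peak_set`.
#' @param trace the trace to read values from.
#' @return a `peak_set` with updated values.
#' @export
reread_extrema <- function(peaks, trace) {
  near <- function(times) trace$value[vapply(times, function(tt)
    which.min(abs(trace$time_h - tt)), integer(1))]
  peaks$peak_values <- near(peaks$peak_times_h)
  peaks$trough_values <- near(peaks$trough_times_h)
  peaks
}
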