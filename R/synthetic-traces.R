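# Synthetic oscillatory reporter traces with treatment epochs.
#
# The generator emulates two recording modalities: photomultiplier-tube
# bioluminescence (6-min bins, here dt = 0.1 h) and longitudinal fluorescence
# imaging (30-min acquisition interval, dt = 0.5 h). Pharmacological
# treatment/washout is modelled as epochs that scale amplitude, offset phase
# and baseline level, with optional exponential amplitude recovery after the
# epoch ends.

#' Specification for a simulated circadian reporter trace
#'
#' @param duration_h total recording length in hours; must exceed two periods.
#' @param dt_h sampling interval in hours (0.1 for PMT-like, 0.5 for
#'   imaging-like recordings).
#' @param period_h free-running period in hours.
#' @param phase_h time of the first peak in hours.
#' @param amplitude oscillation amplitude in arbitrary units (>= 0).
#' @param damping_per_cycle fractional amplitude loss per elapsed cycle,
#'   in \[0, 1).
#' @param drift_slope,drift_intercept linear baseline drift (units/hour and
#'   units).
#' @param noise_sd standard deviation of additive Gaussian noise (units).
#' @param epochs list of [epoch_effect()] treatment windows; must not overlap.
#' @param seed integer seed; all randomness in [simulate_trace()] derives
#'   from it.
#' @return object of class `trace_sim_spec`.
#' @export
trace_sim_spec <- function(duration_h = 240, dt_h = 0.1, period_h = 24,
                           phase_h = 6, amplitude = 1,
                           damping_per_cycle = 0, drift_slope = 0,
                           drift_intercept = 0, noise_sd = 0.05,
                           epochs = list(), seed = 1L) {
  stop_if_not(duration_h > 2 * period_h, "duration_h must exceed 2 periods")
  stop_if_not(dt_h > 0, "dt_h must be positive")
  stop_if_not(amplitude >= 0, "amplitude must be non-negative")
  stop_if_not(damping_per_cycle >= 0 && damping_per_cycle < 1,
              "damping_per_cycle must be in [0, 1)")
  if (length(epochs)) {
    stop_if_not(all(vapply(epochs, inherits, logical(1), "epoch_effect")),
                "epochs must be a list of epoch_effect objects")
    ord <- order(vapply(epochs, `[[`, numeric(1), "start_h"))
    epochs <- epochs[ord]
    starts <- vapply(epochs, `[[`, numeric(1), "start_h")
    ends <- vapply(epochs, `[[`, numeric(1), "end_h")
    if (length(epochs) > 1 && any(starts[-1] < ends[-length(ends)]))
      stop("epochs overlap", call. = FALSE)
  }
  structure(list(duration_h = duration_h, dt_h = dt_h, period_h = period_h,
                 phase_h = phase_h, amplitude = amplitude,
                 damping_per_cycle = damping_per_cycle,
                 drift_slope = drift_slope, drift_intercept = drift_intercept,
                 noise_sd = noise_sd, epochs = epochs,
                 seed = check_seed(seed)),
            class = "trace_sim_spec")
}

#' Treatment epoch effect for trace simulation
#'
#' @param start_h,end_h epoch window in hours (start < end).
#' @param amplitude_factor multiplicative amplitude scaling inside the epoch
#'   (>= 0; 1 = no effect).
#' @param phase_offset_h phase shift imposed from epoch start onward, in
#'   hours; positive = advance (peaks occur earlier).
#' @param level_offset additive baseline offset inside the epoch (units).
#' @param recovery_halflife_h half-life in hours of the exponential return of
#'   amplitude to baseline after the epoch ends, or `NULL` for an immediate
#'   return.
#' @return object of class `epoch_effect`.
#' @export
epoch_effect <- function(start_h, end_h, amplitude_factor = 1,
                         phase_offset_h = 0, level_offset = 0,
                         recovery_halflife_h = NULL) {
  stop_if_not(start_h < end_h, "epoch start_h must precede end_h")
  stop_if_not(amplitude_factor >= 0, "amplitude_factor must be >= 0")
  structure(list(start_h = start_h, end_h = end_h,
                 amplitude_factor = amplitude_factor,
                 phase_offset_h = phase_offset_h,
                 level_offset = level_offset,
                 recovery_halflife_h = recovery_halflife_h),
            class = "epoch_effect")
}

# time-resolved amplitude scaling / phase offset / level implied by epochs
epoch_modifiers <- function(t, epochs) {
  amp <- rep(1, length(t))
  phase <- rep(0, length(t))
  level <- rep(0, length(t))
  for (ep in epochs) {
    inside <- t >= ep$start_h & t < ep$end_h
    amp[inside] <- amp[inside] * ep$amplitude_factor
    level[inside] <- level[inside] + ep$level_offset
    after <- t >= ep$end_h
    if (any(after) && ep$amplitude_factor != 1) {
      if (is.null(ep$recovery_halflife_h)) {
        # immediate return to pre-epoch amplitude
      } else {
        rec <- 1 - (1 - ep$amplitude_factor) *
          2^(-(t[after] - ep$end_h) / ep$recovery_halflife_h)
        amp[after] <- amp[after] * rec
      }
    }
    # phase offset persists from epoch start onward (positive = advance)
    phase[t >= ep$start_h] <- phase[t >= ep$start_h] + ep$phase_offset_h
  }
  list(amp = amp, phase = phase, level = level)
}

#' Simulate a circadian reporter trace
#'
#' The signal is
#' `drift + A(t) * cos(2*pi*(t - phase_h + offset(t)) / period_h) + level(t) + noise`,
#' where `A(t)` combines per-cycle damping, epoch amplitude scaling and
#' post-epoch exponential recovery, and `offset(t)` accumulates epoch phase
#' offsets (positive = advance, so peaks move earlier).
#'
#' @param spec a [trace_sim_spec()].
#' @return object of class `circadian_trace`: a list with `time_h`, `value`,
#'   `epochs` (data frame), `reporter`, and a `truth` list carrying the
#'   generating period, theoretical peak times and the spec itself.
#' @export
simulate_trace <- function(spec) {
  stop_if_not(inherits(spec, "trace_sim_spec"), "spec must be a trace_sim_spec")
  t <- seq(0, spec$duration_h, by = spec$dt_h)
  mod <- epoch_modifiers(t, spec$epochs)
  damp <- (1 - spec$damping_per_cycle)^(t / spec$period_h)
  amp <- spec$amplitude * damp * mod$amp
  drift <- spec$drift_intercept + spec$drift_slope * t
  # positive phase offset advances the oscillation
  osc <- amp * cos(2 * pi * (t - spec$phase_h + mod$phase) / spec$period_h)
  set.seed(spec$seed)
  noise <- if (spec$noise_sd > 0) stats::rnorm(length(t), 0, spec$noise_sd) else 0
  value <- drift + osc + mod$level + noise

  # ground-truth peak times: phase_h + k*period, shifted earlier by the
  # cumulative phase offset in force at that time
  peaks <- spec$phase_h + spec$period_h * seq(0, ceiling(spec$duration_h / spec$period_h))
  if (length(spec$epochs)) {
    for (ep in spec$epochs) {
      if (ep$phase_offset_h != 0)
        peaks[peaks >= ep$start_h] <- peaks[peaks >= ep$start_h] - ep$phase_offset_h
    }
  }
  peaks <- peaks[peaks >= 0 & peaks <= spec$duration_h]

  new_trace(time_h = t, value = value,
            epochs = epochs_as_df(spec$epochs),
            reporter = "synthetic",
            truth = list(period_h = spec$period_h, peak_times_h = peaks,
                         spec = spec))
}

epochs_as_df <- function(epochs) {
  if (!length(epochs))
    return(data.frame(start_h = numeric(0), end_h = numeric(0),
                      amplitude_factor = numeric(0), phase_offset_h = numeric(0),
                      level_offset = numeric(0), recovery_halflife_h = numeric(0)))
  do.call(rbind, lapply(epochs, function(ep) {
    data.frame(start_h = ep$start_h, end_h = ep$end_h,
               amplitude_factor = ep$amplitude_factor,
               phase_offset_h = ep$phase_offset_h,
               level_offset = ep$level_offset,
               recovery_halflife_h = ep$recovery_halflife_h %||% NA_real_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a trace object
#'
#' @param time_h strictly increasing sampling times in hours.
#' @param value signal values.
#' @param epochs optional data frame of named intervals (needs `start_h`,
#'   `end_h` columns at minimum).
#' @param reporter reporter label (e.g. `"PER2::LUC"`, `"jRCaMP1a"`).
#' @param truth optional ground-truth list (synthetic traces only).
#' @return object of class `circadian_trace`.
#' @export
new_trace <- function(time_h, value, epochs = NULL, reporter = "unknown",
                      truth = NULL) {
  stop_if_not(length(time_h) == length(value), "time_h/value length mismatch")
  stop_if_not(all(diff(time_h) > 0), "time_h must be strictly increasing")
  structure(list(time_h = as.numeric(time_h), value = as.numeric(value),
                 epochs = epochs, reporter = reporter, truth = truth),
            class = "circadian_trace")
}

#' @export
print.circadian_trace <- function(x, ...) {
  cat(sprintf("<circadian_trace> %s: %d samples over %.1f h (dt = %.3g h)\n",
              x$reporter, length(x$time_h), diff(range(x$time_h)),
              stats::median(diff(x$time_h))))
  if (!is.null(x$epochs) && nrow(x$epochs))
    cat(sprintf("  epochs: %s\n",
                paste(sprintf("[%g, %g)", x$epochs$start_h, x$epochs$end_h),
                      collapse = " ")))
  invisible(x)
}

#' Write / read a trace as CSV plus sidecar JSON
#'
#' The CSV has header `time_h,value`; epochs and any ground truth go to a
#' sidecar JSON file alongside.
#'
#' @param trace a `circadian_trace`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `circadian_trace`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_h = trace$time_h, value = trace$value),
                   path, row.names = FALSE, quote = FALSE)
  side <- list(reporter = trace$reporter)
  if (!is.null(trace$epochs)) side$epochs <- trace$epochs
  if (!is.null(trace$truth))
    side$truth <- list(period_h = trace$truth$period_h,
                       peak_times_h = trace$truth$peak_times_h)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @param path CSV path written by [write_trace()].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  epochs <- NULL; reporter <- "unknown"; truth <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    reporter <- side$reporter %||% "unknown"
    if (!is.null(side$epochs)) epochs <- as.data.frame(side$epochs)
    if (!is.null(side$truth)) truth <- side$truth
  }
  new_trace(df$time_h, df$value, epochs = epochs, reporter = reporter,
            truth = truth)
}
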