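# Trace analytics: preprocessing, peak detection, cycle metrics, cosine
# fitting, circular statistics, CT assignment, integration and alignment.

line_trace <- function(slope = 2, intercept = 5, dur = 100, dt = 0.5,
                       extra = 0) {
  t <- seq(0, dur, dt)
  # the cosine (when present) is phased symmetrically about the centre of
  # the 72-h fit window [8, 80], so the line fit is unbiased by it
  new_trace(t, intercept + slope * t + extra * cos(2 * pi * (t - 44) / 24),
            epochs = data.frame(start_h = 80, end_h = 100))
}

test_that("detrending removes a pure line and preserves an added cosine", {
  tr <- detrend(line_trace(), baseline_fit_window_h = 72)
  proj <- tr$time_h >= 8
  expect_equal(tr$value[proj], rep(0, sum(proj)), tolerance = 1e-9)

  tr2 <- detrend(line_trace(extra = 1), baseline_fit_window_h = 72)
  proj2 <- tr2$time_h >= 8
  expect_equal(tr2$value[proj2],
               cos(2 * pi * (tr2$time_h[proj2] - 44) / 24),
               tolerance = 0.02)
  expect_error(detrend(line_trace(dur = 50), baseline_fit_window_h = 72),
               "shorter")
})

test_that("detrend recovers the generator's drift slope", {
  sp <- trace_sim_spec(duration_h = 120, dt_h = 0.1, drift_slope = 0.8,
                       drift_intercept = 3, noise_sd = 0.05, seed = 2)
  tr <- detrend(simulate_trace(sp), baseline_fit_window_h = 72)
  expect_lt(abs(tr$detrend_fit[["t"]] - 0.8), 0.05)
})

test_that("moving-average smoothing behaves like an averaging kernel", {
  tr <- new_trace(1:11, rep(4, 11))
  expect_equal(smooth_trace(tr, 5)$value, rep(4, 11))
  spike <- new_trace(1:5, c(0, 0, 5, 0, 0))
  expect_equal(smooth_trace(spike, 5)$value[3], 1)
  set.seed(3)
  noisy <- new_trace(1:200, rnorm(200))
  once <- smooth_trace(noisy, 5)
  twice <- smooth_trace(once, 5)
  expect_lte(stats::var(once$value), stats::var(noisy$value))
  expect_lte(stats::var(twice$value), stats::var(once$value))
  expect_error(smooth_trace(spike, 4), "odd")
  expect_error(smooth_trace(spike, 7), "longer")
})

test_that("peak detection finds noiseless cosine extrema and enforces rules", {
  tr <- simulate_trace(trace_sim_spec(duration_h = 120, dt_h = 0.1,
                                      phase_h = 6, noise_sd = 0, seed = 1))
  pk <- find_peaks_troughs(tr)
  expect_equal(pk$peak_times_h, c(6, 30, 54, 78, 102), tolerance = 0.05)
  # alternation invariant
  ev <- sort(c(pk$peak_times_h, pk$trough_times_h))
  kinds <- ifelse(ev %in% pk$peak_times_h, "p", "t")
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))

  # two close peaks: the lower one is dropped by the separation rule
  t <- seq(0, 48, 0.1)
  v <- exp(-(t - 20)^2 / 4) + 0.6 * exp(-(t - 30)^2 / 4)
  pk2 <- find_peaks_troughs(new_trace(t, v), min_separation_h = 16)
  expect_equal(length(pk2$peak_times_h), 1)
  expect_lt(abs(pk2$peak_times_h - 20), 0.5)

  # flat trace: empty set with warning
  expect_warning(pkf <- find_peaks_troughs(new_trace(t, rep(1, length(t)))),
                 "no qualifying peak")
  expect_equal(length(pkf$peak_times_h), 0)
})

test_that("noisy peak times stay within half an hour of the generator truth", {
  sp <- trace_sim_spec(duration_h = 124, dt_h = 0.1, phase_h = 6,
                       noise_sd = 0.05, seed = 8)
  tr <- simulate_trace(sp)
  pk <- find_peaks_troughs(smooth_trace(tr, 5))
  truth <- tr$truth$peak_times_h
  matched <- vapply(pk$peak_times_h, function(p) min(abs(truth - p)),
                    numeric(1))
  expect_lt(max(matched), 0.5)
})

test_that("period arithmetic follows the stated rules", {
  pk <- structure(list(peak_times_h = c(0, 24, 48),
                       peak_values = c(1, 1, 1),
                       trough_times_h = c(12, 36), trough_values = c(-1, -1)),
                  class = "peak_set")
  expect_equal(compute_period(pk), 24)
  expect_warning(p1 <- compute_period(pk, c(0, 10)), "undefined")
  expect_true(is.na(p1))
  pk2 <- structure(list(peak_times_h = c(100, 124.8, 149.6),
                        peak_values = rep(1, 3),
                        trough_times_h = c(112, 137), trough_values = c(-1, -1)),
                   class = "peak_set")
  expect_equal(compute_period(pk2), 24.8)
})

test_that("phase shift follows the second-peak extrapolation rule", {
  # last pre-treatment peak at 100 h, baseline period 24 h, observed second
  # post-treatment peak at 151 h: predicted 148, shift -3 (delay)
  pk <- structure(list(peak_times_h = c(76, 100, 127, 151),
                       peak_values = rep(1, 4),
                       trough_times_h = c(88, 112, 139),
                       trough_values = rep(-1, 3)),
                  class = "peak_set")
  expect_equal(phase_shift(pk, baseline_period_h = 24, treatment_start_h = 110),
               -3)
  expect_warning(s <- phase_shift(pk, 24, 150), "post-treatment")
  expect_true(is.na(s))
})

test_that("cycle amplitudes normalize to the last baseline cycle", {
  ep <- epoch_effect(72, 240, amplitude_factor = 0.15)
  tr <- simulate_trace(trace_sim_spec(duration_h = 240, dt_h = 0.1,
                                      noise_sd = 0, epochs = list(ep),
                                      seed = 1))
  pk <- find_peaks_troughs(tr, min_prominence_frac = 0.05)
  amps <- cycle_amplitudes(pk, treatment_start_h = 72)
  full <- amps[amps$peak_time_h >= 96 & amps$trough_time_h >= 72, ]
  expect_equal(mean(full$norm_amplitude), 0.15, tolerance = 0.01)
  # scale invariance: doubling the units leaves normalized amplitudes alone
  tr2 <- tr; tr2$value <- 2 * tr$value
  amps2 <- cycle_amplitudes(find_peaks_troughs(tr2, min_prominence_frac = 0.05),
                            treatment_start_h = 72)
  expect_equal(amps2$norm_amplitude, amps$norm_amplitude, tolerance = 1e-9)
})

test_that("B/A ratio is 1 for stationary cycles and below 1 while growing", {
  tr <- simulate_trace(trace_sim_spec(duration_h = 120, dt_h = 0.1,
                                      noise_sd = 0, seed = 1))
  ba <- ba_ratio(find_peaks_troughs(tr))
  expect_equal(ba$ba_ratio, rep(1, nrow(ba)), tolerance = 1e-3)

  # amplitude growing ~20% per cycle: rising amplitude < falling amplitude
  t <- seq(0, 120, 0.1)
  v <- 1.2^(t / 24) * cos(2 * pi * (t - 6) / 24)
  ba2 <- ba_ratio(find_peaks_troughs(new_trace(t, v)))
  expect_true(all(ba2$ba_ratio < 1))
})

test_that("post-washout recovery drives B/A monotonically toward 1", {
  ep <- epoch_effect(96, 168, amplitude_factor = 0.1,
                     recovery_halflife_h = 24)
  tr <- simulate_trace(trace_sim_spec(duration_h = 288, dt_h = 0.1,
                                      noise_sd = 0.02, epochs = list(ep),
                                      seed = 12))
  pk <- find_peaks_troughs(smooth_trace(tr, 5), min_prominence_frac = 0.05)
  ba <- ba_ratio(pk)
  post <- ba$ba_ratio[ba$peak_time_h > 168]
  expect_gte(length(post), 3)
  expect_true(all(diff(post) > 0))
  expect_true(all(post < 1.02))
  ss <- steady_state_ba(pk, washout_start_h = 168)
  expect_equal(ss, post[2])
})

test_that("cosine fits recover parameters and the RAE limits hold", {
  tr <- simulate_trace(trace_sim_spec(duration_h = 120, dt_h = 0.5,
                                      period_h = 24.8, phase_h = 5,
                                      noise_sd = 0, seed = 1))
  fit <- fit_fft_nlls(tr)
  expect_equal(fit$period_h, 24.8, tolerance = 0.01)
  expect_equal(fit$amplitude, 1, tolerance = 0.01)
  expect_lte(rae(fit), 0.01)

  set.seed(2)
  wn <- new_trace(seq(0, 120, 0.5), rnorm(241))
  expect_gte(rae(fit_fft_nlls(wn)), 0.8)
  expect_error(fit_fft_nlls(subset_trace(tr, 0, 20)), "2 cycles")
})

test_that("RAE grows monotonically with noise", {
  noise <- c(0.02, 0.1, 0.3, 0.8, 2)
  raes <- vapply(seq_along(noise), function(i) {
    tr <- simulate_trace(trace_sim_spec(duration_h = 120, dt_h = 0.5,
                                        noise_sd = noise[i], seed = 40 + i))
    rae(fit_fft_nlls(tr))
  }, numeric(1))
  expect_true(all(diff(raes) > 0) || stats::cor(noise, raes, method = "spearman") == 1)
})

test_that("rayleigh statistics match circular expectations", {
  r1 <- rayleigh(rep(13.2, 8))
  expect_equal(r1$R, 1)
  expect_equal(r1$mean_phase_ct, 13.2, tolerance = 1e-9)
  expect_lt(r1$p, 1e-3)
  r0 <- rayleigh(c(0, 6, 12, 18))
  expect_equal(r0$R, 0, tolerance = 1e-12)
  expect_error(rayleigh(5), ">= 2")
  # the series approximation agrees with exp(-Z) to leading order at large n
  ph <- c(rep(3, 30), rep(9, 10))
  rr <- rayleigh(ph)
  expect_equal(rr$p, exp(-40 * rr$R^2), tolerance = 0.05)
})

test_that("circadian time assignment anchors the reference peak", {
  expect_equal(assign_ct(10, reference_peak_time_h = 10), 6)
  expect_equal(assign_ct(22, reference_peak_time_h = 10), 18)  # antiphase
  # astro-like peak 11 h after the neuronal reference maps near CT17
  expect_equal(assign_ct(21, reference_peak_time_h = 10), 17)
  ct <- assign_ct(seq(0, 48, 0.5), 10, period_h = 24)
  expect_true(all(ct >= 0 & ct < 24))
})

test_that("24-h integrals follow linearity and orthogonality", {
  t <- seq(0, 72, 0.5)
  expect_equal(integrate_24h(new_trace(t, rep(1, length(t))))$integral,
               rep(24, 3))
  zc <- integrate_24h(new_trace(t, cos(2 * pi * t / 24)))
  expect_equal(zc$integral, rep(0, 3), tolerance = 1e-9)
  # step increase between windows shifts the integral by step x 24
  step <- ifelse(t < 24, 0, 2)
  si <- integrate_24h(new_trace(t, step))$integral
  expect_equal(si[2] - si[1], 2 * 24, tolerance = 0.6)  # edge sample spans the step
  expect_error(integrate_24h(new_trace(1:10, 1:10)), "24-h window")
})

test_that("pseudo-alignment coincides identical traces and recovers the period", {
  t <- seq(0, 96, 0.5)
  v <- cos(2 * pi * (t - 6) / 24)
  tr <- new_trace(t, v)
  al <- pseudo_align(list(tr, tr, tr), reference_peak_h = c(6, 6, 6))
  expect_equal(al$sem, rep(0, nrow(al)))
  # two traces offset by 3 h coincide after shifting
  tr2 <- new_trace(t, cos(2 * pi * (t - 9) / 24))
  al2 <- pseudo_align(list(tr, tr2), reference_peak_h = c(6, 9))
  expect_equal(max(al2$sem, na.rm = TRUE), 0, tolerance = 1e-9)

  # seeded cohort: mean profile period within 0.2 h of the generator value
  cohort <- lapply(1:6, function(s)
    simulate_trace(trace_sim_spec(duration_h = 124, dt_h = 0.5,
                                  period_h = 24.8, phase_h = 2 + s,
                                  noise_sd = 0.05, seed = 50 + s)))
  refs <- vapply(cohort, function(tr) {
    find_peaks_troughs(smooth_trace(tr, 5))$peak_times_h[1]
  }, numeric(1))
  al3 <- pseudo_align(cohort, refs)
  prof <- new_trace(al3$time_h, al3$mean)
  expect_lt(abs(compute_period(find_peaks_troughs(prof)) - 24.8), 0.2)

  # excluded windows become gaps; missing reference peaks drop the trace
  al4 <- pseudo_align(list(tr, tr2), c(6, 9),
                      exclude_windows_h = data.frame(start_h = 10, end_h = 14))
  expect_true(all(is.na(al4$mean[al4$time_h >= 10 & al4$time_h <= 14])))
  expect_warning(pseudo_align(list(tr, tr, tr2), c(6, NA, 9)), "excluded")
})

test_that("cycle metrics are invariant to affine rescaling of the signal", {
  ep <- list(epoch_effect(120, 192, amplitude_factor = 0.15,
                          phase_offset_h = 2, recovery_halflife_h = 24))
  tr <- simulate_trace(trace_sim_spec(duration_h = 288, dt_h = 0.1,
                                      period_h = 24.8, noise_sd = 0.02,
                                      epochs = ep, seed = 13))
  tr_scaled <- tr
  tr_scaled$value <- 3.7 * tr$value + 11
  m1 <- cycle_metrics(tr, min_prominence_frac = 0.05)
  m2 <- cycle_metrics(tr_scaled, min_prominence_frac = 0.05)
  expect_equal(m1$period_baseline_h, m2$period_baseline_h, tolerance = 1e-6)
  expect_equal(m1$phase_shift_h, m2$phase_shift_h, tolerance = 1e-6)
  expect_equal(m1$norm_amplitude_treatment, m2$norm_amplitude_treatment,
               tolerance = 1e-6)
  expect_equal(m1$steady_state_ba, m2$steady_state_ba, tolerance = 1e-5)
  expect_equal(m1$rae_baseline, m2$rae_baseline, tolerance = 1e-4)
})
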