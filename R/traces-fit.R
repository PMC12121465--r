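# Cosine fitting, relative amplitude error and circular phase statistics.

#' Fit a linear-detrended cosine by FFT-initialized nonlinear least squares
#'
#' Model: `offset + slope * t + A * cos(2*pi*(t - phi) / tau)`. The period,
#' amplitude and phase are initialized from the discrete-Fourier component
#' with the largest amplitude whose period lies within `period_window_h`,
#' then refined by Levenberg-Marquardt least squares with the period
#' constrained to the window.
#'
#' @param trace a `circadian_trace` (or any list with `time_h`, `value`).
#' @param period_window_h admissible circadian period range in hours.
#' @return object of class `nlls_fit`: list with `offset`, `slope`,
#'   `amplitude`, `period_h`, `phase_h`, `amplitude_se` (curvature-based),
#'   `converged`, `fit` (the underlying `nls` object or `NULL`).
#' @export
fit_fft_nlls <- function(trace, period_window_h = c(18, 30)) {
  t <- trace$time_h
  v <- trace$value
  stop_if_not(diff(range(t)) >= 2 * period_window_h[1],
              "need >= 2 cycles of data")
  # linear trend for initialization
  lt <- stats::lm(v ~ t)
  res <- stats::resid(lt)
  n <- length(v)
  dt <- stats::median(diff(t))
  # discrete Fourier spectrum of the residual on the regular grid
  sp <- stats::fft(res)
  freq <- seq(0, n - 1) / (n * dt)
  half <- 2:floor(n / 2 + 1)
  periods <- 1 / freq[half]
  in_win <- periods >= period_window_h[1] & periods <= period_window_h[2]
  amp_sp <- 2 * Mod(sp[half]) / n
  if (!any(in_win)) {
    # fall back to the closest in-band frequency
    in_win <- rep(FALSE, length(periods))
    in_win[which.min(abs(periods - mean(period_window_h)))] <- TRUE
  }
  k <- half[in_win][which.max(amp_sp[in_win])]
  tau0 <- 1 / freq[k]
  A0 <- 2 * Mod(sp[k]) / n
  # cos(2*pi*(t - phi)/tau): phase of the component at t = 0
  phi0 <- (-Arg(sp[k]) * tau0 / (2 * pi) + t[1]) %% tau0

  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ offset + slope * t + A * cos(2 * pi * (t - phi) / tau),
      start = list(offset = unname(stats::coef(lt)[[1]]),
                   slope = unname(stats::coef(lt)[[2]]),
                   A = unname(max(A0, 1e-12)), phi = unname(phi0),
                   tau = unname(tau0)),
      lower = c(-Inf, -Inf, 0, -Inf, period_window_h[1]),
      upper = c(Inf, Inf, Inf, Inf, period_window_h[2]),
      data = data.frame(t = t, v = v),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(offset = NA_real_, slope = NA_real_,
                          amplitude = NA_real_, period_h = NA_real_,
                          phase_h = NA_real_, amplitude_se = NA_real_,
                          converged = FALSE, fit = NULL),
                     class = "nlls_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["A"]], error = function(e) NA_real_)
  structure(list(offset = cf[["offset"]], slope = cf[["slope"]],
                 amplitude = cf[["A"]], period_h = cf[["tau"]],
                 phase_h = cf[["phi"]] %% cf[["tau"]],
                 amplitude_se = se, converged = TRUE, fit = fit),
            class = "nlls_fit")
}

#' Relative amplitude error of a cosine fit
#'
#' RAE is the half-width of the 95% confidence interval on the fitted
#' amplitude divided by the amplitude, clipped to \[0, 1\]: 0 for a perfect
#' rhythm, 1 for no detectable rhythm. A diverged fit reports RAE 1.
#'
#' @param fit an `nlls_fit` from [fit_fft_nlls()].
#' @return RAE in \[0, 1\].
#' @export
rae <- function(fit) {
  if (!isTRUE(fit$converged) || !is.finite(fit$amplitude_se) ||
      fit$amplitude <= 0)
    return(1)
  df <- tryCatch(stats::df.residual(fit$fit), error = function(e) Inf)
  half_ci <- stats::qt(0.975, df) * fit$amplitude_se
  max(0, min(1, half_ci / fit$amplitude))
}

#' @rdname rae
#' @param treatment_rae,baseline_rae RAE values for the treatment and
#'   baseline intervals.
#' @return `rae_normalized`: treatment RAE / baseline RAE.
#' @export
rae_normalized <- function(treatment_rae, baseline_rae) {
  stop_if_not(baseline_rae > 0, "baseline RAE must be positive")
  treatment_rae / baseline_rae
}

#' Rayleigh test of circular phase concentration
#'
#' Phases in CT hours are mapped to angles `2*pi*CT/24`; R is the mean
#' resultant length and the p-value uses the standard series approximation
#' `p = exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`
#' with `Z = n R^2`.
#'
#' @param phases_ct numeric vector of phases in hours (mod 24), length >= 2.
#' @return list: `R` (in \[0, 1\]), `p`, `mean_phase_ct`, `n`.
#' @export
rayleigh <- function(phases_ct) {
  n <- length(phases_ct)
  stop_if_not(n >= 2, "need >= 2 phases")
  theta <- 2 * pi * (phases_ct %% 24) / 24
  C <- mean(cos(theta)); S <- mean(sin(theta))
  R <- sqrt(C^2 + S^2)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- max(0, min(1, p))
  mean_phase <- (atan2(S, C) * 24 / (2 * pi)) %% 24
  list(R = R, p = p, mean_phase_ct = mean_phase, n = n)
}
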