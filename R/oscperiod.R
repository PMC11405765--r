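#' Wavelet analysis settings for clock-period extraction
#'
#' Defaults follow standard practice for ~50-70 min segmentation-clock
#' oscillations sampled every 10 min: detrend cutoff period 100 min,
#' amplitude-envelope window 150 min, and 200 scanned periods spanning
#' 40-100 min.
#'
#' @param interval_min sampling interval (min).
#' @param cutoff_min detrending cutoff period (min); components slower
#'   than this are removed.
#' @param window_min sliding-window length for envelope normalization (min).
#' @param pmin_min,pmax_min smallest and largest scanned period (min).
#' @param n_periods number of periods scanned (linear spacing).
#' @param omega0 Morlet base angular frequency (default 6).
#' @return object of class `wavelet_settings`.
#' @export
wavelet_settings <- function(interval_min = 10, cutoff_min = 100,
                             window_min = 150, pmin_min = 40,
                             pmax_min = 100, n_periods = 200,
                             omega0 = 6) {
  if (pmin_min >= pmax_min) stop("pmin must be < pmax")
  if (n_periods < 2) stop("need at least 2 scanned periods")
  if (cutoff_min <= 2 * interval_min) stop("cutoff must exceed 2 * interval")
  structure(list(interval = interval_min, cutoff = cutoff_min,
                 window = window_min, pmin = pmin_min, pmax = pmax_min,
                 n_periods = as.integer(n_periods), omega0 = omega0),
            class = "wavelet_settings")
}

# Windowed-sinc (Blackman) low-pass: fc in cycles per sample. Kernel spans
# the whole trace (odd number of taps). Edges are padded by point
# reflection through the endpoints (2*x[end] - x), which continues any
# linear trend exactly and so keeps ramp-like baselines artifact-free.
sinc_lowpass <- function(x, fc) {
  n <- length(x)
  M <- if (n %% 2 == 1) n else n - 1
  half <- (M - 1) / 2
  k <- seq(-half, half)
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  w <- 0.42 + 0.5 * cos(2 * pi * k / (M - 1)) + 0.08 * cos(4 * pi * k / (M - 1))
  h <- h * w
  h <- h / sum(h)
  xp <- c(2 * x[1] - x[rev(seq_len(half) + 1)], x,
          2 * x[n] - x[n - seq_len(half)])
  as.numeric(stats::filter(xp, h, method = "convolution", sides = 2))[half + seq_len(n)]
}

#' Remove slow trends from an oscillatory trace
#'
#' Subtracts a windowed-sinc low-pass estimate of the trend, removing all
#' components with period longer than `cutoff_min` (including the mean and
#' any slow fluorescence drift or bleaching baseline).
#'
#' @param trace an `osc_trace` (or data.frame `time_min`, `intensity`).
#' @param cutoff_min cutoff period in minutes (> 2 sampling intervals).
#' @return the trace with detrended `intensity`.
#' @export
detrend_trace <- function(trace, cutoff_min = 100) {
  dt <- trace_interval(trace)
  if (cutoff_min <= 2 * dt) stop("cutoff period is unresolvable at this sampling interval")
  if (nrow(trace) < 4) stop("trace too short to detrend")
  trend <- sinc_lowpass(trace$intensity, fc = dt / cutoff_min)
  out <- trace
  out$intensity <- trace$intensity - trend
  out
}

trace_interval <- function(trace) {
  iv <- attr(trace, "interval")
  if (is.null(iv)) iv <- stats::median(diff(trace$time_min))
  iv
}

#' Normalize a detrended trace by its sliding-window amplitude envelope
#'
#' The envelope is sqrt(2) times the root-mean-square of the detrended
#' signal in a centred sliding window (for a sinusoid of amplitude A this
#' is A), so the normalized oscillation has amplitude ~1 wherever signal
#' is present. Windows are truncated at the trace edges.
#'
#' @param trace a detrended `osc_trace`.
#' @param window_min window length in minutes.
#' @return the trace with unit-amplitude `intensity`.
#' @export
normalize_envelope <- function(trace, window_min = 150) {
  dt <- trace_interval(trace)
  x <- trace$intensity
  n <- length(x)
  half <- max(1L, floor(window_min / dt / 2))
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  env <- sqrt(2 * (cs[hi + 1] - cs[lo]) / (hi - lo + 1))
  if (max(env) < 1e-12) stop("zero envelope: trace carries no signal")
  env <- pmax(env, 1e-12 * max(env))
  out <- trace
  out$intensity <- x / env
  out
}

#' Continuous Morlet wavelet transform and ridge extraction
#'
#' Evaluates Morlet wavelet power on `n_periods` linearly spaced periods
#' between `pmin` and `pmax`, takes the per-timepoint maximum-power ridge,
#' and flags samples inside the cone of influence (further than the
#' wavelet e-folding time, sqrt(2) x scale, from either trace edge) as
#' reliable.
#'
#' @param trace a detrended, envelope-normalized `osc_trace`.
#' @param settings a `wavelet_settings`.
#' @return object of class `period_estimate`: data.frame `time_min`,
#'   `period`, `power`, `phase`, `amplitude`, `in_coi`.
#' @export
cwt_ridge <- function(trace, settings = wavelet_settings()) {
  stopifnot(inherits(settings, "wavelet_settings"))
  dt <- trace_interval(trace)
  x <- trace$intensity
  n <- length(x)
  if ((n - 1) * dt < settings$pmax) {
    stop("trace shorter than one cycle of the largest scanned period")
  }
  w0 <- settings$omega0
  fourier_factor <- 4 * pi / (w0 + sqrt(2 + w0^2))
  periods <- seq(settings$pmin, settings$pmax, length.out = settings$n_periods)
  scales <- periods / fourier_factor

  npad <- 2^ceiling(log2(2 * n))
  xf <- stats::fft(c(x - mean(x), rep(0, npad - n)))
  k <- seq_len(npad) - 1
  omega <- ifelse(k <= npad / 2, k, k - npad) * 2 * pi / (npad * dt)

  W <- matrix(0 + 0i, settings$n_periods, n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi_hat <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-((s * omega - w0)^2) / 2) * (omega > 0)
    Wj <- stats::fft(xf * psi_hat, inverse = TRUE) / npad
    W[j, ] <- Wj[seq_len(n)]
  }
  # power normalized by the trace variance (white noise of any scale then
  # has expectation ~1 at every scale), so ridge power is comparable
  # across traces and usable as a confidence measure
  pow <- Mod(W)^2 / stats::var(x)
  ridge <- max.col(t(pow), ties.method = "first")
  tsec <- trace$time_min
  edge_dist <- pmin(tsec - tsec[1], tsec[n] - tsec)
  idx <- cbind(ridge, seq_len(n))
  est <- data.frame(
    time_min = tsec,
    period = periods[ridge],
    power = pow[idx],
    phase = Arg(W[idx]),
    amplitude = Mod(W[idx]) / sqrt(scales[ridge]),
    in_coi = edge_dist >= sqrt(2) * scales[ridge]
  )
  attr(est, "settings") <- settings
  class(est) <- c("period_estimate", "data.frame")
  est
}

#' Summarize a ridge-period series into mean and intercept periods
#'
#' Restricted to samples inside the cone of influence, takes the first
#' `window_min` minutes (anchored at the first reliable sample) and
#' returns the arithmetic mean period and the y-intercept of an ordinary
#' least-squares line fitted to period versus time-within-window.
#'
#' @param est a `period_estimate`.
#' @param window_min summary window length (default 300 min).
#' @return named numeric vector `mean_period`, `intercept_period` (min).
#' @export
summarize_period <- function(est, window_min = 300) {
  stopifnot(inherits(est, "period_estimate"))
  ok <- est[est$in_coi, , drop = FALSE]
  if (nrow(ok) < 2) stop("fewer than 2 samples inside the cone of influence")
  t0 <- ok$time_min[1]
  win <- ok[ok$time_min <= t0 + window_min, , drop = FALSE]
  if (nrow(win) < 2) stop("fewer than 2 reliable samples in the summary window")
  fit <- stats::lm.fit(cbind(1, win$time_min - t0), win$period)
  c(mean_period = mean(win$period),
    intercept_period = unname(fit$coefficients[1]))
}

#' End-to-end period extraction from a raw trace
#'
#' Chains [detrend_trace()], [normalize_envelope()], [cwt_ridge()] and
#' [summarize_period()] with one settings object.
#'
#' @param trace a raw `osc_trace`.
#' @param settings a `wavelet_settings`.
#' @param window_min summary window (min).
#' @return list `estimate` (the `period_estimate`) and `summary`
#'   (mean/intercept periods).
#' @export
extract_period <- function(trace, settings = wavelet_settings(),
                           window_min = 300) {
  d <- detrend_trace(trace, settings$cutoff)
  nrm <- normalize_envelope(d, settings$window)
  est <- cwt_ridge(nrm, settings)
  list(estimate = est, summary = summarize_period(est, window_min))
}
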