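# Pulse rate variability: pulse detection from PPG, spline resampling of
# the interval series, averaged Blackman-windowed spectra, band powers.

#' Detect pulses in a PPG trace
#'
#' Band-pass prefilter (0.5-8 Hz Butterworth, zero-phase), local-maximum
#' search with an adaptive amplitude threshold, and a 0.3 s refractory
#' interval (keeping the larger peak of any conflicting pair). Detected
#' intervals are screened by an automatic beat-quality rule: any interval
#' outside 0.33-2.0 s, or differing by more than 40% from its predecessor,
#' fails the recording.
#'
#' @param trace a `signal_trace` with modality PPG, at least 60 s long.
#' @param quality_gate apply the interval plausibility screen.
#' @return object of class `pulse_interval_series`: list with
#'   `pulse_times` (s) and `intervals` (ms).
#' @export
detect_pulses <- function(trace, quality_gate = TRUE) {
  stopifnot(inherits(trace, "signal_trace"), trace$modality == "PPG")
  fs <- trace$sampling_rate
  if (trace_duration(trace) < 60) stop("need at least 60 s of PPG")
  x <- trace$samples
  bp <- signal::butter(2, c(0.5, 8) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x - mean(x))
  n <- length(xf)
  is_max <- c(FALSE, xf[2:(n - 1)] > xf[1:(n - 2)] &
                xf[2:(n - 1)] >= xf[3:n], FALSE)
  thr <- 0.4 * stats::quantile(xf[is_max], 0.9, names = FALSE)
  cand <- which(is_max & xf > thr)
  # enforce refractory: greedy keep-largest
  ord <- cand[order(-xf[cand])]
  keep <- logical(n)
  blocked <- logical(n)
  ref <- round(0.3 * fs)
  for (i in ord) {
    if (!blocked[i]) {
      keep[i] <- TRUE
      blocked[max(1, i - ref):min(n, i + ref)] <- TRUE
    }
  }
  pk <- which(keep)
  if (length(pk) < 30) {
    stop(sprintf("pulse detection quality failure: only %d pulses found",
                 length(pk)))
  }
  # parabolic sub-sample refinement of each peak time: the 32 Hz sample
  # grid would otherwise alias ~15 ms of quantization jitter into the
  # interval series
  delta <- vapply(pk, function(i) {
    if (i <= 1 || i >= n) return(0)
    den <- xf[i - 1] - 2 * xf[i] + xf[i + 1]
    if (den >= 0) return(0)
    d <- 0.5 * (xf[i - 1] - xf[i + 1]) / den
    max(-0.5, min(0.5, d))
  }, numeric(1))
  times <- (pk - 1 + delta) / fs
  iv <- diff(times) * 1000
  if (quality_gate) {
    bad_range <- iv < 330 | iv > 2000
    rel <- abs(diff(iv)) / iv[-length(iv)]
    bad_jump <- c(FALSE, rel > 0.4)
    if (any(bad_range | bad_jump)) {
      stop(sprintf("beat quality failure: %d implausible interval(s)",
                   sum(bad_range | bad_jump)))
    }
  }
  structure(list(pulse_times = times, intervals = iv),
            class = "pulse_interval_series")
}

#' @export
print.pulse_interval_series <- function(x, ...) {
  cat(sprintf("<pulse_interval_series> %d pulses over %.1f s, mean interval %.0f ms\n",
              length(x$pulse_times), diff(range(x$pulse_times)),
              mean(x$intervals)))
  invisible(x)
}

#' Resample the interval series onto a uniform grid
#'
#' Cubic-spline interpolation of interval (ms) against time (each interval
#' anchored at its ending pulse), evaluated on a uniform grid spanning the
#' pulse-time range. A 4 Hz grid is the conventional rate for spectral
#' analysis of beat intervals.
#'
#' @param series a `pulse_interval_series`.
#' @param target_rate grid rate in Hz.
#' @return list with `t` (s), `x` (ms) and `rate` (Hz).
#' @export
resample_intervals <- function(series, target_rate = 4) {
  stopifnot(inherits(series, "pulse_interval_series"))
  if (length(series$intervals) < 4) {
    stop("need at least 4 intervals for cubic spline resampling")
  }
  ta <- series$pulse_times[-1]
  grid <- seq(ta[1], ta[length(ta)], by = 1 / target_rate)
  sp <- stats::spline(ta, series$intervals, xout = grid, method = "fmm")
  list(t = grid, x = sp$y, rate = target_rate)
}

#' Averaged spectrum of the resampled interval signal
#'
#' Mean-removed signal, 256-point segments with 50% overlap, Blackman
#' window, FFT per segment, averaged one-sided power. At 4 Hz a 256-point
#' segment spans 64 s, giving 0.0156 Hz resolution — enough to separate
#' the LF band edge at 0.045 Hz from DC.
#'
#' @param interval_signal list as returned by [resample_intervals()].
#' @param nwindow segment length in samples.
#' @return a `spectral_estimate` (power in ms^2 per Hz).
#' @export
prv_spectrum <- function(interval_signal, nwindow = 256) {
  if (length(interval_signal$x) < nwindow) {
    stop(sprintf("interval signal has %d samples, need >= %d (%.0f s at %g Hz)",
                 length(interval_signal$x), nwindow,
                 nwindow / interval_signal$rate, interval_signal$rate))
  }
  welch_psd(interval_signal$x, interval_signal$rate, nwindow)
}

#' PRV band-power indices
#'
#' Trapezoidal band integration of the interval spectrum: LF over
#' [0.045, 0.15) Hz, HF over [0.15, 0.4] Hz (half-open at the shared edge),
#' total power over [0.003, 0.4] Hz, and normalized versions obtained by
#' dividing by total power.
#'
#' @param spectrum a `spectral_estimate` covering at least 0-0.4 Hz.
#' @return list with PRVLF, PRVHF (ms^2), PRVLFn, PRVHFn (n.u.),
#'   total_power (ms^2) and `degenerate` (TRUE when total power is zero and
#'   the normalized indices are undefined, reported as NA).
#' @export
prv_indices <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectral_estimate"))
  if (max(spectrum$freqs) < 0.4) stop("spectrum must cover 0-0.4 Hz")
  lf <- band_power(spectrum, 0.045, 0.15, right_open = TRUE)
  hf <- band_power(spectrum, 0.15, 0.4)
  tot <- band_power(spectrum, 0.003, 0.4)
  if (tot <= 0) {
    return(list(PRVLF = lf, PRVHF = hf, PRVLFn = NA_real_,
                PRVHFn = NA_real_, total_power = tot, degenerate = TRUE))
  }
  list(PRVLF = lf, PRVHF = hf, PRVLFn = lf / tot, PRVHFn = hf / tot,
       total_power = tot, degenerate = FALSE)
}

#' PRV indices straight from a PPG trace
#'
#' Convenience chain: [detect_pulses()], [resample_intervals()],
#' [prv_spectrum()], [prv_indices()].
#'
#' @param trace PPG `signal_trace`.
#' @param quality_gate passed to [detect_pulses()].
#' @return as [prv_indices()].
#' @export
prv_features <- function(trace, quality_gate = TRUE) {
  series <- detect_pulses(trace, quality_gate = quality_gate)
  rs <- resample_intervals(series)
  prv_indices(prv_spectrum(rs))
}
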