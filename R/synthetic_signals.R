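# Synthetic PPG and EDA generators. Each generator returns both the trace
# and a ground-truth log (pulse times, SCR events, parameters) so that the
# feature extractors can be validated against known answers.

#' Pulse model parameters
#'
#' Parameters of the synthetic PPG generator. Pulse-to-pulse intervals are
#' modulated sinusoidally in the LF (0.045-0.15 Hz) and HF (0.15-0.4 Hz)
#' autonomic bands, so band powers of the downstream pulse rate variability
#' spectrum have closed-form values (a sinusoidal interval modulation of
#' amplitude `a` contributes power a^2/2 in its band).
#'
#' @param mean_ipi mean inter-pulse interval in seconds.
#' @param lf_amp,lf_freq LF modulation amplitude (s) and frequency (Hz).
#' @param hf_amp,hf_freq HF modulation amplitude (s) and frequency (Hz).
#' @param ipi_noise_sd white interval jitter SD (s).
#' @param pulse_width width of the rendered pulse bump (s).
#' @param waveform_noise_sd additive white noise SD on the waveform (a.u.).
#' @param sampling_rate output rate in Hz.
#' @param duration trace duration in seconds.
#' @return list of validated parameters, class `pulse_model_params`.
#' @export
pulse_model_params <- function(mean_ipi = 0.85,
                               lf_amp = 0, lf_freq = 0.1,
                               hf_amp = 0, hf_freq = 0.25,
                               ipi_noise_sd = 0,
                               pulse_width = 0.12,
                               waveform_noise_sd = 0,
                               sampling_rate = 32,
                               duration = 240) {
  if (mean_ipi <= 0) stop("mean_ipi must be positive")
  if (lf_amp < 0 || hf_amp < 0 || ipi_noise_sd < 0 || waveform_noise_sd < 0) {
    stop("amplitudes and noise SDs must be nonnegative")
  }
  if (lf_freq < 0.045 || lf_freq > 0.15) stop("lf_freq outside 0.045-0.15 Hz")
  if (hf_freq < 0.15 || hf_freq > 0.4) stop("hf_freq outside 0.15-0.4 Hz")
  if (lf_amp + hf_amp + 4 * ipi_noise_sd >= mean_ipi) {
    stop("infeasible pulse model: lf_amp + hf_amp + 4*ipi_noise_sd must stay below mean_ipi")
  }
  structure(list(mean_ipi = mean_ipi, lf_amp = lf_amp, lf_freq = lf_freq,
                 hf_amp = hf_amp, hf_freq = hf_freq,
                 ipi_noise_sd = ipi_noise_sd, pulse_width = pulse_width,
                 waveform_noise_sd = waveform_noise_sd,
                 sampling_rate = sampling_rate, duration = duration),
            class = "pulse_model_params")
}

#' Generate a synthetic PPG trace
#'
#' Places pulses at times governed by the interval model
#' `IPI(k) = mean_ipi + lf_amp*sin(2*pi*lf_freq*t_k) +
#' hf_amp*sin(2*pi*hf_freq*t_k) + noise`, rendering each pulse as a smooth
#' Gaussian bump. Pulse morphology carries no information downstream (only
#' peak times are used), so a unimodal bump with a detectable maximum
#' suffices.
#'
#' @param params a `pulse_model_params`.
#' @param seed integer seed; identical (params, seed) give identical output.
#' @param stage stage tag for the returned trace.
#' @return list with `trace` (a `signal_trace`, modality PPG) and
#'   `pulse_times` (ground truth, seconds).
#' @export
generate_ppg <- function(params, seed, stage = "rest") {
  stopifnot(inherits(params, "pulse_model_params"))
  set.seed(as.integer(seed))
  t <- 0.3  # first pulse clear of the record edge
  times <- numeric(0)
  while (t < params$duration - 0.3) {
    times <- c(times, t)
    ipi <- params$mean_ipi +
      params$lf_amp * sin(2 * pi * params$lf_freq * t) +
      params$hf_amp * sin(2 * pi * params$hf_freq * t) +
      stats::rnorm(1, 0, params$ipi_noise_sd)
    if (ipi <= 0) stop("generated non-positive inter-pulse interval")
    t <- t + ipi
  }
  fs <- params$sampling_rate
  n <- round(params$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  sdp <- params$pulse_width / 2.5
  half <- ceiling(4 * sdp * fs)
  for (tp in times) {
    c0 <- round(tp * fs) + 1
    idx <- max(1, c0 - half):min(n, c0 + half)
    x[idx] <- x[idx] + exp(-((tt[idx] - tp)^2) / (2 * sdp^2))
  }
  if (params$waveform_noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, params$waveform_noise_sd)
  }
  list(trace = signal_trace(x, fs, stage = stage, modality = "PPG"),
       pulse_times = times)
}

#' EDA model parameters
#'
#' Parameters of the synthetic skin-conductance generator: a tonic level
#' with optional linear drift, phasic skin conductance responses (SCRs)
#' rendered with a Bateman (bi-exponential) kernel at Poisson event times
#' with a 1 s refractory interval, optional additive sinusoid (so spectral
#' indices have analytic oracle values), and white measurement noise.
#'
#' @param tonic_level baseline conductance (microsiemens).
#' @param tonic_drift_slope linear drift (microsiemens per minute).
#' @param scr_rate SCR event rate (events/min); must be < 60/min given the
#'   1 s refractory interval.
#' @param scr_amp_meanlog,scr_amp_sdlog log-normal SCR amplitude parameters
#'   (microsiemens).
#' @param bateman_rise_tau,bateman_decay_tau Bateman kernel time constants
#'   (s); decay must exceed rise.
#' @param noise_sd white noise SD (microsiemens).
#' @param sinusoid_amp,sinusoid_freq optional additive sinusoid
#'   (microsiemens, Hz).
#' @param sampling_rate output rate in Hz.
#' @param duration trace duration in seconds.
#' @param scr_times,scr_amps optional explicit event times (s) and
#'   amplitudes (microsiemens) overriding the Poisson draw — used to plant
#'   known events for validation.
#' @return list of validated parameters, class `eda_model_params`.
#' @export
eda_model_params <- function(tonic_level = 2,
                             tonic_drift_slope = 0,
                             scr_rate = 4,
                             scr_amp_meanlog = log(0.3),
                             scr_amp_sdlog = 0.4,
                             bateman_rise_tau = 0.7,
                             bateman_decay_tau = 2.0,
                             noise_sd = 0,
                             sinusoid_amp = 0, sinusoid_freq = 0.1,
                             sampling_rate = 32,
                             duration = 120,
                             scr_times = NULL, scr_amps = NULL) {
  if (tonic_level < 0) stop("tonic_level must be nonnegative")
  if (scr_rate < 0) stop("scr_rate must be nonnegative")
  if (scr_rate >= 60) stop("scr_rate >= 60/min violates the 1 s refractory interval")
  if (bateman_rise_tau <= 0 || bateman_decay_tau <= bateman_rise_tau) {
    stop("require bateman_decay_tau > bateman_rise_tau > 0")
  }
  if (!is.null(scr_times) && is.null(scr_amps)) {
    stop("scr_amps must accompany scr_times")
  }
  structure(list(tonic_level = tonic_level,
                 tonic_drift_slope = tonic_drift_slope,
                 scr_rate = scr_rate,
                 scr_amp_meanlog = scr_amp_meanlog,
                 scr_amp_sdlog = scr_amp_sdlog,
                 bateman_rise_tau = bateman_rise_tau,
                 bateman_decay_tau = bateman_decay_tau,
                 noise_sd = noise_sd,
                 sinusoid_amp = sinusoid_amp, sinusoid_freq = sinusoid_freq,
                 sampling_rate = sampling_rate, duration = duration,
                 scr_times = scr_times, scr_amps = scr_amps),
            class = "eda_model_params")
}

#' Bateman impulse response, peak-normalized
#'
#' `b(t) = exp(-t/decay) - exp(-t/rise)` for `t >= 0`, scaled so its
#' maximum is 1; a planted SCR of amplitude `a` then peaks at `a`
#' microsiemens above baseline.
#'
#' @param t time points (s).
#' @param rise_tau,decay_tau time constants (s).
#' @return kernel values.
#' @export
bateman_kernel <- function(t, rise_tau = 0.7, decay_tau = 2.0) {
  b <- ifelse(t >= 0, exp(-t / decay_tau) - exp(-t / rise_tau), 0)
  tpk <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  bmax <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  b / bmax
}

#' Generate a synthetic EDA trace
#'
#' Conductance = tonic level + drift + sum of Bateman-shaped SCRs +
#' optional sinusoid + white noise. Event times follow a Poisson process
#' with a 1 s refractory interval whose mean gap equals `60/scr_rate`
#' seconds exactly, so the planted rate is unbiased. Errors if the
#' parameter combination produces negative conductance.
#'
#' @param params an `eda_model_params`.
#' @param seed integer seed.
#' @param stage stage tag for the returned trace.
#' @return list with `trace` (a `signal_trace`, modality EDA), `scr_times`
#'   and `scr_amps` (ground truth).
#' @export
generate_eda <- function(params, seed, stage = "rest") {
  stopifnot(inherits(params, "eda_model_params"))
  set.seed(as.integer(seed))
  fs <- params$sampling_rate
  n <- round(params$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  refractory <- 1
  if (!is.null(params$scr_times)) {
    ev_t <- params$scr_times
    ev_a <- params$scr_amps
  } else if (params$scr_rate > 0) {
    mean_gap <- 60 / params$scr_rate
    exp_rate <- 1 / (mean_gap - refractory)
    t <- 2 + stats::rexp(1, 1 / mean_gap)  # settle-in before first event
    ev_t <- numeric(0)
    while (t < params$duration - 5) {
      ev_t <- c(ev_t, t)
      t <- t + refractory + stats::rexp(1, exp_rate)
    }
    ev_a <- stats::rlnorm(length(ev_t), params$scr_amp_meanlog,
                          params$scr_amp_sdlog)
  } else {
    ev_t <- numeric(0); ev_a <- numeric(0)
  }
  x <- params$tonic_level + params$tonic_drift_slope * tt / 60
  for (i in seq_along(ev_t)) {
    x <- x + ev_a[i] * bateman_kernel(tt - ev_t[i], params$bateman_rise_tau,
                                      params$bateman_decay_tau)
  }
  if (params$sinusoid_amp > 0) {
    x <- x + params$sinusoid_amp * sin(2 * pi * params$sinusoid_freq * tt)
  }
  if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
  if (any(x < 0)) {
    stop("EDA parameter combination produced negative conductance")
  }
  list(trace = signal_trace(x, fs, stage = stage, modality = "EDA"),
       scr_times = ev_t, scr_amps = ev_a)
}
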