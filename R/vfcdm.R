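# Variable-frequency complex demodulation (VFCDM) of EDA and the TVSymp
# index. Two-stage algorithm: a fixed-frequency complex demodulation bank
# tiles 0 to n_components * bandwidth Hz; each component's instantaneous
# frequency is then tracked from its analytic phase and the signal is
# re-demodulated along that variable center frequency.

#' VFCDM configuration
#'
#' Components tile contiguous 0.08 Hz bands at a 2 Hz working rate, so
#' components 2 and 3 span approximately 0.08-0.24 Hz — the band carrying
#' sympathetically mediated EDA oscillations, from which TVSymp is
#' computed.
#'
#' @param working_rate working sampling rate (Hz).
#' @param n_components number of demodulation bands.
#' @param component_bandwidth bandwidth per component (Hz); component n
#'   spans ((n-1)*bw, n*bw].
#' @param fir_taps FIR low-pass length (samples) for the demodulators.
#' @param tvsymp_components which components form the TVSymp signal.
#' @param normalization `"per_session"` (amplitude SD taken over the
#'   concatenated rest+test record) or `"per_stage"`.
#' @return list of class `vfcdm_config`.
#' @export
vfcdm_config <- function(working_rate = 2, n_components = 8,
                         component_bandwidth = 0.08, fir_taps = 64,
                         tvsymp_components = c(2, 3),
                         normalization = c("per_session", "per_stage")) {
  normalization <- match.arg(normalization)
  if (n_components * component_bandwidth > working_rate / 2) {
    stop("component bank exceeds the Nyquist frequency")
  }
  structure(list(working_rate = working_rate, n_components = n_components,
                 component_bandwidth = component_bandwidth,
                 fir_taps = fir_taps, tvsymp_components = tvsymp_components,
                 normalization = normalization),
            class = "vfcdm_config")
}

# Single-pass linear-phase FIR low-pass with reflection padding and group
# delay removal; applied componentwise to complex series. (A two-pass
# zero-phase filter would square the magnitude response, pushing band-edge
# gain to 0.25 and breaking the demodulation bank's amplitude tiling.)
.lpf_real <- function(v, b, taps) {
  pad <- taps
  vp <- c(rev(v[2:(pad + 1)]), v, rev(v[(length(v) - pad):(length(v) - 1)]))
  y <- stats::filter(vp, b, method = "convolution", sides = 1)
  as.numeric(y[(pad + taps / 2 + 1):(pad + taps / 2 + length(v))])
}

.lpf_complex <- function(z, b, taps) {
  complex(real = .lpf_real(Re(z), b, taps),
          imaginary = .lpf_real(Im(z), b, taps))
}

# FIR magnitude response at frequency f (Hz) for sampling rate fs
.fir_mag <- function(b, f, fs) {
  abs(sum(b * exp(-1i * 2 * pi * f * (seq_along(b) - 1) / fs)))
}

#' VFCDM decomposition of an EDA trace
#'
#' Stage 1: complex demodulation at fixed center frequencies
#' `f_n = (n - 1/2) * bw` — multiply by `exp(-i 2 pi f_n t)`, low-pass at
#' bw/2 (64-tap Hamming FIR, linear phase with the group delay removed),
#' shift back. The demodulated magnitudes are divided by the bank's flat
#' in-band tiling gain (computed from the filter design) so that the
#' stage-1 components sum to the band-limited input. Stage 2: the
#' instantaneous frequency of each component (smoothed phase derivative,
#' clamped to the component's band) defines a variable center frequency
#' along which the component is re-demodulated, sharpening the amplitude
#' estimate; the refinement residual is folded back through the fixed bank
#' so the components still sum to the band-limited input.
#'
#' @param trace EDA `signal_trace` (any rate; resampled internally) or a
#'   plain numeric vector already at the working rate.
#' @param config a `vfcdm_config`.
#' @return matrix, one column per component, at the working rate.
#' @export
vfcdm_decompose <- function(trace, config = vfcdm_config()) {
  fs <- config$working_rate
  x <- if (inherits(trace, "signal_trace")) {
    resample_fir(trace$samples, trace$sampling_rate, fs)
  } else {
    as.numeric(trace)
  }
  x <- x - mean(x)
  n <- length(x)
  if (n < 3 * config$fir_taps) {
    stop(sprintf("trace too short for VFCDM: %d samples, need >= %d",
                 n, 3 * config$fir_taps))
  }
  tt <- (seq_len(n) - 1) / fs
  bw <- config$component_bandwidth
  taps <- config$fir_taps
  b <- as.numeric(signal::fir1(taps, (bw / 2) / (fs / 2), type = "low"))
  b <- b / sum(b)  # unit DC gain
  # flat tiling gain of the overlapped bank, from the filter design
  fref <- (config$n_components / 2) * bw  # an interior reference frequency
  gain <- sum(vapply(seq_len(config$n_components), function(k) {
    fc <- (k - 0.5) * bw
    .fir_mag(b, fref - fc, fs) + .fir_mag(b, fref + fc, fs)
  }, numeric(1)))
  b0 <- .fir_mag(b, 0, fs)
  smooth_len <- max(3L, round(4 * fs))  # ~4 s moving average on the IF
  bank <- function(v) {
    vapply(seq_len(config$n_components), function(k) {
      fc <- (k - 0.5) * bw
      z <- .lpf_complex(v * exp(-1i * 2 * pi * fc * tt), b, taps) / gain
      2 * Re(z * exp(1i * 2 * pi * fc * tt))
    }, numeric(n))
  }
  comps <- matrix(0, n, config$n_components)
  for (k in seq_len(config$n_components)) {
    fc <- (k - 0.5) * bw
    z <- .lpf_complex(x * exp(-1i * 2 * pi * fc * tt), b, taps) / gain
    y1 <- 2 * Re(z * exp(1i * 2 * pi * fc * tt))
    # stage 2: track the component's instantaneous frequency and refine
    ph <- .unwrap_phase(Arg(z))
    finst <- fc + c(0, diff(ph)) * fs / (2 * pi)
    finst <- stats::filter(finst, rep(1 / smooth_len, smooth_len),
                           sides = 2)
    finst[is.na(finst)] <- fc
    finst <- pmin(pmax(finst, fc - bw / 2), fc + bw / 2)
    theta <- 2 * pi * cumsum(finst) / fs
    z2 <- .lpf_complex(y1 * exp(-1i * theta), b, taps) / b0
    comps[, k] <- 2 * Re(z2 * exp(1i * theta))
  }
  # fold the refinement residual back through the fixed bank so the
  # decomposition stays complete over the covered band
  comps + bank(x - rowSums(comps))
}

.unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

#' TVSymp from VFCDM components
#'
#' Sums the sympathetic-band components (2 and 3, ~0.08-0.24 Hz), takes
#' the instantaneous amplitude (modulus of the analytic signal), and
#' normalizes by a standard deviation so the index is dimensionless. The
#' session value is the mean normalized amplitude with one FIR length
#' trimmed at each end (edge transients).
#'
#' @param components matrix from [vfcdm_decompose()].
#' @param config a `vfcdm_config`.
#' @param norm_sd optional externally supplied normalization SD (used for
#'   per-session normalization across rest and test); defaults to the SD
#'   of this window's sympathetic-band signal.
#' @return list with `instantaneous_amplitude`, `session_value` and
#'   `degenerate` (TRUE, with session_value 0, when the band signal has
#'   zero variance).
#' @export
compute_tvsymp <- function(components, config = vfcdm_config(),
                           norm_sd = NULL) {
  s <- rowSums(components[, config$tvsymp_components, drop = FALSE])
  sds <- stats::sd(s)
  if (is.null(norm_sd)) norm_sd <- sds
  if (!is.finite(norm_sd) || norm_sd <= .Machine$double.eps * 100) {
    return(list(instantaneous_amplitude = rep(0, length(s)),
                session_value = 0, degenerate = TRUE))
  }
  amp <- Mod(analytic_signal(s / norm_sd))
  edge <- config$fir_taps
  core <- amp[(edge + 1):(length(amp) - edge)]
  list(instantaneous_amplitude = amp, session_value = mean(core),
       degenerate = FALSE)
}

#' TVSymp for a rest/test pair of EDA traces
#'
#' With the default per-session normalization the sympathetic-band SD is
#' computed over the concatenated rest+test record and applied to both
#' stages, so a stage with stronger 0.08-0.24 Hz activity scores above 1
#' and the quieter stage below 1 — the rest < test ordering typical of
#' cognitive-stress protocols. Per-stage normalization scores each window
#' against its own SD.
#'
#' @param eda_rest,eda_test EDA `signal_trace` objects.
#' @param config a `vfcdm_config`.
#' @return list with `rest` and `test` TVSymp session values.
#' @export
tvsymp_pair <- function(eda_rest, eda_test, config = vfcdm_config()) {
  cr <- vfcdm_decompose(eda_rest, config)
  ct <- vfcdm_decompose(eda_test, config)
  if (config$normalization == "per_session") {
    sr <- rowSums(cr[, config$tvsymp_components, drop = FALSE])
    st <- rowSums(ct[, config$tvsymp_components, drop = FALSE])
    sd_all <- stats::sd(c(sr, st))
    list(rest = compute_tvsymp(cr, config, norm_sd = sd_all)$session_value,
         test = compute_tvsymp(ct, config, norm_sd = sd_all)$session_value)
  } else {
    list(rest = compute_tvsymp(cr, config)$session_value,
         test = compute_tvsymp(ct, config)$session_value)
  }
}
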