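# Welch-style averaged periodograms with amplitude-calibrated scaling, band
# integration, and the analytic signal. Shared by the PRV and EDA spectral
# indices.

#' Averaged windowed periodogram (Welch estimate)
#'
#' Splits the mean-removed signal into `nwindow`-point segments with 50%
#' overlap, applies a Blackman window, and averages the one-sided power
#' spectral densities. The density is compensated by the window mean-square
#' so that a sinusoid of amplitude `a` integrates to `a^2/2` over its band,
#' making band powers directly comparable to analytic oracle values.
#'
#' @param x numeric signal (units u).
#' @param fs sampling rate in Hz.
#' @param nwindow segment length in samples.
#' @param window window samples; defaults to a Blackman window.
#' @param overlap fractional segment overlap (0.5 = 50%).
#' @param demean remove the signal mean before segmenting.
#' @return object of class `spectral_estimate`: list with `freqs` (Hz),
#'   `power` (u^2 per Hz, one-sided), `resolution` (Hz) and
#'   `n_segments_averaged`.
#' @export
welch_psd <- function(x, fs, nwindow, window = signal::blackman(nwindow),
                      overlap = 0.5, demean = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < nwindow) {
    stop(sprintf("signal length %d shorter than one %d-point segment",
                 n, nwindow))
  }
  if (demean) x <- x - mean(x)
  step <- max(1L, floor(nwindow * (1 - overlap)))
  starts <- seq(1L, n - nwindow + 1L, by = step)
  wss <- sum(window^2)
  nfft <- nwindow
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nwindow - 1L)] * window
    X <- stats::fft(seg)
    p <- Mod(X[seq_len(nfft %/% 2 + 1)])^2 / (fs * wss)
    # one-sided: double everything but DC (and Nyquist for even nfft)
    dbl <- rep(2, length(p)); dbl[1] <- 1
    if (nfft %% 2 == 0) dbl[length(p)] <- 1
    acc <- acc + p * dbl
  }
  structure(
    list(freqs = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft,
         power = acc / length(starts),
         resolution = fs / nfft,
         n_segments_averaged = length(starts)),
    class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d bins, 0-%.3g Hz, df = %.4g Hz, %d segment(s)\n",
              length(x$freqs), max(x$freqs), x$resolution,
              x$n_segments_averaged))
  invisible(x)
}

#' Integrate spectral power over a frequency band
#'
#' Trapezoidal integration of the power density over grid bins whose
#' frequency lies in the band. The lower edge is inclusive; `right_open`
#' controls the upper edge (half-open bands avoid double counting at a
#' shared edge such as 0.15 Hz).
#'
#' @param spec a `spectral_estimate`.
#' @param lo,hi band edges in Hz.
#' @param right_open exclude bins at exactly `hi`.
#' @return integrated power (u^2).
#' @export
band_power <- function(spec, lo, hi, right_open = FALSE) {
  f <- spec$freqs
  keep <- if (right_open) f >= lo & f < hi else f >= lo & f <= hi
  if (sum(keep) < 2) return(0)
  pracma::trapz(f[keep], spec$power[keep])
}

#' Analytic signal via the FFT half-spectrum method
#'
#' @param x real numeric vector.
#' @return complex vector whose real part is `x` and whose modulus is the
#'   instantaneous amplitude envelope.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Resample to a lower rate through a linear-phase FIR anti-alias filter
# (cutoff 0.9x the target Nyquist, delay removed, reflection padding)
# followed by decimation. Flat passband well past the analysis bands, so
# band powers are not biased by resampler droop.
resample_fir <- function(x, fs_in, fs_out, taps = 192) {
  if (fs_in == fs_out) return(x)
  fac <- fs_in / fs_out
  if (abs(fac - round(fac)) > 1e-9) {
    stop("resample_fir: sampling rates must have an integer ratio")
  }
  b <- as.numeric(signal::fir1(taps, (0.9 * fs_out / 2) / (fs_in / 2)))
  b <- b / sum(b)
  y <- .lpf_real(x, b, taps)
  y[seq(1, length(y), by = as.integer(round(fac)))]
}

# Resample a uniformly sampled signal to a lower rate by block averaging
# (integer factor). Used on the deconvolution path, where the content of
# interest is far below the target Nyquist and exact preservation of
# constants keeps degenerate inputs exactly flat.
resample_block <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  fac <- fs_in / fs_out
  if (abs(fac - round(fac)) > 1e-9) {
    stop("resample_block: sampling rates must have an integer ratio")
  }
  fac <- as.integer(round(fac))
  nblk <- length(x) %/% fac
  colMeans(matrix(x[seq_len(nblk * fac)], nrow = fac))
}
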