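test_that("periodic noise-free pulse train is detected exactly", {
  p <- pulse_model_params(mean_ipi = 1, duration = 120)
  g <- generate_ppg(p, 1)
  det <- detect_pulses(g$trace)
  expect_equal(length(det$pulse_times), length(g$pulse_times))
  expect_lt(max(abs(det$pulse_times - g$pulse_times)), 1 / 32)
  expect_equal(det$intervals, rep(1000, length(det$intervals)),
               tolerance = 1e-3)
})

test_that("modulated pulses at 20 dB SNR are matched within 50 ms", {
  p <- pulse_model_params(lf_amp = 0.03, hf_amp = 0.02,
                          waveform_noise_sd = 0.045, duration = 300)
  g <- generate_ppg(p, 9)
  det <- detect_pulses(g$trace, quality_gate = FALSE)
  hit <- vapply(g$pulse_times, function(tp) {
    min(abs(det$pulse_times - tp)) < 0.05
  }, TRUE)
  expect_gte(mean(hit), 0.99)
})

test_that("flat or degenerate PPG fails the quality gate", {
  flat <- signal_trace(rep(0, 32 * 120), 32, "rest", "PPG")
  expect_error(detect_pulses(flat), "quality failure")
})

test_that("interval resampling is exact on constants and linear trends", {
  mk <- function(iv_ms) {
    times <- cumsum(c(0.5, iv_ms / 1000))
    structure(list(pulse_times = times, intervals = iv_ms),
              class = "pulse_interval_series")
  }
  rs <- resample_intervals(mk(rep(1000, 60)))
  expect_equal(rs$x, rep(1000, length(rs$x)))
  # intervals that are an exact linear function of their anchor time:
  # t[k+1] solves t[k+1] = t[k] + (1000 + 0.5 t[k+1]) / 1000
  tms <- Reduce(function(tk, .) (tk + 1) / (1 - 5e-4), seq_len(80),
                init = 0.5, accumulate = TRUE)
  iv_lin <- 1000 + 0.5 * tms[-1]
  rs2 <- resample_intervals(structure(
    list(pulse_times = tms, intervals = iv_lin),
    class = "pulse_interval_series"))
  expect_equal(rs2$x, 1000 + 0.5 * rs2$t, tolerance = 1e-9)
  # sinusoidal modulation reproduced on the grid (phase left free:
  # intervals are anchored at the ending pulse, one beat after the
  # modulation they sample)
  p <- pulse_model_params(lf_amp = 0.03, duration = 300)
  g <- generate_ppg(p, 4)
  rs3 <- resample_intervals(detect_pulses(g$trace))
  basis <- cbind(sin(2 * pi * 0.1 * rs3$t), cos(2 * pi * 0.1 * rs3$t))
  fitted <- stats::lm.fit(cbind(1, basis), rs3$x)$fitted.values
  expect_gt(stats::cor(rs3$x, fitted), 0.999)
  mk3 <- structure(list(pulse_times = cumsum(c(0.5, rep(1, 3))),
                        intervals = rep(1000, 3)),
                   class = "pulse_interval_series")
  expect_error(resample_intervals(mk3), "at least 4")
})

test_that("spectrum calibration: sinusoid band power equals a^2/2", {
  t <- seq(0, 240, by = 1 / 4)
  sig <- list(t = t, x = 850 + 30 * sin(2 * pi * 0.1 * t), rate = 4)
  sp <- prv_spectrum(sig)
  expect_equal(band_power(sp, 0.045, 0.15, right_open = TRUE), 450,
               tolerance = 0.05)
  # Parseval on white noise
  set.seed(5)
  wn <- list(t = t, x = rnorm(length(t), sd = 20), rate = 4)
  spw <- prv_spectrum(wn)
  expect_equal(band_power(spw, 0, 2), 400, tolerance = 0.10)
  # constant signal has an identically zero spectrum
  spc <- prv_spectrum(list(t = t, x = rep(900, length(t)), rate = 4))
  expect_equal(max(spc$power), 0, tolerance = 1e-18)
  expect_error(prv_spectrum(list(t = 1:10, x = 1:10, rate = 4)), "need >=")
})

test_that("band indices: concentration, a^2/2 at 0.25 Hz, degeneracy flag", {
  t <- seq(0, 240, by = 1 / 4)
  lf <- prv_indices(prv_spectrum(list(t = t,
                                      x = 850 + 30 * sin(2 * pi * 0.1 * t),
                                      rate = 4)))
  expect_gte(lf$PRVLFn, 0.95)
  expect_lte(lf$PRVHFn, 0.05)
  hf <- prv_indices(prv_spectrum(list(t = t,
                                      x = 850 + 20 * sin(2 * pi * 0.25 * t),
                                      rate = 4)))
  expect_equal(hf$PRVHF, 200, tolerance = 0.05)
  z <- prv_indices(prv_spectrum(list(t = t, x = rep(850, length(t)),
                                     rate = 4)))
  expect_true(z$degenerate)
  expect_true(is.na(z$PRVLFn))
})

test_that("band powers follow the c^2 law; normalized indices are scale-free", {
  t <- seq(0, 240, by = 1 / 4)
  x <- 30 * sin(2 * pi * 0.1 * t) + 20 * sin(2 * pi * 0.25 * t)
  for (c_scale in c(0.5, 3)) {
    a <- prv_indices(prv_spectrum(list(t = t, x = x, rate = 4)))
    b <- prv_indices(prv_spectrum(list(t = t, x = c_scale * x, rate = 4)))
    expect_equal(b$PRVLF, c_scale^2 * a$PRVLF, tolerance = 1e-6)
    expect_equal(b$PRVHF, c_scale^2 * a$PRVHF, tolerance = 1e-6)
    expect_equal(b$PRVLFn, a$PRVLFn, tolerance = 1e-9)
    expect_equal(b$PRVHFn, a$PRVHFn, tolerance = 1e-9)
    expect_lte(b$PRVLFn + b$PRVHFn, 1)
  }
})

test_that("end-to-end PRV recovers calibrated band powers within 10%", {
  p <- pulse_model_params(lf_amp = 0.03, hf_amp = 0.02,
                          waveform_noise_sd = 0.045, duration = 300)
  g <- generate_ppg(p, 12)
  pr <- prv_features(g$trace, quality_gate = FALSE)
  expect_equal(pr$PRVLF, 450, tolerance = 0.10)
  expect_equal(pr$PRVHF, 200, tolerance = 0.10)
})
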