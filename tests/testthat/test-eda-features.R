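test_that("constant input decomposes into pure tonic with zero driver", {
  g <- generate_eda(eda_model_params(tonic_level = 2, scr_rate = 0), 1)
  dec <- decompose_eda(g$trace)
  expect_equal(compute_scl(dec), 2, tolerance = 0.01)
  expect_equal(sum(dec$driver), 0)
  expect_lt(dec$residual_rms, 0.01)
  expect_equal(nrow(detect_scrs(dec)), 0)
})

test_that("SCL is the mean of the tonic component", {
  # ramp 1 -> 3 uS: mean 2
  g <- generate_eda(eda_model_params(tonic_level = 1, scr_rate = 0,
                                     tonic_drift_slope = 1), 1)
  dec <- decompose_eda(g$trace)
  expect_equal(compute_scl(dec), 2, tolerance = 0.02)
  # tonic-only input leaves almost no driver mass
  expect_lt(sum(dec$driver), 0.01 * sqrt(sum(g$trace$samples^2)))
  dec_empty <- dec; dec_empty$tonic <- numeric(0)
  expect_error(compute_scl(dec_empty), "empty tonic")
})

test_that("a single planted SCR is recovered in time and amplitude", {
  e <- eda_model_params(tonic_level = 2, scr_rate = 0, noise_sd = 0,
                        scr_times = 60, scr_amps = 0.4)
  dec <- decompose_eda(generate_eda(e, 1)$trace)
  ev <- detect_scrs(dec)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_time - 60), 1)
  expect_equal(ev$amplitude, 0.4, tolerance = 0.2 * 0.4)
  expect_true(all(dec$driver >= 0))
})

test_that("multiple planted SCRs are counted exactly", {
  e <- eda_model_params(tonic_level = 2, scr_rate = 0, noise_sd = 0,
                        scr_times = c(10, 30, 50, 70, 90),
                        scr_amps = c(0.1, 0.2, 0.3, 0.4, 0.5))
  dec <- decompose_eda(generate_eda(e, 1)$trace)
  ev <- detect_scrs(dec)
  expect_equal(nrow(ev), 5)
  expect_true(all(abs(ev$onset_time - c(10, 30, 50, 70, 90)) < 1))
  expect_equal(ns_scr_rate(ev, 120), 2.5)
})

test_that("sub-threshold events are detected but not counted in NS.SCRs", {
  e <- eda_model_params(tonic_level = 2, scr_rate = 0, noise_sd = 0,
                        scr_times = c(10, 30, 50, 70, 90),
                        scr_amps = c(0.02, 0.02, 0.3, 0.3, 0.3))
  ev <- detect_scrs(decompose_eda(generate_eda(e, 1)$trace))
  expect_equal(nrow(ev), 5)
  expect_equal(sum(ev$amplitude > 0.05), 3)
  expect_equal(ns_scr_rate(ev, 120), 1.5)
})

test_that("NS.SCRs arithmetic uses a strict threshold and real minutes", {
  ev <- data.frame(onset_time = 1:3, peak_time = 2:4,
                   amplitude = c(0.04, 0.3, 0.5))
  expect_equal(ns_scr_rate(ev, 120), 1.0)
  expect_equal(ns_scr_rate(ev[0, ], 120), 0)
  # exactly at threshold does not count ("higher than")
  expect_equal(ns_scr_rate(data.frame(amplitude = 0.05), 60), 0)
  expect_error(ns_scr_rate(ev, 0), "positive")
})

test_that("NS.SCRs is invariant to adding a pure tonic ramp", {
  base <- eda_model_params(tonic_level = 2, scr_rate = 0, noise_sd = 0,
                           scr_times = c(20, 60, 100),
                           scr_amps = c(0.2, 0.3, 0.4))
  ramped <- base; ramped$tonic_drift_slope <- 0.5
  n1 <- ns_scr_rate(detect_scrs(decompose_eda(generate_eda(base, 1)$trace)),
                    120)
  n2 <- ns_scr_rate(detect_scrs(decompose_eda(generate_eda(ramped, 1)$trace)),
                    120)
  expect_equal(n1, n2)
  expect_equal(n1, 1.5)
})

test_that("spectral calibration: 0.2 uS sinusoid at 0.1 Hz gives 0.02 uS^2", {
  tr <- generate_eda(eda_model_params(tonic_level = 2, scr_rate = 0,
                                      sinusoid_amp = 0.2), 1)$trace
  sp <- eda_spectral_indices(tr)
  expect_equal(sp$EDASymp, 0.02, tolerance = 0.05)
  # constant trace: zero power, normalized index undefined
  spc <- eda_spectral_indices(generate_eda(
    eda_model_params(tonic_level = 2, scr_rate = 0), 1)$trace)
  expect_true(spc$degenerate)
  expect_true(is.na(spc$EDASympn))
})

test_that("EDASympn splits power between in-band and out-of-band tones", {
  v <- seq(0, 120 - 1 / 32, by = 1 / 32)
  x <- 2 + 0.2 * sin(2 * pi * 0.1 * v) + 0.2 * sin(2 * pi * 0.5 * v)
  sp <- eda_spectral_indices(signal_trace(x, 32, "rest", "EDA"))
  expect_equal(sp$EDASympn, 0.5, tolerance = 0.1)
})

test_that("EDASymp follows the c^2 law and EDASympn is scale-free", {
  v <- seq(0, 120 - 1 / 32, by = 1 / 32)
  x <- 2 + 0.2 * sin(2 * pi * 0.1 * v) + 0.1 * sin(2 * pi * 0.5 * v)
  a <- eda_spectral_indices(signal_trace(x, 32, "rest", "EDA"))
  b <- eda_spectral_indices(signal_trace(2 + 3 * (x - 2), 32, "rest", "EDA"))
  expect_equal(b$EDASymp, 9 * a$EDASymp, tolerance = 1e-6)
  expect_equal(b$EDASympn, a$EDASympn, tolerance = 1e-9)
})

test_that("driver nonnegativity holds across noisy solver runs", {
  for (seed in 1:3) {
    g <- generate_eda(eda_model_params(tonic_level = 3, scr_rate = 8,
                                       noise_sd = 0.02), seed)
    dec <- decompose_eda(g$trace)
    expect_true(all(dec$driver >= 0))
    expect_equal(dec$reconstruction, dec$tonic + dec$phasic)
  }
})
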