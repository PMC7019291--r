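test_that("generators are deterministic given (params, seed)", {
  p <- pulse_model_params(lf_amp = 0.02, ipi_noise_sd = 0.005)
  a <- generate_ppg(p, 99); b <- generate_ppg(p, 99)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$pulse_times, b$pulse_times)
  e <- eda_model_params(scr_rate = 6, noise_sd = 0.01)
  x <- generate_eda(e, 42); y <- generate_eda(e, 42)
  expect_identical(x$trace$samples, y$trace$samples)
  expect_identical(x$scr_times, y$scr_times)
  expect_false(identical(generate_eda(e, 43)$trace$samples,
                         x$trace$samples))
})

test_that("unmodulated pulse model produces strictly periodic pulses", {
  p <- pulse_model_params(mean_ipi = 1, lf_amp = 0, hf_amp = 0,
                          ipi_noise_sd = 0, duration = 120)
  g <- generate_ppg(p, 1)
  expect_equal(diff(g$pulse_times), rep(1, length(g$pulse_times) - 1))
})

test_that("pulse model rejects infeasible interval modulation", {
  expect_error(pulse_model_params(mean_ipi = 0.5, lf_amp = 0.3,
                                  hf_amp = 0.25),
               "infeasible")
  expect_error(pulse_model_params(lf_freq = 0.2), "lf_freq")
})

test_that("quiet EDA model yields a constant trace at the tonic level", {
  e <- eda_model_params(tonic_level = 2, scr_rate = 0, noise_sd = 0)
  g <- generate_eda(e, 1)
  expect_equal(g$trace$samples, rep(2, length(g$trace$samples)))
  expect_length(g$scr_times, 0)
})

test_that("EDA generator refuses parameters driving conductance negative", {
  e <- eda_model_params(tonic_level = 0.5, scr_rate = 0, sinusoid_amp = 2)
  expect_error(generate_eda(e, 1), "negative conductance")
})

test_that("planted SCR ground truth is returned exactly", {
  e <- eda_model_params(scr_rate = 0, noise_sd = 0,
                        scr_times = c(10, 30, 50, 70, 90),
                        scr_amps = rep(0.3, 5))
  g <- generate_eda(e, 1)
  expect_identical(g$scr_times, c(10, 30, 50, 70, 90))
  expect_identical(g$scr_amps, rep(0.3, 5))
  # count above the 0.05 uS threshold per minute: 5 events / 2 min
  expect_equal(sum(g$scr_amps > 0.05) / (e$duration / 60), 2.5)
})

test_that("calibration inverts the analytic index relations", {
  cal <- calibrate_params(list(PRVLF = 450))
  expect_equal(cal$ppg$lf_amp, 0.030, tolerance = 1e-12)
  cal2 <- calibrate_params(list(SCL = 2.2))
  expect_equal(cal2$eda$tonic_level, 2.2)
  cal3 <- calibrate_params(list(EDASymp = 0.02, SCL = 2))
  expect_equal(cal3$eda$sinusoid_amp, 0.2)
  flat <- calibrate_params(list(SCL = 0, `NS.SCRs` = 0, EDASymp = 0,
                                PRVLF = 0, PRVHF = 0))
  expect_equal(flat$ppg$lf_amp, 0)
  expect_equal(flat$ppg$hf_amp, 0)
  expect_equal(flat$eda$scr_rate, 0)
  expect_error(calibrate_params(list(PRVLF = -1)), "infeasible")
})

test_that("cohort has the study structure: 68 sessions, 51 wet / 17 dry", {
  spec <- cohort_effect_spec(n_subjects = 17, seed = 7)
  ch <- generate_cohort(spec)
  expect_length(ch$sessions, 68)
  labs <- vapply(ch$sessions, function(s) s$hydration_label, "")
  expect_equal(sum(labs == "wet"), 51)
  expect_equal(sum(labs == "dry"), 17)
  meas <- vapply(ch$sessions, function(s) s$measurement_id, "")
  expect_true(all(labs[meas == "M3"] == "dry"))
  expect_true(all(labs[meas != "M3"] == "wet"))
  # every generated trace satisfies the session contract
  for (s in ch$sessions[1:4]) {
    for (tr in s$traces) expect_silent(validate_trace(tr))
  }
  # ground-truth log mirrors the sessions
  expect_length(ch$log, 68)
  expect_true(all(vapply(ch$log, function(l)
    length(l$rest$pulse_times) > 30, TRUE)))
})

test_that("cohort-level mean of extracted SCL tracks the generator target", {
  # degenerate-variance corner: zero SD targets, zero noise
  g <- expand.grid(stage = c("rest", "test"),
                   measurement = c("M1", "M2", "M3", "M4"),
                   stringsAsFactors = FALSE)
  tg <- data.frame(g, index = "SCL", mean = 2.5, sd = 0)
  spec <- cohort_effect_spec(n_subjects = 3, targets = tg,
                             eda_noise_sd = 0, ipi_noise_sd = 0, seed = 1)
  ch <- generate_cohort(spec)
  scls <- vapply(ch$sessions[1:4], function(s) {
    compute_scl(decompose_eda(s$traces$eda_rest))
  }, numeric(1))
  expect_equal(scls, rep(2.5, 4), tolerance = 0.01)
  # full default cohort: extracted SCL mean within 15% of the mean target
  feats <- planted_cohort_features()
  expect_equal(mean(feats$rest$SCL),
               mean(ifelse(feats$rest$measurement == "M3", 3.0, 2.0)),
               tolerance = 0.15)
})
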