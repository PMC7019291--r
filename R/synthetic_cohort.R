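# Whole-cohort simulation: 17 subjects x 4 measurements x {rest, test},
# with index-level targets mapped analytically onto signal parameters.

#' Default per-cell index targets for the synthetic cohort
#'
#' Target mean and SD of the five directly calibratable indices (SCL,
#' NS.SCRs, EDASymp, PRVLF, PRVHF) for each measurement (M1, M2 euhydrated;
#' M3 dehydrated; M4 rehydrated) and stage (rest, test), reflecting the
#' reported cohort statistics of the hydration study the generator
#' emulates. PRV powers are in ms^2, EDA power in microsiemens^2.
#'
#' @return data.frame with columns measurement, stage, index, mean, sd.
#' @export
default_cohort_targets <- function() {
  g <- expand.grid(stage = c("rest", "test"),
                   measurement = c("M1", "M2", "M3", "M4"),
                   stringsAsFactors = FALSE)
  tab <- list(
    SCL       = list(m = c(2.2, 7.1, 2.3, 5.5, 3.8, 7.9, 3.8, 6.3),
                     s = c(2.4, 4.4, 3.6, 6.4, 4.7, 6.4, 5.5, 6.6)),
    `NS.SCRs` = list(m = c(3.8, 8.1, 4.2, 6.6, 3.9, 8.2, 3.9, 7.3),
                     s = c(1.9, 2.1, 2.6, 3.8, 2.5, 3.0, 2.2, 3.6)),
    EDASymp   = list(m = c(0.2, 6.6, 0.19, 0.97, 1.3, 0.61, 0.092, 0.096),
                     s = c(0.48, 24, 0.33, 3.1, 4.8, 1.1, 0.17, 0.086)),
    PRVLF     = list(m = c(14, 15, 13, 15, 170, 120, 13, 19),
                     s = c(12, 12, 15, 15, 650, 420, 12, 28)),
    PRVHF     = list(m = c(15, 16, 12, 17, 37, 55, 17, 27),
                     s = c(23, 18, 10, 22, 110, 140, 22, 69)))
  do.call(rbind, lapply(names(tab), function(ix) {
    data.frame(measurement = g$measurement, stage = g$stage, index = ix,
               mean = tab[[ix]]$m, sd = tab[[ix]]$s)
  }))
}

#' Cohort effect specification
#'
#' Describes a synthetic wet/dry cohort: number of subjects, per-cell index
#' targets, how much of the target dispersion is shared between repeated
#' measurements of the same subject, and an overall dispersion scale.
#' Per-subject, per-index random effects are drawn once and reused across
#' all of a subject's measurements, giving the repeated-measures structure
#' the leave-one-subject-out evaluation relies on.
#'
#' @param n_subjects number of subjects (>= 2); the study design uses 17.
#' @param targets data.frame as from [default_cohort_targets()]; any subset
#'   of cells/indices may be given, the rest fall back to defaults.
#' @param between_subject_share fraction (0-1) of the log-scale variance
#'   attributed to stable subject differences.
#' @param sd_scale multiplier on all target SDs.
#' @param eda_noise_sd measurement noise on EDA traces (microsiemens).
#' @param ipi_noise_sd interval jitter on PPG (s).
#' @param seed integer seed for the cohort draw.
#' @return list of class `cohort_effect_spec`.
#' @export
cohort_effect_spec <- function(n_subjects = 17,
                               targets = default_cohort_targets(),
                               between_subject_share = 0.5,
                               sd_scale = 1,
                               eda_noise_sd = 0.01,
                               ipi_noise_sd = 0.005,
                               seed = 1) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  stopifnot(all(c("measurement", "stage", "index", "mean", "sd") %in%
                  names(targets)))
  if (any(!is.finite(targets$mean)) || any(!is.finite(targets$sd)) ||
      any(targets$mean < 0) || any(targets$sd < 0)) {
    stop("targets must be finite and nonnegative")
  }
  if (between_subject_share < 0 || between_subject_share > 1) {
    stop("between_subject_share must lie in [0, 1]")
  }
  structure(list(n_subjects = n_subjects, targets = targets,
                 between_subject_share = between_subject_share,
                 sd_scale = sd_scale, eda_noise_sd = eda_noise_sd,
                 ipi_noise_sd = ipi_noise_sd, seed = seed),
            class = "cohort_effect_spec")
}

#' Map index targets to signal-model parameters
#'
#' Analytic inversions: the tonic level equals the SCL target; the SCR
#' rate equals the NS.SCRs target; a sinusoidal interval modulation of
#' amplitude `a` carries band power a^2/2, so `lf_amp = sqrt(2*PRVLF)` (ms,
#' converted to s), `hf_amp = sqrt(2*PRVHF)` and the EDA sinusoid amplitude
#' is `sqrt(2*EDASymp)`. Unspecified targets fall back to the generator
#' defaults. To keep conductance positive the EDA oscillation is capped at
#' 70% of the tonic level, and the tonic level is floored at 0.1
#' microsiemens.
#'
#' @param targets named list/vector with any of SCL, NS.SCRs, EDASymp,
#'   PRVLF, PRVHF (units: microsiemens, events/min, microsiemens^2, ms^2,
#'   ms^2).
#' @param eda_noise_sd,ipi_noise_sd noise levels passed through.
#' @param eda_duration,ppg_duration trace durations (s).
#' @return list with elements `ppg` (`pulse_model_params`) and `eda`
#'   (`eda_model_params`).
#' @export
calibrate_params <- function(targets, eda_noise_sd = 0, ipi_noise_sd = 0,
                             eda_duration = 120, ppg_duration = 240) {
  targets <- as.list(targets)
  get <- function(nm, default) {
    v <- targets[[nm]]
    if (is.null(v)) default else v
  }
  scl <- get("SCL", 2)
  nsscr <- get("NS.SCRs", 4)
  edasymp <- get("EDASymp", 0)
  prvlf <- get("PRVLF", 0)
  prvhf <- get("PRVHF", 0)
  if (any(c(scl, nsscr, edasymp, prvlf, prvhf) < 0)) {
    stop("infeasible targets: negative index target")
  }
  tonic <- max(scl, 0.1)
  sin_amp <- sqrt(2 * edasymp)
  if (sin_amp > 0.7 * tonic) sin_amp <- 0.7 * tonic
  lf_amp <- sqrt(2 * prvlf) / 1000   # ms^2 -> s
  hf_amp <- sqrt(2 * prvhf) / 1000
  # keep interval modulation well inside the positivity margin
  mean_ipi <- 0.85
  cap <- 0.2 * mean_ipi
  lf_amp <- min(lf_amp, cap)
  hf_amp <- min(hf_amp, cap)
  list(
    ppg = pulse_model_params(mean_ipi = mean_ipi,
                             lf_amp = lf_amp, lf_freq = 0.1,
                             hf_amp = hf_amp, hf_freq = 0.25,
                             ipi_noise_sd = ipi_noise_sd,
                             duration = ppg_duration),
    eda = eda_model_params(tonic_level = tonic, scr_rate = min(nsscr, 30),
                           noise_sd = min(eda_noise_sd, 0.02 * tonic),
                           sinusoid_amp = sin_amp, sinusoid_freq = 0.1,
                           duration = eda_duration))
}

# Draw one lognormal cell value with mean m, sd s (moment-matched), with a
# subject effect z shared across the subject's measurements.
.lognormal_cell <- function(m, s, z_subject, share) {
  if (m <= 0) return(0)
  if (s <= 0) return(m)
  sig2 <- log(1 + (s / m)^2)
  mu <- log(m) - sig2 / 2
  z <- sqrt(share) * z_subject + sqrt(1 - share) * stats::rnorm(1)
  exp(mu + sqrt(sig2) * z)
}

#' Generate a synthetic wet/dry cohort
#'
#' For each subject and measurement, draws per-cell index targets from
#' moment-matched log-normal distributions around the specified cell means
#' and SDs (log-normal, because several indices are strongly right-skewed
#' and must stay positive), maps them to signal parameters with
#' [calibrate_params()], and synthesizes the four traces per session.
#' Hydration labels follow the study design: M1, M2, M4 wet; M3 dry.
#'
#' @param effect a `cohort_effect_spec`.
#' @return list with `sessions` (list of `subject_session`) and `log`
#'   (per-session ground truth: drawn targets, SCR events, pulse times).
#' @export
generate_cohort <- function(effect) {
  stopifnot(inherits(effect, "cohort_effect_spec"))
  set.seed(as.integer(effect$seed))
  tg <- effect$targets
  indices <- unique(tg$index)
  sessions <- list()
  log <- list()
  for (s in seq_len(effect$n_subjects)) {
    sid <- sprintf("S%02d", s)
    z_subj <- stats::rnorm(length(indices))
    names(z_subj) <- indices
    for (m in c("M1", "M2", "M3", "M4")) {
      traces <- list()
      truth <- list(subject = sid, measurement = m)
      for (st in c("rest", "test")) {
        cell <- tg[tg$measurement == m & tg$stage == st, , drop = FALSE]
        drawn <- stats::setNames(vapply(seq_len(nrow(cell)), function(i) {
          .lognormal_cell(cell$mean[i], cell$sd[i] * effect$sd_scale,
                          z_subj[[cell$index[i]]],
                          effect$between_subject_share)
        }, numeric(1)), cell$index)
        pars <- calibrate_params(as.list(drawn),
                                 eda_noise_sd = effect$eda_noise_sd,
                                 ipi_noise_sd = effect$ipi_noise_sd)
        seed_eda <- sample.int(.Machine$integer.max, 1)
        seed_ppg <- sample.int(.Machine$integer.max, 1)
        eda <- generate_eda(pars$eda, seed_eda, stage = st)
        ppg <- generate_ppg(pars$ppg, seed_ppg, stage = st)
        traces[[paste0("eda_", st)]] <- eda$trace
        traces[[paste0("ppg_", st)]] <- ppg$trace
        truth[[st]] <- list(targets = as.list(drawn),
                            scr_times = eda$scr_times,
                            scr_amps = eda$scr_amps,
                            pulse_times = ppg$pulse_times)
      }
      sessions[[length(sessions) + 1L]] <-
        subject_session(sid, m, traces$eda_rest, traces$eda_test,
                        traces$ppg_rest, traces$ppg_test)
      log[[length(log) + 1L]] <- truth
    }
  }
  list(sessions = sessions, log = log)
}
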