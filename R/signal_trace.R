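#' Signal trace constructor
#'
#' A `signal_trace` holds one uniformly sampled physiological signal for one
#' stage of the rest/test protocol: electrodermal activity (EDA, in
#' microsiemens) or a photoplethysmographic pulse waveform (PPG, arbitrary
#' units), sampled at 32 Hz on the recording device.
#'
#' @param samples numeric vector of signal samples; no missing values.
#' @param sampling_rate sampling rate in Hz (32 for raw device traces).
#' @param stage `"rest"` or `"test"`.
#' @param modality `"EDA"` or `"PPG"`.
#' @return an object of class `signal_trace`.
#' @export
signal_trace <- function(samples, sampling_rate, stage = c("rest", "test"),
                         modality = c("EDA", "PPG")) {
  stage <- match.arg(stage)
  modality <- match.arg(modality)
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("signal_trace: samples contain missing values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("signal_trace: sampling_rate must be a single positive number")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         stage = stage, modality = modality),
    class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$modality, x$stage, length(x$samples), x$sampling_rate,
              trace_duration(x)))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param trace a `signal_trace`.
#' @return duration in seconds.
#' @export
trace_duration <- function(trace) {
  length(trace$samples) / trace$sampling_rate
}

# Minimum usable stage lengths: the analysis uses the first two minutes of
# EDA and four minutes of PPG per stage.
.min_duration_s <- c(EDA = 120, PPG = 240)

#' Validate a trace against protocol expectations
#'
#' Checks sampling rate (raw traces must be 32 Hz), absence of missing
#' samples, and minimum usable stage duration per modality (120 s of EDA,
#' 240 s of PPG).
#'
#' @param trace a `signal_trace`.
#' @param raw_rate required sampling rate in Hz; `NULL` skips the check.
#' @return the trace, invisibly; errors describe the offending trace.
#' @export
validate_trace <- function(trace, raw_rate = 32) {
  lab <- sprintf("%s/%s trace", trace$modality, trace$stage)
  if (!is.null(raw_rate) && trace$sampling_rate != raw_rate) {
    stop(sprintf("%s: sampling rate %g Hz, expected %g Hz",
                 lab, trace$sampling_rate, raw_rate))
  }
  need <- .min_duration_s[[trace$modality]]
  if (trace_duration(trace) < need) {
    stop(sprintf("%s: %.1f s of data, need at least %g s",
                 lab, trace_duration(trace), need))
  }
  invisible(trace)
}

#' Subject session constructor
#'
#' One subject x one measurement occasion: four traces (EDA and PPG, each
#' with a rest and a test stage) plus the hydration label. Measurements 1,
#' 2 and 4 of the study design are euhydrated ("wet"); measurement 3, taken
#' after 24 h of fluid restriction, is mildly dehydrated ("dry").
#'
#' @param subject_id subject identifier (string).
#' @param measurement_id one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param eda_rest,eda_test,ppg_rest,ppg_test `signal_trace` objects.
#' @param hydration_label `"wet"` or `"dry"`; defaults to the label implied
#'   by the measurement (M3 dry, others wet).
#' @param validate validate traces against the 32 Hz / duration contract.
#' @return an object of class `subject_session`.
#' @export
subject_session <- function(subject_id, measurement_id,
                            eda_rest, eda_test, ppg_rest, ppg_test,
                            hydration_label = NULL, validate = TRUE) {
  measurement_id <- match.arg(measurement_id, c("M1", "M2", "M3", "M4"))
  implied <- if (measurement_id == "M3") "dry" else "wet"
  if (is.null(hydration_label)) hydration_label <- implied
  hydration_label <- match.arg(hydration_label, c("wet", "dry"))
  if (hydration_label != implied) {
    stop(sprintf("session %s/%s: label '%s' contradicts measurement design (%s is '%s')",
                 subject_id, measurement_id, hydration_label, measurement_id, implied))
  }
  traces <- list(eda_rest = eda_rest, eda_test = eda_test,
                 ppg_rest = ppg_rest, ppg_test = ppg_test)
  want <- list(eda_rest = c("EDA", "rest"), eda_test = c("EDA", "test"),
               ppg_rest = c("PPG", "rest"), ppg_test = c("PPG", "test"))
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    if (!inherits(tr, "signal_trace")) stop(nm, " is not a signal_trace")
    if (tr$modality != want[[nm]][1] || tr$stage != want[[nm]][2]) {
      stop(sprintf("trace '%s' has modality/stage %s/%s, expected %s/%s",
                   nm, tr$modality, tr$stage, want[[nm]][1], want[[nm]][2]))
    }
    if (validate) validate_trace(tr)
  }
  structure(
    list(subject_id = as.character(subject_id),
         measurement_id = measurement_id,
         hydration_label = hydration_label,
         traces = traces),
    class = "subject_session")
}

#' @export
print.subject_session <- function(x, ...) {
  cat(sprintf("<subject_session> %s %s [%s], 4 traces\n",
              x$subject_id, x$measurement_id, x$hydration_label))
  invisible(x)
}

#' Canonical names of the nine autonomic indices
#'
#' Fixed vocabulary of index names: EDA indices (SCL, NS.SCRs, EDASymp,
#' EDASympn, TVSymp) and PRV indices (PRVLF, PRVLFn, PRVHF, PRVHFn).
#' @return character vector of length 9.
#' @export
index_names <- function() {
  c("SCL", "NS.SCRs", "EDASymp", "EDASympn", "TVSymp",
    "PRVLF", "PRVLFn", "PRVHF", "PRVHFn")
}
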