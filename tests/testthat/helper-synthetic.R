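# Shared fixtures, built in code. The planted-separation cohort and its
# extracted features are expensive (~3 min), so they are computed once per
# test run and cached for every test that needs them.

.fixture_cache <- new.env(parent = emptyenv())

# Cohort with a ~2-pooled-SD wet/dry separation planted on SCL, NS.SCRs
# and PRVLF (identical rest/test targets within class, so every data view
# carries the separation); remaining indices carry no class signal.
planted_cohort_spec <- function(seed = 20260101, n_subjects = 17) {
  g <- expand.grid(stage = c("rest", "test"),
                   measurement = c("M1", "M2", "M3", "M4"),
                   stringsAsFactors = FALSE)
  dry <- g$measurement == "M3"
  tg <- rbind(
    data.frame(g, index = "SCL", mean = ifelse(dry, 3.0, 2.0), sd = 0.5),
    data.frame(g, index = "NS.SCRs", mean = ifelse(dry, 6, 4), sd = 1),
    data.frame(g, index = "PRVLF", mean = ifelse(dry, 30, 20), sd = 5),
    data.frame(g, index = "PRVHF", mean = 15, sd = 4),
    data.frame(g, index = "EDASymp", mean = 0.005, sd = 0.002))
  cohort_effect_spec(n_subjects = n_subjects, targets = tg,
                     between_subject_share = 0.3, seed = seed)
}

planted_cohort_features <- function() {
  if (!is.null(.fixture_cache$feats)) return(.fixture_cache$feats)
  cohort <- generate_cohort(planted_cohort_spec())
  feats <- extract_cohort_features(cohort$sessions)
  .fixture_cache$feats <- feats
  feats
}

# A minimal valid subject session with short-but-valid trace durations.
make_session <- function(subject = "S01", measurement = "M1", seed = 1) {
  eda_p <- eda_model_params(tonic_level = 2, scr_rate = 4, duration = 120)
  ppg_p <- pulse_model_params(duration = 240)
  subject_session(
    subject, measurement,
    generate_eda(eda_p, seed, "rest")$trace,
    generate_eda(eda_p, seed + 1, "test")$trace,
    generate_ppg(ppg_p, seed + 2, "rest")$trace,
    generate_ppg(ppg_p, seed + 3, "test")$trace)
}

# Random 17x4 feature table with labels following the study design; used
# by classification tests that need structure but not real signals.
random_feature_table <- function(seed = 1, n_subjects = 17, shift = 0,
                                 shifted_cols = character(0),
                                 view = "test_only") {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (m in c("M1", "M2", "M3", "M4")) {
      lab <- if (m == "M3") "dry" else "wet"
      v <- stats::rnorm(9)
      names(v) <- index_names()
      if (lab == "dry") v[shifted_cols] <- v[shifted_cols] + shift
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = sprintf("S%02d", s), measurement = m,
                   label = lab),
        as.data.frame(as.list(v), check.names = FALSE))
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "view") <- view
  tab
}
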