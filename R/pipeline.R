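# End-to-end orchestration: simulate or load a cohort, extract the nine
# indices per stage, write the stats report and the classification sweep.

#' Extract the nine autonomic indices for one session
#'
#' EDA time-domain indices (SCL, NS.SCRs) come from the sparse
#' deconvolution of the first two minutes of each stage; spectral EDA
#' power from the Welch estimate; TVSymp from the VFCDM decomposition
#' (normalized across the rest+test pair by default); PRV band powers from
#' four minutes of PPG.
#'
#' @param session a `subject_session`.
#' @param eda_cfg from [eda_config()].
#' @param vf_cfg from [vfcdm_config()].
#' @param quality_gate passed to the pulse detector.
#' @return list with `rest` and `test`: named numeric vectors of the nine
#'   indices.
#' @export
extract_session_features <- function(session, eda_cfg = eda_config(),
                                     vf_cfg = vfcdm_config(),
                                     quality_gate = TRUE) {
  stopifnot(inherits(session, "subject_session"))
  tv <- tvsymp_pair(session$traces$eda_rest, session$traces$eda_test, vf_cfg)
  out <- list()
  for (st in c("rest", "test")) {
    eda <- eda_features(session$traces[[paste0("eda_", st)]], eda_cfg)
    prv <- prv_features(session$traces[[paste0("ppg_", st)]],
                        quality_gate = quality_gate)
    out[[st]] <- c(SCL = eda$SCL, `NS.SCRs` = eda$`NS.SCRs`,
                   EDASymp = eda$EDASymp, EDASympn = eda$EDASympn,
                   TVSymp = tv[[st]],
                   PRVLF = prv$PRVLF, PRVLFn = prv$PRVLFn,
                   PRVHF = prv$PRVHF, PRVHFn = prv$PRVHFn)
  }
  out
}

#' Extract per-stage feature tables for a list of sessions
#'
#' @param sessions list of `subject_session`.
#' @param ... passed to [extract_session_features()].
#' @return list with `rest` and `test` feature tables (one row per
#'   session: subject, measurement, label, nine index columns).
#' @export
extract_cohort_features <- function(sessions, ...) {
  rows_r <- list(); rows_t <- list()
  for (s in sessions) {
    fx <- extract_session_features(s, ...)
    meta <- data.frame(subject = s$subject_id,
                       measurement = s$measurement_id,
                       label = s$hydration_label)
    rows_r[[length(rows_r) + 1L]] <-
      cbind(meta, as.data.frame(as.list(fx$rest), check.names = FALSE))
    rows_t[[length(rows_t) + 1L]] <-
      cbind(meta, as.data.frame(as.list(fx$test), check.names = FALSE))
  }
  list(rest = do.call(rbind, rows_r), test = do.call(rbind, rows_t))
}

#' Pipeline configuration
#'
#' @param cohort either a `cohort_effect_spec` (synthetic run) or a
#'   directory containing session manifests (`*_manifest.json`).
#' @param out_dir output directory.
#' @param seed integer seed; mandatory for synthetic runs.
#' @param views data views to sweep.
#' @param families classifier family names to sweep.
#' @param max_subset_size cap on swept subset size (9 = full sweep).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, out_dir, seed = 1,
                            views = c("rest_only", "test_only",
                                      "increment", "rest_and_test"),
                            families = names(all_classifiers()),
                            max_subset_size = 9) {
  if (inherits(cohort, "cohort_effect_spec") && is.null(seed)) {
    stop("synthetic runs require a seed")
  }
  structure(list(cohort = cohort, out_dir = out_dir, seed = seed,
                 views = views, families = families,
                 max_subset_size = max_subset_size),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulate (or load) the cohort, extract per-stage feature tables, write
#' the rest-vs-test stats report, run the LOSO classification sweep per
#' data view, and write a run manifest. All outputs are deterministic
#' given the configuration and seed.
#'
#' @param config a `pipeline_config`.
#' @param verbose print per-stage progress.
#' @return (invisibly) list with the feature tables, stats report, sweep
#'   results and output paths.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- cohort --
  if (inherits(config$cohort, "cohort_effect_spec")) {
    say("simulate: %d subjects, seed %d", config$cohort$n_subjects,
        config$cohort$seed)
    cohort <- generate_cohort(config$cohort)
    sessions <- cohort$sessions
  } else {
    manifests <- sort(list.files(config$cohort, "_manifest\\.json$",
                                 full.names = TRUE))
    if (length(manifests) == 0) {
      stop("no session manifests found in ", config$cohort)
    }
    say("load: %d session manifests", length(manifests))
    sessions <- lapply(manifests, read_session)
  }

  # -- features --
  say("extract: %d sessions", length(sessions))
  feats <- extract_cohort_features(sessions)
  paths <- list(
    features_rest = file.path(config$out_dir, "features_rest.csv"),
    features_test = file.path(config$out_dir, "features_test.csv"))
  write_feature_table(feats$rest, paths$features_rest)
  write_feature_table(feats$test, paths$features_test)

  # -- stats --
  say("stats: rest vs test per index and measurement")
  report <- stats_report(feats$rest, feats$test)
  paths$stats_report <- file.path(config$out_dir, "stats_report.csv")
  utils::write.csv(report, paths$stats_report, row.names = FALSE)

  # -- sweep --
  views <- build_views(feats$rest, feats$test)
  fams <- all_classifiers()[config$families]
  indices <- index_names()
  subsets <- Filter(function(s) length(s) <= config$max_subset_size,
                    enumerate_subsets(indices))
  sweep <- list()
  for (v in config$views) {
    say("sweep: view %s, %d subsets x %d families", v, length(subsets),
        length(fams))
    for (fam in fams) {
      for (ss in subsets) {
        sweep[[length(sweep) + 1L]] <-
          loso_evaluate(views[[v]], ss, fam, seed = config$seed)
      }
    }
  }
  sweep <- do.call(rbind, sweep)
  sweep <- sweep[order(-sweep$accuracy, sweep$n_features, sweep$subset), ,
                 drop = FALSE]
  paths$sweep_results <- file.path(config$out_dir, "sweep_results.jsonl")
  write_sweep_results(sweep, paths$sweep_results)
  # best model per view, Table-style summary
  best <- do.call(rbind, lapply(split(sweep, sweep$view), function(d) {
    d[1, , drop = FALSE]
  }))
  paths$sweep_summary <- file.path(config$out_dir, "sweep_summary.csv")
  utils::write.csv(best, paths$sweep_summary, row.names = FALSE)

  # -- manifest --
  manifest <- list(
    package_version = as.character(utils::packageVersion("hydrans")),
    seed = config$seed,
    n_sessions = length(sessions),
    views = config$views,
    families = names(fams),
    max_subset_size = config$max_subset_size,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  paths$run_manifest <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$run_manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done in %.1f s", manifest$elapsed_s)
  invisible(list(features = feats, stats = report, sweep = sweep,
                 best = best, paths = paths))
}
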