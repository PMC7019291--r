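# File formats: two-column CSV (time_s, value) per trace, a JSON manifest
# per session, CSV feature tables, JSON-lines sweep results.

#' Write one signal trace as CSV
#'
#' Two columns, `time_s` and `value`, with header. Times are derived from
#' the sampling rate starting at 0.
#'
#' @param trace a `signal_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(
    time_s = (seq_along(trace$samples) - 1) / trace$sampling_rate,
    value = trace$samples)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one signal trace from CSV
#'
#' @param path CSV file with `time_s` and `value` columns.
#' @param sampling_rate declared sampling rate in Hz; checked against the
#'   time column.
#' @param stage,modality trace metadata.
#' @return a `signal_trace`.
#' @export
read_trace <- function(path, sampling_rate, stage, modality) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)) || ncol(df) != 2L) {
    stop("trace file ", path, ": expected exactly columns time_s,value")
  }
  tt <- df$time_s
  if (nrow(df) >= 2) {
    dt <- diff(tt)
    if (any(dt <= 0)) stop("trace file ", path, ": non-monotonic time column")
    step <- stats::median(dt)
    if (abs(step - 1 / sampling_rate) > 1e-6 * max(1, step)) {
      stop(sprintf("trace file %s: time step %.6g s inconsistent with declared %g Hz",
                   path, step, sampling_rate))
    }
  }
  signal_trace(df$value, sampling_rate, stage = stage, modality = modality)
}

#' Write a subject session (manifest + trace files)
#'
#' Writes four trace CSVs next to a JSON manifest that records subject,
#' measurement, hydration label, sampling rate and the trace file names.
#'
#' @param session a `subject_session`.
#' @param dir output directory (created if needed).
#' @return path to the manifest JSON, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("%s_%s", session$subject_id, session$measurement_id)
  files <- list()
  for (nm in names(session$traces)) {
    fn <- sprintf("%s_%s.csv", stem, nm)
    write_trace(session$traces[[nm]], file.path(dir, fn))
    files[[nm]] <- fn
  }
  manifest <- list(
    subject_id = session$subject_id,
    measurement_id = session$measurement_id,
    hydration_label = session$hydration_label,
    sampling_rate = session$traces$eda_rest$sampling_rate,
    traces = files)
  mpath <- file.path(dir, sprintf("%s_manifest.json", stem))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a subject session from its manifest
#'
#' @param manifest_path path to a session manifest JSON as written by
#'   [write_session()].
#' @return a `subject_session`.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  need <- c("subject_id", "measurement_id", "hydration_label",
            "sampling_rate", "traces")
  if (!all(need %in% names(m))) {
    stop("manifest ", manifest_path, ": missing fields ",
         paste(setdiff(need, names(m)), collapse = ", "))
  }
  dir <- dirname(manifest_path)
  meta <- list(eda_rest = c("EDA", "rest"), eda_test = c("EDA", "test"),
               ppg_rest = c("PPG", "rest"), ppg_test = c("PPG", "test"))
  tr <- lapply(names(meta), function(nm) {
    read_trace(file.path(dir, m$traces[[nm]]), m$sampling_rate,
               stage = meta[[nm]][2], modality = meta[[nm]][1])
  })
  names(tr) <- names(meta)
  subject_session(m$subject_id, m$measurement_id,
                  tr$eda_rest, tr$eda_test, tr$ppg_rest, tr$ppg_test,
                  hydration_label = m$hydration_label)
}

#' Validate a feature table
#'
#' A feature table has one row per (subject, measurement) with the nine
#' index columns, plus `subject`, `measurement` and `label` columns. Views
#' combining stages (rest and test) carry suffixed index columns.
#'
#' @param table a data.frame.
#' @param feature_cols expected feature column names; defaults to the nine
#'   canonical indices.
#' @return the table, invisibly.
#' @export
validate_feature_table <- function(table, feature_cols = index_names()) {
  need <- c("subject", "measurement", "label")
  if (!all(need %in% names(table))) {
    stop("feature table missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  }
  missing <- setdiff(feature_cols, names(table))
  if (length(missing)) {
    stop("feature table missing index columns: ",
         paste(missing, collapse = ", "))
  }
  if (!all(table$label %in% c("wet", "dry"))) {
    stop("feature table labels must be 'wet' or 'dry'")
  }
  invisible(table)
}

#' Write a feature table as CSV
#' @param table validated feature table.
#' @param path output CSV path.
#' @param feature_cols feature column names to require.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, feature_cols = index_names()) {
  validate_feature_table(table, feature_cols)
  utils::write.csv(format(table, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV path as written by [write_feature_table()].
#' @param feature_cols feature column names to require.
#' @return a data.frame.
#' @export
read_feature_table <- function(path, feature_cols = index_names()) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject = "character"))
  validate_feature_table(df, feature_cols)
  df
}

#' Write sweep results as JSON lines
#'
#' One JSON object per (data view, classifier, feature subset) result, in
#' deterministic order: data view, classifier family, then the subset as a
#' bitmask over the canonical index order. Subsets serialize as canonically
#' ordered index names.
#'
#' @param results data.frame of sweep results from [exhaustive_sweep()] or
#'   [loso_evaluate()].
#' @param path output path (JSON lines).
#' @return `path`, invisibly.
#' @export
write_sweep_results <- function(results, path) {
  ord <- order(results$view, results$family, results$subset_mask)
  results <- results[ord, , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(results))) {
    r <- as.list(results[i, , drop = FALSE])
    r$subset <- strsplit(r$subset, ";", fixed = TRUE)[[1]]
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read sweep results from JSON lines
#' @param path path written by [write_sweep_results()].
#' @return a data.frame with one row per result.
#' @export
read_sweep_results <- function(path) {
  if (!file.exists(path)) stop("sweep results not found: ", path)
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    r$subset <- paste(r$subset, collapse = ";")
    as.data.frame(r)
  })
  do.call(rbind, rows)
}

#' Canonicalize a feature subset
#'
#' Sorts subset members into the canonical nine-index order and computes
#' the subset bitmask (bit i set when the i-th canonical index is present).
#'
#' @param subset character vector of index names.
#' @param universe ordered index vocabulary.
#' @return list with `names` (sorted) and `mask` (integer bitmask).
#' @export
canonical_subset <- function(subset, universe = index_names()) {
  bad <- setdiff(subset, universe)
  if (length(bad)) stop("unknown index names: ", paste(bad, collapse = ", "))
  idx <- sort(match(unique(subset), universe))
  list(names = universe[idx], mask = sum(bitwShiftL(1L, idx - 1L)))
}
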