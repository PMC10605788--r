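# On-disk dataset format and run-directory output.
#
# Canonical schema: one CSV per trial whose header is the per-sensor
# prefixed channel vocabulary (e.g. `shankR_Mag_X`), plus a manifest
# CSV (participant, surface, trial, duration, path). Values are written
# with 17 significant digits so a write/read round trip reproduces the
# doubles exactly.

.trial_filename <- function(participant_id, surface, trial_index) {
  sprintf("p%02d_%s_t%d.csv", participant_id, surface, trial_index)
}

#' Write a dataset as per-trial CSV files plus a manifest
#'
#' @param dataset A [gait_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (tr in dataset$trials) {
    cols <- list()
    for (s in names(tr$data))
      for (ch in channel_names())
        cols[[paste(s, ch, sep = "_")]] <-
          trimws(formatC(tr$data[[s]][, ch], digits = 17, format = "g"))
    fn <- .trial_filename(tr$participant_id, tr$surface, tr$trial_index)
    df <- as.data.frame(cols, check.names = FALSE)
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE,
                     quote = FALSE)
    manifest[[length(manifest) + 1L]] <- data.frame(
      participant_id = tr$participant_id, surface = tr$surface,
      trial_index = tr$trial_index, n_samples = tr$n_samples,
      duration_s = tr$n_samples / tr$sample_rate,
      sample_rate = tr$sample_rate, path = fn,
      stringsAsFactors = FALSE)
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, manifest), mp, row.names = FALSE)
  invisible(mp)
}

#' Read one trial CSV
#'
#' Columns are matched by name (order-independent) against the
#' per-sensor prefixed channel vocabulary; a sensor is included when at
#' least one of its columns is present, and a sensor present with an
#' incomplete channel set raises a schema error naming the first
#' missing column. Unknown columns are ignored with a warning. Missing
#' markers (`NA`) are preserved.
#'
#' @param path CSV path.
#' @param participant_id,surface,trial_index Trial key.
#' @param sample_rate Sampling rate in Hz.
#' @return A [gait_trial()].
#' @export
read_trial_csv <- function(path, participant_id, surface, trial_index,
                           sample_rate = 100) {
  df <- utils::read.csv(path, check.names = FALSE)
  known <- as.vector(outer(channel_names(), sensor_levels(),
                           function(ch, s) paste(s, ch, sep = "_")))
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    warning("read_trial_csv: ignoring unknown column(s): ",
            paste(unknown, collapse = ", "))
  data <- list()
  for (s in sensor_levels()) {
    want <- paste(s, channel_names(), sep = "_")
    have <- want %in% names(df)
    if (!any(have)) next
    if (!all(have))
      stop("read_trial_csv: sensor ", s, " is missing channel column ",
           want[!have][1])
    m <- as.matrix(df[want])
    storage.mode(m) <- "double"  # an all-NA column parses as logical
    colnames(m) <- channel_names()
    data[[s]] <- m
  }
  if (!length(data))
    stop("read_trial_csv: no recognizable sensor columns in ", path)
  gait_trial(participant_id, surface, trial_index, data,
             sample_rate = sample_rate)
}

#' Read a dataset directory written by [write_dataset_csv()]
#'
#' @param dir Directory containing `manifest.csv` and per-trial CSVs.
#' @return A [gait_dataset()] with `provenance = "on_disk"`.
#' @export
read_dataset_csv <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stop("read_dataset_csv: no manifest.csv in ", dir)
  manifest <- utils::read.csv(mp, stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    read_trial_csv(file.path(dir, row$path), row$participant_id,
                   row$surface, row$trial_index,
                   sample_rate = row$sample_rate %||% 100)
  })
  gait_dataset(trials, provenance = "on_disk")
}

#' Write the outputs of a cross-validation run
#'
#' Creates (or reuses) a run directory and writes the aggregated
#' metrics as JSON, the confusion matrix and per-segment predictions as
#' CSV, one history CSV per fold, and optionally experiment records and
#' a config snapshot.
#'
#' @param dir Run directory.
#' @param cv A `cv_result`.
#' @param records Optional experiment records data.frame.
#' @param config_snapshot Optional list serialized verbatim as JSON.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(dir, cv, records = NULL,
                              config_snapshot = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cv_metrics(cv)
  jsonlite::write_json(
    list(groups = cv$groups, sensors = cv$sensors,
         window_length = cv$window_length,
         n_predictions = length(cv$truth),
         precision = m$precision, recall = m$recall, f1 = m$f1,
         accuracy = m$accuracy),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame.matrix(m$confusion),
                   file.path(dir, "confusion.csv"))
  preds <- cbind(cv$provenance,
                 truth = surface_levels()[cv$truth + 1L],
                 predicted = surface_levels()[cv$predicted + 1L])
  utils::write.csv(preds, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  for (f in cv$folds)
    utils::write.csv(f$history,
                     file.path(dir, sprintf("history_fold%d.csv", f$fold)),
                     row.names = FALSE)
  if (!is.null(records))
    write_experiment_records(records, file.path(dir, "records.csv"))
  if (!is.null(config_snapshot))
    jsonlite::write_json(unclass(config_snapshot),
                         file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
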