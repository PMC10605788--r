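# Shared vocabulary: surface conditions, sensor sites, signal groups,
# trials, datasets, windowed segment sets.

#' Walking-surface condition codes
#'
#' The nine outdoor walking-surface conditions the classifier
#' distinguishes, in their fixed canonical order. The position of a code
#' in this vector (minus one) is its class ordinal, used as the axis
#' order of every confusion matrix and report.
#'
#' @return Character vector of length 9: flat even pavement (`FE`),
#'   stairs up/down (`StrU`, `StrD`), slope up/down (`SlpU`, `SlpD`),
#'   grass (`GR`), banked left/right (`BnkL`, `BnkR`), cobblestone
#'   (`CS`).
#' @export
surface_levels <- function() {
  c("FE", "StrU", "StrD", "SlpU", "SlpD", "GR", "BnkL", "BnkR", "CS")
}

#' Body-worn sensor site codes
#'
#' The six inertial measurement unit placements, in fixed canonical
#' order (their rank breaks ties deterministically wherever sensors are
#' sorted).
#'
#' @return Character vector of length 6.
#' @export
sensor_levels <- function() {
  c("wrist", "thighR", "thighL", "shankR", "shankL", "trunk")
}

#' Signal groups and their channel names
#'
#' Each inertial unit records 22 channels organised into 7 named
#' groups: 3D acceleration (`Acc`), gravity-subtracted acceleration
#' (`FreeAcc`), rate of turn (`Gyr`), magnetic field (`Mag`), velocity
#' increment (`VelInc`), orientation-increment quaternion (`Ori`, 4
#' channels), and yaw/pitch/roll Euler angles (`YPR`).
#'
#' @return Named list mapping group name to its ordered channel names.
#' @export
signal_groups <- function() {
  list(
    Acc     = c("Acc_X", "Acc_Y", "Acc_Z"),
    FreeAcc = c("FreeAcc_X", "FreeAcc_Y", "FreeAcc_Z"),
    Gyr     = c("Gyr_X", "Gyr_Y", "Gyr_Z"),
    Mag     = c("Mag_X", "Mag_Y", "Mag_Z"),
    VelInc  = c("VelInc_X", "VelInc_Y", "VelInc_Z"),
    Ori     = c("OriInc_q0", "OriInc_q1", "OriInc_q2", "OriInc_q3"),
    YPR     = c("Yaw", "Pitch", "Roll")
  )
}

#' All 22 per-sensor channel names in canonical order
#' @return Character vector of length 22.
#' @export
channel_names <- function() {
  unlist(signal_groups(), use.names = FALSE)
}

#' Build the fused channel layout for a signal/sensor configuration
#'
#' Determines the column order of the 2D input matrices fed to the
#' network: the outer loop runs over signal groups in the order given by
#' the caller (i.e. selection order), the inner loop over sensors in
#' canonical site order, and within a (group, sensor) cell the group's
#' channels in their fixed order. The layout is therefore a pure
#' function of the configuration, independent of how the configuration
#' was discovered.
#'
#' @param groups Character vector of signal group names (no duplicates).
#' @param sensors Character vector of sensor site codes (no duplicates).
#' @return A data.frame of class `channel_layout` with columns `group`,
#'   `sensor`, `channel` and `column` (the fused column name
#'   `<sensor>_<channel>`), one row per fused input column.
#' @examples
#' nrow(channel_layout("Acc", c("shankL", "shankR")))  # 6
#' @export
channel_layout <- function(groups, sensors) {
  groups <- as.character(groups)
  sensors <- as.character(sensors)
  if (length(groups) == 0L || length(sensors) == 0L)
    stop("channel_layout: need at least one group and one sensor")
  if (anyDuplicated(groups))
    stop("channel_layout: duplicate signal group in configuration")
  if (anyDuplicated(sensors))
    stop("channel_layout: duplicate sensor in configuration")
  sg <- signal_groups()
  bad <- setdiff(groups, names(sg))
  if (length(bad))
    stop("channel_layout: unknown signal group(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(sensors, sensor_levels())
  if (length(bad))
    stop("channel_layout: unknown sensor(s): ", paste(bad, collapse = ", "))
  # inner sensor loop in canonical rank order, regardless of caller order
  sensors <- sensor_levels()[sensor_levels() %in% sensors]
  rows <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(sensors, function(s) {
      data.frame(group = g, sensor = s, channel = sg[[g]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rows$column <- paste(rows$sensor, rows$channel, sep = "_")
  class(rows) <- c("channel_layout", "data.frame")
  rows
}

#' Construct a single labeled walking trial
#'
#' @param participant_id Positive integer participant identifier.
#' @param surface Surface code, one of [surface_levels()].
#' @param trial_index Integer 1--6, the repetition index within a
#'   (participant, surface) pair.
#' @param data Named list mapping sensor site code to an
#'   `n_samples x 22` numeric matrix whose columns are
#'   [channel_names()]; a site may be absent or `NULL` (fully missing
#'   recording).
#' @param sample_rate Sampling rate in Hz (the study design is 100).
#' @return Object of class `gait_trial`.
#' @export
gait_trial <- function(participant_id, surface, trial_index, data,
                       sample_rate = 100) {
  surface <- match.arg(surface, surface_levels())
  data <- data[!vapply(data, is.null, logical(1))]
  bad <- setdiff(names(data), sensor_levels())
  if (length(bad)) stop("gait_trial: unknown sensor(s): ", paste(bad, collapse = ", "))
  ns <- unique(vapply(data, nrow, integer(1)))
  if (length(ns) > 1L)
    stop("gait_trial: sensors disagree on sample count")
  for (s in names(data)) {
    if (ncol(data[[s]]) != 22L)
      stop("gait_trial: sensor ", s, " must have 22 channels")
    colnames(data[[s]]) <- channel_names()
  }
  structure(
    list(participant_id = as.integer(participant_id), surface = surface,
         trial_index = as.integer(trial_index),
         sample_rate = sample_rate, data = data,
         n_samples = if (length(ns)) ns else 0L),
    class = "gait_trial")
}

#' Construct a gait dataset (collection of trials)
#'
#' @param trials List of [gait_trial()] objects with unique
#'   (participant, surface, trial_index) keys.
#' @param provenance `"synthetic"` or `"on_disk"`.
#' @return Object of class `gait_dataset`.
#' @export
gait_dataset <- function(trials, provenance = c("synthetic", "on_disk")) {
  provenance <- match.arg(provenance)
  keys <- vapply(trials, function(tr)
    paste(tr$participant_id, tr$surface, tr$trial_index, sep = "/"),
    character(1))
  if (anyDuplicated(keys))
    stop("gait_dataset: duplicate (participant, surface, trial) key")
  structure(list(trials = trials, provenance = provenance),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat("<gait_dataset> ", length(x$trials), " trials (",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

#' @export
length.gait_dataset <- function(x) length(x$trials)

#' Trial key table of a dataset
#'
#' @param dataset A `gait_dataset`.
#' @return data.frame with columns `participant_id`, `surface`,
#'   `trial_index`, `n_samples` and one logical column per sensor site
#'   indicating presence.
#' @export
trial_keys <- function(dataset) {
  df <- do.call(rbind, lapply(dataset$trials, function(tr) {
    row <- data.frame(participant_id = tr$participant_id,
                      surface = tr$surface,
                      trial_index = tr$trial_index,
                      n_samples = tr$n_samples,
                      stringsAsFactors = FALSE)
    for (s in sensor_levels())
      row[[s]] <- s %in% names(tr$data) && !all(is.na(tr$data[[s]]))
    row
  }))
  rownames(df) <- NULL
  df
}

#' Construct a segment set (windowed network inputs)
#'
#' Internal container produced by [assemble_segments()]. Segments are
#' stored as a dense `L x C x n` array for efficient batching.
#'
#' @param x Numeric array `L x C x n_segments`.
#' @param label Integer vector of class ordinals (0-based, canonical
#'   surface order).
#' @param provenance data.frame with one row per segment: columns
#'   `participant_id`, `surface`, `trial_index`, `window_ordinal`.
#' @param layout The `channel_layout` of the columns.
#' @return Object of class `segment_set`.
#' @keywords internal
#' @export
segment_set <- function(x, label, provenance, layout) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(label),
            nrow(provenance) == length(label),
            dim(x)[2] == nrow(layout))
  structure(list(x = x, label = as.integer(label),
                 provenance = provenance, layout = layout,
                 window_length = dim(x)[1]),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> ", dim(x$x)[3], " segments of ",
      x$window_length, " x ", dim(x$x)[2], "\n", sep = "")
  invisible(x)
}

#' Number of segments in a segment set
#' @param x A `segment_set`.
#' @export
n_segments <- function(x) dim(x$x)[3]

#' Subset a segment set by segment index
#' @param set A `segment_set`.
#' @param idx Integer index vector.
#' @export
subset_segments <- function(set, idx) {
  segment_set(set$x[, , idx, drop = FALSE], set$label[idx],
              set$provenance[idx, , drop = FALSE], set$layout)
}
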