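# Signal conditioning: Butterworth smoothing, missing-value repair,
# trial dropping, window segmentation, per-fold min-max standardization.

#' Low-pass Butterworth smoothing
#'
#' Applies a second-order low-pass Butterworth filter (default cutoff
#' 6 Hz at 100 Hz sampling) to every column of a channel matrix. By
#' default the filter is run forward and backward (zero-phase), the
#' biomechanics convention, so gait-event timing is preserved; the
#' single-pass causal variant is available with `zero_phase = FALSE`.
#' Odd-reflection padding is used at the edges so a constant series
#' passes through unchanged.
#'
#' Columns containing missing values are filtered on each contiguous
#' non-missing span separately (spans too short for the filter warm-up
#' are left as-is); fully missing columns pass through untouched.
#'
#' @param series Numeric matrix `n x k` (or vector), one column per
#'   channel.
#' @param sample_rate Sampling rate in Hz.
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param order Filter order.
#' @param zero_phase Forward-backward filtering if `TRUE` (default).
#' @return Filtered matrix of the same shape.
#' @export
butterworth_lowpass <- function(series, sample_rate = 100, cutoff_hz = 6,
                                order = 2, zero_phase = TRUE) {
  vec <- is.null(dim(series))
  m <- as.matrix(series)
  n <- nrow(m)
  if (n <= 3 * order)
    stop("butterworth_lowpass: series too short for filter warm-up (n = ",
         n, ")")
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  # generous pad: the IIR impulse response must decay inside the pad
  padlen <- min(n - 1L, 100L)
  filt1 <- function(x) {
    if (zero_phase) {
      # mirror the ends, then forward-backward: the crease the mirror
      # introduces is high-frequency and dies in the stopband, and the
      # extension carries no spurious offset into the retained span
      pre <- x[seq(padlen + 1, 2)]
      post <- x[seq(length(x) - 1, length(x) - padlen)]
      y <- signal::filtfilt(bf, c(pre, x, post))
      y[(padlen + 1):(padlen + length(x))]
    } else {
      as.numeric(signal::filter(bf, x))
    }
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (!anyNA(x)) {
      out[, j] <- filt1(x)
    } else if (!all(is.na(x))) {
      runs <- rle(!is.na(x))
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values & runs$lengths > 3 * order + padlen))
        out[starts[r]:ends[r], j] <- filt1(x[starts[r]:ends[r]])
    }
  }
  if (vec) out[, 1] else out
}

#' Repair missing samples by nearest-preceding fill
#'
#' Each missing value takes the nearest preceding observed value; a
#' leading run of missing values takes the first subsequent observed
#' value. A column with no observed value at all cannot be repaired and
#' raises an error (such streams are meant to be handled by
#' [drop_unusable()] instead).
#'
#' @param series Numeric matrix (or vector) with `NA` missing markers.
#' @return Matrix of the same shape with no missing values.
#' @export
fill_missing <- function(series) {
  vec <- is.null(dim(series))
  m <- as.matrix(series)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (all(is.na(x)))
      stop("fill_missing: channel ", j, " is entirely missing (unrepairable)")
    x <- zoo::na.locf(x, na.rm = FALSE)
    x <- zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)
    m[, j] <- x
  }
  if (vec) m[, 1] else m
}

#' Drop trials whose required sensors are unusable
#'
#' A trial is unusable for a configuration when any required sensor is
#' absent or its recording is entirely missing.
#'
#' @param dataset A [gait_dataset()].
#' @param required_sensors Character vector of sensor codes the
#'   configuration needs.
#' @return List with `dataset` (the usable trials) and `dropped`
#'   (data.frame of the excluded trials' keys and the sensor that
#'   caused the exclusion; zero rows when nothing was dropped).
#' @export
drop_unusable <- function(dataset, required_sensors) {
  required_sensors <- as.character(required_sensors)
  bad <- setdiff(required_sensors, sensor_levels())
  if (length(bad))
    stop("drop_unusable: unknown sensor(s): ", paste(bad, collapse = ", "))
  keep <- logical(length(dataset$trials))
  drops <- list()
  for (i in seq_along(dataset$trials)) {
    tr <- dataset$trials[[i]]
    missing <- required_sensors[vapply(required_sensors, function(s)
      is.null(tr$data[[s]]) || all(is.na(tr$data[[s]])), logical(1))]
    keep[i] <- length(missing) == 0L
    if (!keep[i])
      drops[[length(drops) + 1L]] <- data.frame(
        participant_id = tr$participant_id, surface = tr$surface,
        trial_index = tr$trial_index, missing_sensor = missing[1],
        stringsAsFactors = FALSE)
  }
  dropped <- if (length(drops)) do.call(rbind, drops) else
    data.frame(participant_id = integer(), surface = character(),
               trial_index = integer(), missing_sensor = character(),
               stringsAsFactors = FALSE)
  ds <- dataset
  ds$trials <- dataset$trials[keep]
  list(dataset = ds, dropped = dropped)
}

#' Cut a channel matrix into non-overlapping windows
#'
#' Produces `floor(n / L)` consecutive disjoint windows starting at the
#' first sample; the trailing remainder is discarded. Zero windows is a
#' valid result for a trial shorter than one window.
#'
#' @param series Numeric matrix `n x k`.
#' @param window_length Window length `L` in samples.
#' @return List of `L x k` matrices.
#' @export
segment_trial <- function(series, window_length) {
  stopifnot(window_length >= 1)
  m <- as.matrix(series)
  nwin <- nrow(m) %/% window_length
  if (nwin == 0L) return(list())
  lapply(seq_len(nwin), function(w)
    m[((w - 1L) * window_length + 1L):(w * window_length), , drop = FALSE])
}

#' Fit the per-channel min-max scaler on training segments
#'
#' Learns the global per-channel minimum and maximum over all segments
#' of the (training-fold) set. Applying the fitted state maps training
#' data into `[0, 1]`; validation/test data may fall outside that range
#' and are deliberately not clipped.
#'
#' @param train_set A `segment_set` drawn from the training fold only.
#' @return Object of class `scaler_state`.
#' @export
fit_scaler <- function(train_set) {
  stopifnot(inherits(train_set, "segment_set"))
  lo <- apply(train_set$x, 2, min)
  hi <- apply(train_set$x, 2, max)
  structure(list(min = lo, max = hi,
                 columns = train_set$layout$column,
                 fitted_on = nrow(unique(train_set$provenance[
                   c("participant_id", "surface", "trial_index")]))),
            class = "scaler_state")
}

#' Apply a fitted min-max scaler
#'
#' @param state A `scaler_state` from [fit_scaler()].
#' @param set A `segment_set` with the same channel layout.
#' @return The scaled `segment_set`; channels that were constant in
#'   training map to 0.
#' @export
apply_scaler <- function(state, set) {
  if (!inherits(state, "scaler_state"))
    stop("apply_scaler: scaler has not been fitted")
  if (!identical(state$columns, set$layout$column))
    stop("apply_scaler: channel layout mismatch")
  rng <- state$max - state$min
  x <- set$x
  for (j in seq_along(rng)) {
    x[, j, ] <- if (rng[j] > 0) (x[, j, ] - state$min[j]) / rng[j] else 0
  }
  set$x <- x
  set
}

#' Smooth and repair every trial of a dataset
#'
#' Runs the conditioning chain in its fixed order: low-pass smoothing on
#' non-missing spans first, then missing-value repair. Sensors whose
#' recording is entirely missing are left missing (they are excluded
#' later by [drop_unusable()] when a configuration requires them).
#'
#' @param dataset A [gait_dataset()].
#' @param cutoff_hz,order,zero_phase Filter settings, see
#'   [butterworth_lowpass()].
#' @return The conditioned dataset.
#' @export
preprocess_dataset <- function(dataset, cutoff_hz = 6, order = 2,
                               zero_phase = TRUE) {
  for (i in seq_along(dataset$trials)) {
    tr <- dataset$trials[[i]]
    for (s in names(tr$data)) {
      m <- tr$data[[s]]
      if (all(is.na(m))) next
      m <- butterworth_lowpass(m, sample_rate = tr$sample_rate,
                               cutoff_hz = cutoff_hz, order = order,
                               zero_phase = zero_phase)
      if (anyNA(m)) m <- fill_missing(m)
      dataset$trials[[i]]$data[[s]] <- m
    }
  }
  dataset
}
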