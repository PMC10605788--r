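# Fusion of per-sensor signal groups into windowed 2D network inputs.

#' Assemble fused, windowed input matrices
#'
#' For every usable trial, selects the requested signal groups from the
#' requested sensors, stacks them column-wise in the order defined by
#' [channel_layout()], and cuts the fused matrix into non-overlapping
#' windows of `window_length` samples. Trials lacking any requested
#' sensor are excluded (see [drop_unusable()]). Labels and trial
#' provenance are carried on every window so fold membership can be
#' enforced downstream at the trial level.
#'
#' @param dataset A preprocessed [gait_dataset()] (smoothed and
#'   repaired; see [preprocess_dataset()]).
#' @param groups Ordered character vector of signal group names.
#' @param sensors Character vector of sensor site codes.
#' @param window_length Window length `L` in samples.
#' @return A `segment_set` whose matrices are `L x C`, with
#'   `C = sum(group widths) * length(sensors)`.
#' @export
assemble_segments <- function(dataset, groups, sensors, window_length) {
  layout <- channel_layout(groups, sensors)
  usable <- drop_unusable(dataset, unique(layout$sensor))
  ds <- usable$dataset
  if (length(ds$trials) == 0L)
    stop("assemble_segments: no usable trials for sensors ",
         paste(unique(layout$sensor), collapse = ", "))
  surf_ord <- stats::setNames(seq_along(surface_levels()) - 1L,
                              surface_levels())
  mats <- list(); labs <- integer(); prov <- list()
  for (tr in ds$trials) {
    fused <- do.call(cbind, lapply(seq_len(nrow(layout)), function(r)
      tr$data[[layout$sensor[r]]][, layout$channel[r]]))
    wins <- segment_trial(fused, window_length)
    if (length(wins) == 0L) next
    for (w in seq_along(wins)) {
      mats[[length(mats) + 1L]] <- wins[[w]]
      labs[length(labs) + 1L] <- surf_ord[[tr$surface]]
      prov[[length(prov) + 1L]] <- data.frame(
        participant_id = tr$participant_id, surface = tr$surface,
        trial_index = tr$trial_index, window_ordinal = w - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(mats) == 0L)
    stop("assemble_segments: no trial is long enough for a ",
         window_length, "-sample window")
  x <- array(unlist(mats, use.names = FALSE),
             dim = c(window_length, nrow(layout), length(mats)))
  segment_set(x, labs, do.call(rbind, prov), layout)
}

#' Per-class window counts for a segment set
#'
#' @param set A `segment_set`.
#' @return Named integer vector over [surface_levels()] plus a `Total`
#'   entry.
#' @export
segment_class_counts <- function(set) {
  counts <- table(factor(set$provenance$surface, levels = surface_levels()))
  out <- c(as.integer(counts), sum(counts))
  names(out) <- c(surface_levels(), "Total")
  out
}
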