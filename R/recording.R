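#' Multichannel recording buffer
#'
#' Thin container for extracellular data: a channels x time matrix of samples
#' in microvolts plus the sampling rate.
#'
#' @param samples numeric matrix, channels in rows, time in columns (uV).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @return object of class `recording`.
#' @export
recording <- function(samples, sampling_rate = 30000) {
  samples <- as.matrix(samples)
  if (!all(is.finite(samples))) stop("recording samples must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be > 0")
  structure(list(samples = samples, sampling_rate = sampling_rate),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channel(s), %.2f s at %g Hz\n",
              nrow(x$samples), ncol(x$samples) / x$sampling_rate,
              x$sampling_rate))
  if (inherits(x, "labeled_recording"))
    cat(sprintf("  ground truth: %d events, %d unit(s)\n",
                nrow(x$true_events), length(x$true_units)))
  invisible(x)
}

#' One cluster of sorted spike events
#'
#' @param unit_id integer identifier.
#' @param times event times in seconds, sorted non-decreasing.
#' @param segments optional n x 90 matrix of peak-aligned waveforms (uV).
#' @param scores optional numeric vector of per-event MSLE scores.
#' @param labels optional factor of ground-truth labels (synthetic units).
#' @param channel optional channel index (scalar or per-event vector).
#' @return object of class `sorted_unit`.
#' @export
sorted_unit <- function(unit_id, times, segments = NULL, scores = NULL,
                        labels = NULL, channel = NA_integer_) {
  times <- as.numeric(times)
  if (is.unsorted(times)) stop("'times' must be sorted")
  if (!is.null(segments)) {
    segments <- as.matrix(segments)
    if (nrow(segments) != length(times))
      stop("'segments' and 'times' must have the same length")
  }
  if (!is.null(scores) && length(scores) != length(times))
    stop("'scores' and 'times' must have the same length")
  structure(list(unit_id = as.integer(unit_id), times = times,
                 segments = segments, scores = scores, labels = labels,
                 channel = channel),
            class = "sorted_unit")
}

#' @export
print.sorted_unit <- function(x, ...) {
  cat(sprintf("sorted_unit %d: %d events%s%s\n", x$unit_id, length(x$times),
              if (!is.null(x$scores)) ", scored" else "",
              if (!is.null(x$labels)) ", labeled" else ""))
  invisible(x)
}
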