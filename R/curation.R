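#' Pre-clustering event filter
#'
#' Scores detected events with the autoencoder and removes those whose MSLE
#' strictly exceeds the threshold, so that clustering only sees likely
#' neural spikes. Order is preserved; the removal log lists every excluded
#' event with its score, and kept plus removed always partition the input.
#'
#' @param segments n x 90 matrix of detected event segments.
#' @param model a fitted [spike_autoencoder()].
#' @param threshold MSLE threshold (defaults to the model's stored value).
#' @return list with `kept` (row indices kept, in order), `removed`
#'   (data.frame index, msle), `scores` (all scores, input order) and
#'   `segments` (the kept rows).
#' @export
prefilter_events <- function(segments, model, threshold = model$threshold) {
  segments <- as.matrix(segments)
  scores <- predict(model, segments)
  keep <- scores <= threshold
  list(kept = which(keep),
       removed = data.frame(index = which(!keep), msle = scores[!keep]),
       scores = scores,
       segments = segments[keep, , drop = FALSE])
}

#' Score a sorted unit's events
#'
#' @param unit a [sorted_unit()] with segments.
#' @param model a fitted [spike_autoencoder()].
#' @return the unit with its `scores` field filled.
#' @export
score_unit <- function(unit, model) {
  stopifnot(inherits(unit, "sorted_unit"))
  if (is.null(unit$segments)) stop("unit has no segments to score")
  unit$scores <- predict(model, unit$segments)
  unit
}

#' Classify a sorted unit as neural, hybrid or non-neural
#'
#' The unit's neural fraction is the proportion of its events whose MSLE is
#' at or below the threshold. Units are triaged into three classes:
#' `NEURAL_UNIT` when the fraction is at least `neural_cut` (0.95),
#' `HYBRID_UNIT` between `nonneural_cut` (0.50, inclusive) and `neural_cut`,
#' `NON_NEURAL_UNIT` below 0.50.
#'
#' @param unit a scored [sorted_unit()] (see [score_unit()]).
#' @param threshold per-event MSLE threshold.
#' @param neural_cut,nonneural_cut class boundaries on the neural fraction.
#' @return list with `kind` (factor) and `neural_fraction`.
#' @export
classify_unit <- function(unit, threshold = 1.5, neural_cut = 0.95,
                          nonneural_cut = 0.50) {
  stopifnot(inherits(unit, "sorted_unit"))
  if (is.null(unit$scores)) stop("unit must be scored first (see score_unit)")
  if (length(unit$times) == 0) stop("cannot classify an empty unit")
  frac <- mean(unit$scores <= threshold)
  kind <- if (frac >= neural_cut) "NEURAL_UNIT"
          else if (frac >= nonneural_cut) "HYBRID_UNIT"
          else "NON_NEURAL_UNIT"
  list(kind = factor(kind, levels = c("NEURAL_UNIT", "HYBRID_UNIT",
                                      "NON_NEURAL_UNIT")),
       neural_fraction = frac)
}

#' Refine a unit by removing high-MSLE events
#'
#' Event-level refinement for hybrid units: events with MSLE above the
#' threshold are dropped, the rest keep their time order. An empty result
#' is returned (with a warning) when every event exceeds the threshold.
#'
#' @inheritParams classify_unit
#' @return the refined [sorted_unit()].
#' @export
refine_unit <- function(unit, threshold = 1.5) {
  stopifnot(inherits(unit, "sorted_unit"))
  if (is.null(unit$scores)) stop("unit must be scored first (see score_unit)")
  keep <- unit$scores <= threshold
  if (!any(keep)) warning("refinement removed every event of unit ", unit$unit_id)
  sorted_unit(unit$unit_id, unit$times[keep],
              segments = if (!is.null(unit$segments)) unit$segments[keep, , drop = FALSE],
              scores = unit$scores[keep],
              labels = if (!is.null(unit$labels)) unit$labels[keep],
              channel = unit$channel)
}

#' Post-clustering curation of a sorting
#'
#' Applies the unit triage policy: neural units are kept intact, non-neural
#' units are discarded, hybrid units are refined event by event. Discarded
#' units are retained in the report, never silently deleted.
#'
#' @param units list of [sorted_unit()] objects with segments.
#' @param model a fitted [spike_autoencoder()].
#' @param threshold per-event MSLE threshold.
#' @param neural_cut,nonneural_cut triage boundaries (see [classify_unit()]).
#' @return list with `units` (kept/refined units) and `report`, a
#'   `curation_report` data.frame: unit_id, class, neural_fraction,
#'   n_events, n_removed, action.
#' @export
curate_sorting <- function(units, model, threshold = 1.5, neural_cut = 0.95,
                           nonneural_cut = 0.50) {
  units <- lapply(units, function(u)
    if (is.null(u$scores)) score_unit(u, model) else u)
  rows <- list()
  kept <- list()
  for (u in units) {
    cls <- classify_unit(u, threshold, neural_cut, nonneural_cut)
    action <- switch(as.character(cls$kind),
                     NEURAL_UNIT = "kept",
                     HYBRID_UNIT = "refined",
                     NON_NEURAL_UNIT = "discarded")
    n0 <- length(u$times)
    if (action == "kept") {
      kept[[length(kept) + 1L]] <- u
      n_rm <- 0L
    } else if (action == "refined") {
      r <- refine_unit(u, threshold)
      kept[[length(kept) + 1L]] <- r
      n_rm <- n0 - length(r$times)
    } else {
      n_rm <- n0
    }
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = u$unit_id, class = as.character(cls$kind),
      neural_fraction = cls$neural_fraction, n_events = n0,
      n_removed = n_rm, action = action)
  }
  report <- do.call(rbind, rows)
  report$threshold <- threshold
  class(report) <- c("curation_report", "data.frame")
  list(units = kept, report = report)
}
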