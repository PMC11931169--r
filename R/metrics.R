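#' Match sorted events to ground-truth spike times
#'
#' Greedy one-to-one matching in time order: a sorted event matches a
#' ground-truth event when their time stamps differ by at most `tol`
#' seconds; each event is used at most once and ties go to the earlier
#' ground-truth event. For every ground-truth unit, the sorted unit with the
#' highest matched fraction is selected; its matched events count as neural
#' (`n_neural`) and its remaining events as non-neural (`n_non_neural`).
#'
#' @param gt_units list of numeric vectors of ground-truth spike times
#'   (seconds, sorted), named by unit id.
#' @param sorted_units list of [sorted_unit()] objects (or plain numeric
#'   time vectors).
#' @param tol matching tolerance in seconds (1 ms by default).
#' @return a `match_report` data.frame with one row per ground-truth unit:
#'   `gt_unit`, `best_sorted`, `n_gt`, `n_neural`, `n_non_neural`.
#' @export
match_events <- function(gt_units, sorted_units, tol = 1e-3) {
  get_times <- function(u) if (inherits(u, "sorted_unit")) u$times else as.numeric(u)
  get_id <- function(u, i) if (inherits(u, "sorted_unit")) u$unit_id else i
  rows <- list()
  for (g in seq_along(gt_units)) {
    gt <- as.numeric(gt_units[[g]])
    if (is.unsorted(gt)) stop("ground-truth times must be sorted")
    best <- list(n = -1L, id = NA_integer_, total = 0L)
    for (s in seq_along(sorted_units)) {
      st <- get_times(sorted_units[[s]])
      if (is.unsorted(st)) stop("sorted-unit times must be sorted")
      n_match <- greedy_match_count(gt, st, tol)
      if (n_match > best$n)
        best <- list(n = n_match, id = get_id(sorted_units[[s]], s),
                     total = length(st))
    }
    rows[[g]] <- data.frame(
      gt_unit = if (!is.null(names(gt_units))) names(gt_units)[g] else as.character(g),
      best_sorted = best$id, n_gt = length(gt),
      n_neural = max(best$n, 0L), n_non_neural = best$total - max(best$n, 0L))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gt_unit = character(0), best_sorted = integer(0),
               n_gt = integer(0), n_neural = integer(0),
               n_non_neural = integer(0))
  class(out) <- c("match_report", "data.frame")
  out
}

## greedy in-order one-to-one matching within tol; ties (a sorted event
## within tol of several ground-truth events) resolve to the earliest
## unconsumed ground-truth event
greedy_match_count <- function(gt, st, tol) {
  i <- 1L; j <- 1L; n <- 0L
  while (i <= length(gt) && j <= length(st)) {
    d <- st[j] - gt[i]
    if (abs(d) <= tol) { n <- n + 1L; i <- i + 1L; j <- j + 1L }
    else if (d < 0) j <- j + 1L
    else i <- i + 1L
  }
  n
}

#' Spike-sorting sensitivity
#'
#' For a best-matched sorted unit, the fraction of its events that
#' correspond to ground-truth spikes:
#' `n_neural / (n_neural + n_non_neural)`.
#'
#' @param report a `match_report` from [match_events()], or a single row.
#' @return numeric vector of per-unit sensitivities (NA for empty units).
#' @export
sensitivity <- function(report) {
  tot <- report$n_neural + report$n_non_neural
  ifelse(tot > 0, report$n_neural / tot, NA_real_)
}

#' Inter-spike-interval violation rate
#'
#' Violations are intervals shorter than `window` (1.5 ms). In `"pairwise"`
#' mode (the default) every ordered pair of events closer than the window
#' counts as one violation and the count is divided by the number of
#' events, so the rate can exceed 100% when several events crowd into one
#' window. `"consecutive"` mode counts only adjacent-interval violations
#' over `n - 1` intervals.
#'
#' @param times sorted event times in seconds.
#' @param window violation window in seconds (default 1.5 ms).
#' @param mode `"pairwise"` or `"consecutive"`.
#' @return violation rate (proportion; 0 when fewer than 2 events).
#' @export
isi_violation_rate <- function(times, window = 1.5e-3,
                               mode = c("pairwise", "consecutive")) {
  mode <- match.arg(mode)
  times <- as.numeric(times)
  if (is.unsorted(times)) stop("'times' must be sorted")
  n <- length(times)
  if (n < 2) return(0)
  if (mode == "consecutive") {
    mean(diff(times) < window)
  } else {
    ## pairs (i < j) with t_j - t_i < window, counted per event
    upper <- findInterval(times + window, times, left.open = TRUE)
    sum(upper - seq_len(n)) / n
  }
}

#' Accept or reject a unit on its ISI violation rate
#'
#' @param rate ISI violation rate (>= 0).
#' @return `TRUE` when the rate is strictly below 5%.
#' @export
accept_unit <- function(rate) {
  if (any(rate < 0)) stop("'rate' must be >= 0")
  rate < 0.05
}

#' Silhouette scores of a clustering
#'
#' Per-point silhouette `S_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the
#' mean distance to the other points of the same cluster and `b_i` the mean
#' distance to the points of the nearest other cluster, computed with
#' Euclidean distance on the raw segments. Wraps [cluster::silhouette()].
#'
#' @param points n x p numeric matrix (rows are events).
#' @param labels cluster assignment (length n, at least 2 distinct values).
#' @return list with `s` (per-point scores in `[-1, 1]`), `cluster`
#'   (the labels) and `cluster_means` (named per-cluster mean silhouette).
#' @export
silhouette_scores <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.vector(labels)
  if (length(labels) != nrow(points))
    stop("'labels' must have one entry per row of 'points'")
  if (length(unique(labels)) < 2)
    stop("silhouette needs at least 2 clusters")
  f <- factor(labels)
  sil <- cluster::silhouette(as.integer(f), stats::dist(points))
  s <- sil[, "sil_width"]
  means <- tapply(s, f, mean)
  list(s = as.numeric(s), cluster = labels,
       cluster_means = stats::setNames(as.numeric(means), levels(f)))
}

#' Event-classification accuracy against ground truth
#'
#' Fraction of events where the decision matches the label: `NEURAL` maps
#' to `SPIKE`, and both non-neural types map to `NON_NEURAL`.
#'
#' @param true_labels factor/character with values `NEURAL`, `TYPE1`, `TYPE2`.
#' @param decisions factor/character with values `SPIKE`, `NON_NEURAL`
#'   (see [classify_events()]).
#' @return proportion correct.
#' @export
classification_accuracy <- function(true_labels, decisions) {
  if (length(true_labels) != length(decisions))
    stop("'true_labels' and 'decisions' must have the same length")
  expected <- ifelse(as.character(true_labels) == "NEURAL", "SPIKE", "NON_NEURAL")
  mean(expected == as.character(decisions))
}
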