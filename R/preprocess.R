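#' Zero-phase bandpass filter
#'
#' Butterworth bandpass applied forward and backward (`signal::filtfilt`) so
#' spike peaks are not shifted in time. Removes DC and out-of-band
#' interference before detection.
#'
#' @param rec a [recording()].
#' @param low,high band corners in Hz (`0 < low < high < sampling_rate / 2`).
#' @param order filter order (per pass).
#' @return filtered [recording()], same shape.
#' @export
bandpass_filter <- function(rec, low = 300, high = 6000, order = 3) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band corners must satisfy 0 < low < high < sampling_rate/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- t(apply(rec$samples, 1, function(ch) signal::filtfilt(bf, ch)))
  if (nrow(rec$samples) == 1) out <- matrix(out, nrow = 1)
  rec$samples <- out
  rec
}

#' Common median reference
#'
#' Subtracts the per-sample median across channels from every channel,
#' cancelling interference shared by the array. With a single channel the
#' recording is returned unchanged, with a warning.
#'
#' @param rec a [recording()].
#' @return referenced [recording()].
#' @export
common_median_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$samples) < 2) {
    warning("common median reference needs >= 2 channels; returning input")
    return(rec)
  }
  med <- apply(rec$samples, 2, stats::median)
  rec$samples <- sweep(rec$samples, 2, med)
  rec
}

#' Robust noise standard deviation
#'
#' Estimates the background noise scale as `median(|x|) / 0.6745`, the
#' median-absolute-deviation estimator about zero. Unlike the plain standard
#' deviation it is barely perturbed by sparse large spikes.
#'
#' @param x numeric vector of samples from one channel (>= 1000 samples).
#' @return estimated noise standard deviation (uV).
#' @export
noise_sigma <- function(x) {
  if (length(x) < 1000)
    stop("need at least 1000 samples for a noise estimate")
  stats::median(abs(x)) / 0.6745
}

#' Calibrate the noise floor
#'
#' Applies one global gain so that the robust noise estimate (averaged over
#' channels) equals `target_sigma`. A fixed MSLE threshold trained at a
#' 10 uV noise floor only transfers to a new recording when the new floor is
#' commensurate, so recordings are calibrated rather than left at their raw
#' gain.
#'
#' @param rec a [recording()].
#' @param target_sigma desired noise standard deviation (uV).
#' @return rescaled [recording()] with attribute `gain`.
#' @export
normalize_noise <- function(rec, target_sigma = 10) {
  stopifnot(inherits(rec, "recording"))
  est <- mean(apply(rec$samples, 1, noise_sigma))
  if (est <= 0) stop("noise estimate is zero; cannot normalize")
  rec$samples <- rec$samples * (target_sigma / est)
  attr(rec, "gain") <- target_sigma / est
  rec
}

#' Threshold-crossing event detection
#'
#' Finds negative excursions below `-k_sigma` times the per-channel robust
#' noise estimate and reports one event per excursion at its local minimum.
#' Events on the same channel are separated by at least `dead_time_ms`; when
#' several channels cross within the dead time, only the channel with the
#' largest absolute peak keeps the event.
#'
#' @param rec a [recording()].
#' @param k_sigma detection threshold in noise standard deviations.
#' @param dead_time_ms minimum separation between events (ms).
#' @return data.frame with columns `peak_sample` (1-based), `channel`,
#'   `peak_uV` (signed) and `time_s`, sorted by time.
#' @export
detect_events <- function(rec, k_sigma = 5, dead_time_ms = 1) {
  stopifnot(inherits(rec, "recording"))
  if (k_sigma <= 0) stop("'k_sigma' must be > 0")
  fs <- rec$sampling_rate
  dead <- max(1L, round(dead_time_ms / 1000 * fs))
  out <- list()
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    thr <- -k_sigma * noise_sigma(x)
    below <- x < thr
    if (!any(below)) next
    ## group threshold crossings into excursions, take each local minimum
    idx <- which(below)
    brk <- c(0L, which(diff(idx) > 1L), length(idx))
    peaks <- vapply(seq_len(length(brk) - 1L), function(k) {
      seg <- idx[(brk[k] + 1L):brk[k + 1L]]
      seg[which.min(x[seg])]
    }, integer(1))
    ## enforce dead time within the channel (keep the larger peak)
    if (length(peaks) > 1) {
      keep <- logical(length(peaks))
      last <- -Inf; last_k <- 0L
      for (k in seq_along(peaks)) {
        if (peaks[k] - last >= dead) {
          keep[k] <- TRUE; last <- peaks[k]; last_k <- k
        } else if (x[peaks[k]] < x[peaks[last_k]]) {
          keep[last_k] <- FALSE; keep[k] <- TRUE
          last <- peaks[k]; last_k <- k
        }
      }
      peaks <- peaks[keep]
    }
    if (length(peaks))
      out[[length(out) + 1L]] <- data.frame(
        peak_sample = peaks, channel = ch, peak_uV = x[peaks])
  }
  if (!length(out))
    return(data.frame(peak_sample = integer(0), channel = integer(0),
                      peak_uV = numeric(0), time_s = numeric(0)))
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$peak_sample, ev$channel), , drop = FALSE]
  ## cross-channel deduplication: within the dead time the largest |peak| wins
  if (nrow(ev) > 1) {
    keep <- rep(TRUE, nrow(ev))
    i <- 1L
    while (i < nrow(ev)) {
      j <- i + 1L
      while (j <= nrow(ev) && ev$peak_sample[j] - ev$peak_sample[i] < dead) {
        if (abs(ev$peak_uV[j]) > abs(ev$peak_uV[i])) keep[i] <- FALSE
        else keep[j] <- FALSE
        j <- j + 1L
      }
      i <- j
    }
    ev <- ev[keep, , drop = FALSE]
  }
  ev$time_s <- (ev$peak_sample - 1) / fs
  rownames(ev) <- NULL
  ev
}

#' Extract peak-aligned 3 ms segments
#'
#' Cuts the 90-sample window (1.5 ms either side at 30 kHz) around each
#' detected event on its channel and re-centres it so the absolute-maximum
#' sample sits at index 46 (ties broken towards the earliest sample).
#' Recordings at other sampling rates are linearly resampled to 30 kHz
#' first. Events whose window would leave the recording are skipped with a
#' warning.
#'
#' @param rec a [recording()].
#' @param events data.frame from [detect_events()] (columns `peak_sample`,
#'   `channel`).
#' @return list with `segments` (n x 90 matrix), `events` (the rows actually
#'   extracted).
#' @export
extract_segments <- function(rec, events) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sampling_rate
  x <- rec$samples
  if (fs != 30000) {
    n_new <- round(ncol(x) / fs * 30000)
    x <- t(apply(x, 1, function(ch)
      stats::approx(seq_along(ch), ch, n = n_new)$y))
    if (nrow(rec$samples) == 1) x <- matrix(x, nrow = 1)
    events$peak_sample <- round((events$peak_sample - 1) / fs * 30000) + 1L
  }
  n_t <- ncol(x)
  half <- 45L
  ok <- logical(nrow(events))
  segs <- matrix(NA_real_, nrow(events), 90)
  for (i in seq_len(nrow(events))) {
    p <- events$peak_sample[i]
    if (p - half < 1 || p + 44L > n_t) next
    seg <- x[events$channel[i], (p - half):(p + 44L)]
    ## re-centre on the absolute maximum (earliest sample on ties)
    p2 <- p - half - 1L + which.max(abs(seg))
    if (p2 - half < 1 || p2 + 44L > n_t) next
    segs[i, ] <- x[events$channel[i], (p2 - half):(p2 + 44L)]
    ok[i] <- TRUE
  }
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge were skipped")
  list(segments = segs[ok, , drop = FALSE], events = events[ok, , drop = FALSE])
}

#' Linear signal-to-noise ratio of a segment
#'
#' Peak magnitude of the aligned segment divided by the background noise
#' standard deviation. An event with SNR below the threshold (default 10)
#' is treated as a Type II non-neural event.
#'
#' @param segment numeric vector of 90 samples (peak at index 46).
#' @param sigma background noise standard deviation (uV, > 0).
#' @return linear SNR.
#' @export
snr <- function(segment, sigma) {
  if (sigma <= 0) stop("'sigma' must be > 0")
  max(abs(segment)) / sigma
}

#' Detection front end: filter, reference, calibrate, detect, extract
#'
#' Runs the fixed preprocessing order (bandpass, common median reference,
#' noise-floor calibration, threshold detection, segment extraction) and
#' returns peak-aligned feature vectors ready for scoring.
#'
#' @param rec a [recording()].
#' @param low,high bandpass corners (Hz).
#' @param target_sigma calibration target for the noise floor (uV).
#' @param k_sigma detection threshold (noise SDs).
#' @param dead_time_ms detector dead time (ms).
#' @return list with `segments`, `events`, and the preprocessed `recording`.
#' @export
preprocess_recording <- function(rec, low = 300, high = 6000,
                                 target_sigma = 10, k_sigma = 5,
                                 dead_time_ms = 1) {
  rec <- bandpass_filter(rec, low, high)
  if (nrow(rec$samples) >= 2) rec <- common_median_reference(rec)
  rec <- normalize_noise(rec, target_sigma)
  ev <- detect_events(rec, k_sigma = k_sigma, dead_time_ms = dead_time_ms)
  out <- extract_segments(rec, ev)
  out$recording <- rec
  out
}
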