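#' Poisson spike train with refractory period
#'
#' Homogeneous Poisson process thinned by an absolute refractory period:
#' exponential inter-spike intervals are drawn and the refractory gap added,
#' so consecutive gaps are always at least `refractory` seconds.
#'
#' @param rate mean firing rate in Hz (>= 0).
#' @param duration recording duration in seconds.
#' @param refractory minimum inter-spike interval in seconds.
#' @param seed integer seed.
#' @return strictly increasing numeric vector of spike times in `[0, duration)`.
#' @export
poisson_train <- function(rate, duration, refractory = 0.002, seed = 1) {
  if (!is.numeric(rate) || rate < 0) stop("'rate' must be >= 0")
  if (refractory < 0) stop("'refractory' must be >= 0")
  if (duration <= 0) stop("'duration' must be > 0")
  set.seed(as.integer(seed))
  if (rate == 0) return(numeric(0))
  ## draw gaps in blocks until past the end
  times <- numeric(0)
  t <- 0
  repeat {
    gaps <- stats::rexp(max(16, ceiling(rate * duration * 0.5)), rate) + refractory
    new <- t + cumsum(gaps)
    times <- c(times, new)
    t <- times[length(times)]
    if (t >= duration) break
  }
  times[times < duration]
}

#' Periodic (Type I) artifact segment
#'
#' One 90-sample window of a sinusoid, sawtooth or square wave of the given
#' frequency and amplitude, plus i.i.d. Gaussian noise. These emulate
#' non-biological interference (mains harmonics, stimulation or movement
#' artifacts) that threshold detection picks up alongside spikes.
#'
#' @param kind one of `"sine"`, `"sawtooth"`, `"square"`.
#' @param freq fundamental frequency in Hz (> 0).
#' @param amplitude peak amplitude in microvolts (> 0).
#' @param noise_sigma standard deviation of additive Gaussian noise (uV).
#' @param seed integer seed.
#' @param phase optional phase offset in radians; drawn uniformly when `NULL`.
#' @return numeric vector of 90 samples (microvolts).
#' @export
type1_event <- function(kind = c("sine", "sawtooth", "square"), freq, amplitude,
                        noise_sigma = 10, seed = 1, phase = NULL) {
  kind <- match.arg(kind)
  if (freq <= 0) stop("'freq' must be > 0")
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  set.seed(as.integer(seed))
  if (is.null(phase)) phase <- stats::runif(1, 0, 2 * pi)
  tt <- (seq_len(90) - 1) / 30000
  ph <- 2 * pi * freq * tt + phase
  w <- switch(kind,
    sine     = amplitude * sin(ph),
    sawtooth = amplitude * (2 * ((ph / (2 * pi)) %% 1) - 1),
    square   = amplitude * sign(sin(ph)))
  ## sign(0) = 0 would leave a non-level sample on the square wave
  if (kind == "square") w[w == 0] <- amplitude
  if (noise_sigma > 0) w <- w + stats::rnorm(90, 0, noise_sigma)
  w
}

#' Low-SNR (Type II) spike segment
#'
#' A spike template buried in heavy Gaussian noise, emulating events from
#' remote neurons. The template is attenuated only when its amplitude would
#' violate the linear SNR bound `amplitude / noise_sigma < snr_threshold`;
#' the labeled-set generator ([labeled_events()]) additionally attenuates to
#' a deep sub-noise SNR to reflect genuinely remote sources.
#'
#' @param template a [spike_template()].
#' @param noise_sigma Gaussian noise standard deviation in uV (> 0; 30 uV is
#'   the reference regime for remote sources).
#' @param seed integer seed.
#' @param snr_threshold linear SNR bound separating neural from Type II
#'   events (default 10).
#' @param target_snr optional linear SNR the template is scaled to before
#'   noise is added; `NULL` preserves the template amplitude (capped just
#'   under `snr_threshold * noise_sigma`).
#' @return numeric vector of 90 samples (microvolts).
#' @export
type2_event <- function(template, noise_sigma = 30, seed = 1,
                        snr_threshold = 10, target_snr = NULL) {
  stopifnot(inherits(template, "spike_template"))
  if (noise_sigma <= 0)
    stop("'noise_sigma' must be > 0: the SNR bound cannot be met without noise")
  set.seed(as.integer(seed))
  amp <- template$amplitude
  scale <- if (is.null(target_snr)) {
    min(1, 0.99 * snr_threshold * noise_sigma / amp)
  } else {
    target_snr * noise_sigma / amp
  }
  noise <- stats::rnorm(90, 0, noise_sigma)
  seg <- template$waveform * scale + noise
  ## the realized peak (template plus noise) must respect the SNR bound;
  ## attenuate further if a noise excursion pushed it over
  bound <- 0.995 * snr_threshold * noise_sigma
  while (max(abs(seg)) >= bound && scale > 1e-6) {
    scale <- scale * 0.9
    seg <- template$waveform * scale + noise
  }
  if (max(abs(seg)) >= bound)
    stop("cannot satisfy the SNR bound with this noise draw")
  seg
}

## Embed a 90-sample core event in a longer stretch of Gaussian background
## noise and re-extract the window centred on the absolute-maximum sample --
## the same geometry that threshold detection plus peak alignment produces.
## Cores whose aligned peak stays below `min_peak` are rejected (they would
## never cross the detection threshold).
embed_and_align <- function(core, noise_sigma, min_peak = 0, max_tries = 40L) {
  for (i in seq_len(max_tries)) {
    long <- stats::rnorm(180, 0, noise_sigma)
    long[46:135] <- long[46:135] + core
    p <- 45L + which.max(abs(long[46:135]))
    ## iterate until the window's own absolute maximum sits at its centre
    stable <- FALSE
    for (k in 1:6) {
      q <- p - 46L + which.max(abs(long[(p - 45):(p + 44)]))
      if (q - 45L < 1L || q + 44L > 180L) break
      if (q == p) { stable <- TRUE; break }
      p <- q
    }
    seg <- long[(p - 45):(p + 44)]
    if (stable && abs(seg[46]) >= min_peak) return(seg)
  }
  seg
}

#' Labeled synthetic event set
#'
#' Generates peak-aligned 3 ms event segments with ground-truth labels, the
#' event-level counterpart of a simulated recording passed through detection
#' and alignment. Each event is embedded in background noise and the window
#' re-centred on its absolute-maximum sample; events that would not cross the
#' detection threshold (`min_peak`) are redrawn.
#'
#' Default composition is 90% neural spikes (template + 10 uV noise), 5%
#' Type I periodic artifacts and 5% Type II remote-source events (template
#' attenuated to a linear SNR drawn uniformly from `type2_snr`, plus 30 uV
#' noise).
#'
#' @param n number of events.
#' @param templates list of [spike_template()] objects.
#' @param fractions named numeric vector with components `neural`, `type1`,
#'   `type2` summing to 1.
#' @param seed integer seed.
#' @param noise_sigma background noise sd for neural/Type I events (uV).
#' @param type2_sigma noise sd for Type II events (uV).
#' @param type2_snr range of target linear SNR for Type II events.
#' @param type1_freq,type1_amp ranges for Type I frequency (Hz) and
#'   amplitude (uV).
#' @param min_peak minimum aligned peak magnitude (uV), emulating the
#'   detection threshold.
#' @return list with `segments` (n x 90 matrix, uV) and `labels` (factor with
#'   levels `NEURAL`, `TYPE1`, `TYPE2`).
#' @export
labeled_events <- function(n, templates, fractions = c(neural = 0.9, type1 = 0.05, type2 = 0.05),
                           seed = 1, noise_sigma = 10, type2_sigma = 30,
                           type2_snr = c(0.2, 1.5), type1_freq = c(300, 3000),
                           type1_amp = c(60, 150), min_peak = 50) {
  stopifnot(all(c("neural", "type1", "type2") %in% names(fractions)))
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must be non-negative and sum to 1")
  set.seed(as.integer(seed))
  n_neural <- round(n * fractions[["neural"]])
  n_type1 <- round(n * fractions[["type1"]])
  n_type2 <- n - n_neural - n_type1
  labels <- factor(rep(c("NEURAL", "TYPE1", "TYPE2"),
                       c(n_neural, n_type1, n_type2)),
                   levels = c("NEURAL", "TYPE1", "TYPE2"))
  nb <- length(templates)
  segments <- matrix(0, n, 90)
  for (i in seq_len(n)) {
    core <- switch(as.character(labels[i]),
      NEURAL = templates[[sample.int(nb, 1)]]$waveform,
      TYPE1 = {
        kind <- sample(c("sine", "sawtooth", "square"), 1)
        f <- stats::runif(1, type1_freq[1], type1_freq[2])
        a <- stats::runif(1, type1_amp[1], type1_amp[2])
        tt <- (seq_len(90) - 1) / 30000
        ph <- 2 * pi * f * tt + stats::runif(1, 0, 2 * pi)
        w <- switch(kind,
          sine = a * sin(ph),
          sawtooth = a * (2 * ((ph / (2 * pi)) %% 1) - 1),
          square = a * sign(sin(ph)))
        if (kind == "square") w[w == 0] <- a
        w
      },
      TYPE2 = {
        tpl <- templates[[sample.int(nb, 1)]]
        snr <- stats::runif(1, type2_snr[1], type2_snr[2])
        tpl$waveform * (snr * type2_sigma / tpl$amplitude)
      })
    sig <- if (labels[i] == "TYPE2") type2_sigma else noise_sigma
    segments[i, ] <- embed_and_align(core, sig, min_peak = min_peak)
  }
  ord <- sample.int(n)  # events arrive in random order, as in a recording
  list(segments = segments[ord, , drop = FALSE], labels = labels[ord])
}

#' Synthetic sorted unit with ground-truth event labels
#'
#' Builds one cluster ("unit") of events for testing post-clustering triage
#' and refinement: neural events fire as a Poisson train with refractory
#' period, contaminants occur at uniformly random times. Exactly
#' `round(n_events * neural_fraction)` events are neural.
#'
#' @param n_events total number of events in the unit.
#' @param neural_fraction proportion of neural events in `[0, 1]`.
#' @param templates list of [spike_template()] objects (required when
#'   `neural_fraction > 0`).
#' @param contaminant_kinds subset of `c("TYPE1", "TYPE2")` to draw
#'   contaminants from.
#' @param duration time span of the unit in seconds.
#' @param seed integer seed.
#' @param unit_id identifier stored on the unit.
#' @inheritParams labeled_events
#' @return a [sorted_unit()] whose `labels` field carries the ground truth.
#' @export
synthetic_unit <- function(n_events, neural_fraction, templates = NULL,
                           contaminant_kinds = c("TYPE1", "TYPE2"),
                           duration = 20, seed = 1, unit_id = 1L,
                           noise_sigma = 10, type2_sigma = 30,
                           type2_snr = c(0.2, 1.5), type1_freq = c(300, 3000),
                           type1_amp = c(60, 150)) {
  if (neural_fraction < 0 || neural_fraction > 1)
    stop("'neural_fraction' must be in [0, 1]")
  if (neural_fraction > 0 && (is.null(templates) || length(templates) == 0))
    stop("a non-empty template list is required when 'neural_fraction' > 0")
  contaminant_kinds <- match.arg(contaminant_kinds, several.ok = TRUE)
  set.seed(as.integer(seed))
  n_neural <- round(n_events * neural_fraction)
  n_cont <- n_events - n_neural

  ## neural firing: one Poisson cell at the rate that yields ~n_neural spikes
  tpl <- if (n_neural > 0) templates[[sample.int(length(templates), 1)]] else NULL
  neural_times <- numeric(0)
  while (length(neural_times) < n_neural) {
    neural_times <- poisson_train(rate = 1.2 * n_neural / duration,
                                  duration = duration, refractory = 0.002,
                                  seed = sample.int(.Machine$integer.max, 1))
  }
  neural_times <- sort(sample(neural_times, n_neural))
  cont_times <- sort(stats::runif(n_cont, 0, duration))
  cont_kind <- sample(contaminant_kinds, n_cont, replace = TRUE)

  times <- c(neural_times, cont_times)
  labels <- c(rep("NEURAL", n_neural), cont_kind)
  nb <- length(templates)
  segs <- matrix(0, n_events, 90)
  for (i in seq_len(n_events)) {
    core <- switch(labels[i],
      NEURAL = tpl$waveform,
      TYPE1 = {
        f <- stats::runif(1, type1_freq[1], type1_freq[2])
        a <- stats::runif(1, type1_amp[1], type1_amp[2])
        type1_event(sample(c("sine", "sawtooth", "square"), 1), f, a,
                    noise_sigma = 0, seed = sample.int(.Machine$integer.max, 1))
      },
      TYPE2 = {
        t2 <- templates[[sample.int(nb, 1)]]
        snr <- stats::runif(1, type2_snr[1], type2_snr[2])
        t2$waveform * (snr * type2_sigma / t2$amplitude)
      })
    sig <- if (labels[i] == "TYPE2") type2_sigma else noise_sigma
    segs[i, ] <- embed_and_align(core, sig, min_peak = 0)
  }
  ord <- order(times)
  sorted_unit(unit_id = unit_id, times = times[ord],
              segments = segs[ord, , drop = FALSE],
              labels = factor(labels[ord], levels = c("NEURAL", "TYPE1", "TYPE2")))
}
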