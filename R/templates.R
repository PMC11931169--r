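#' Parametric tri-phasic spike template
#'
#' Builds a 3 ms (90 samples at 30 kHz) extracellular spike waveform from a
#' sum of Gaussian lobes: a modest positive deflection, a pronounced negative
#' peak, and a slow positive repolarization hump. The negative peak is placed
#' exactly at sample 46 (the window centre) and scaled to `-amplitude`; a
#' Tukey taper forces the endpoints towards zero so the template fits cleanly
#' inside its window.
#'
#' @param template_id integer identity of the template; together with `seed`
#'   it determines the randomized lobe geometry.
#' @param amplitude peak magnitude in microvolts (must be > 0).
#' @param width approximate full width at half maximum of the negative phase,
#'   in milliseconds (0.2 to 1.5).
#' @param seed integer seed; a fixed (template_id, amplitude, width, seed)
#'   quadruple always yields the identical waveform.
#' @return An object of class `spike_template`: a list with `waveform`
#'   (90 numeric samples, microvolts), `peak_index` (46), `amplitude` and
#'   `template_id`.
#' @examples
#' tpl <- spike_template(1, amplitude = 120, width = 0.5, seed = 1)
#' which.min(tpl$waveform)  # 46
#' @export
spike_template <- function(template_id, amplitude, width = 0.6, seed = 1) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude <= 0)
    stop("'amplitude' must be a single positive number (microvolts)")
  if (!is.numeric(width) || width < 0.2 || width > 1.5)
    stop("'width' must be between 0.2 and 1.5 ms")
  set.seed(as.integer(seed) * 10000L + as.integer(template_id))

  gauss <- function(t, mu, s) exp(-((t - mu)^2) / (2 * s^2))
  ## build on a wider grid, then cut the 90-sample window around the trough
  tw <- (seq_len(150) - 76) / 30  # ms relative to provisional centre
  s_neg <- width / 2.355          # FWHM -> sd
  ## randomized lobe geometry: pre-peak and repolarization amplitudes,
  ## offsets and widths, plus an asymmetric negative phase (fast
  ## depolarization, slower return), so banks are diverse in shape and not
  ## just in amplitude
  r_pre <- stats::runif(1, 0.10, 0.60)
  r_rep <- stats::runif(1, 0.05, 0.40)
  d_pre <- stats::runif(1, 0.25, 0.65)
  d_rep <- stats::runif(1, 0.35, 0.85)
  s_pre <- s_neg * stats::runif(1, 0.6, 1.4)
  s_rep <- s_neg * stats::runif(1, 1.2, 2.2)
  skew <- stats::runif(1, 0.7, 1.5)
  neg <- ifelse(tw < 0, gauss(tw, 0, s_neg), gauss(tw, 0, s_neg * skew))
  w <- -neg +
    r_pre * gauss(tw, -d_pre, s_pre) +
    r_rep * gauss(tw, d_rep, s_rep)
  p <- which.min(w)
  w <- w[(p - 45):(p + 44)]
  w <- w * tukey_window(90, 0.35)
  w <- w / abs(min(w)) * amplitude
  stopifnot(which.min(w) == 46L)

  structure(
    list(waveform = w, peak_index = 46L, amplitude = amplitude,
         template_id = as.integer(template_id)),
    class = "spike_template")
}

## Tukey (tapered cosine) window; flat in the middle, cosine ramps of total
## fraction `alpha` at the edges.
tukey_window <- function(n, alpha) {
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / alpha + 1)))
  w
}

#' Bank of diverse spike templates
#'
#' Draws `n` templates with amplitudes and widths sampled uniformly from the
#' given ranges. The default amplitude range keeps every template's linear
#' SNR at or above 10 against the 10 uV training noise floor, so that spikes
#' inserted into a simulated recording qualify as neural events.
#'
#' @param n number of templates.
#' @param amplitude_range range of peak magnitudes (microvolts).
#' @param width_range range of negative-phase widths (ms).
#' @param seed integer seed.
#' @return list of [spike_template()] objects.
#' @export
template_bank <- function(n = 20, amplitude_range = c(110, 250),
                          width_range = c(0.2, 0.75), seed = 1) {
  set.seed(as.integer(seed))
  amps <- stats::runif(n, amplitude_range[1], amplitude_range[2])
  ## widths are stratified over the range (with jitter) so every bank spans
  ## narrow and broad spikes; diversity then never hinges on a lucky draw
  step <- diff(width_range) / n
  wids <- sample(seq(width_range[1] + step / 2, width_range[2] - step / 2,
                     length.out = n) +
                 stats::runif(n, -step / 2, step / 2))
  lapply(seq_len(n), function(i)
    spike_template(i, amplitude = amps[i], width = wids[i], seed = seed))
}

#' @export
print.spike_template <- function(x, ...) {
  cat(sprintf("spike_template #%d: amplitude %.1f uV, trough at sample %d/90\n",
              x$template_id, x$amplitude, x$peak_index))
  invisible(x)
}
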