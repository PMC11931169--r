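---
title: "Autoencoder-based curation of spike sorting: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoencoder-based curation of spike sorting: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aecurate)
```

## The curation problem

Spike sorting decomposes an extracellular voltage recording into the firing
times of individual neurons. Detection and clustering are automated, but the
final step — deciding which detected events and which clustered units are
actually neural — is traditionally done by a human looking at waveforms.
`aecurate` automates that step. Events fall into three classes:

* **neural spikes** — tri-phasic waveforms (a modest positive deflection, a
  pronounced negative peak, a slow repolarization) with a linear
  signal-to-noise ratio (peak magnitude over background noise SD) of at
  least 10;
* **Type I non-neural events** — artifacts of non-biological origin
  (interference, movement, stimulation), modeled as periodic waveforms;
* **Type II non-neural events** — spike-shaped events from remote sources,
  too noise-corrupted to attribute to a nearby neuron (SNR below 10).

## The reconstruction score

Every detected event is a peak-aligned 3 ms segment: 90 samples at 30 kHz,
with the absolute-maximum sample at index 46. A fully connected autoencoder
with a single 8-dimensional bottleneck (90–8–90) is trained to reconstruct
segments of *neural spikes only*. An event \(x\) is scored by the mean
squared logarithmic error of its reconstruction \(\hat x\):

\[
S(\hat x, x) = \frac{1}{N}\sum_{i=1}^{N}
  \bigl(\log(|\hat x[i]|+1) - \log(|x[i]|+1)\bigr)^2 , \qquad N = 90 .
\]

The absolute value and the added one keep the logarithm defined for signed
microvolt samples; the log transform makes the score robust to amplitude
fluctuations, which vary with electrode placement and gain. Events with
\(S \le 1.5\) are kept as spikes; strict exceedance marks an event
non-neural. The threshold of 1.5 is calibrated for segments whose
background noise floor is 10 µV — the training regime — which is why the
preprocessing calibrates recordings to that floor (below).

## Model internals and why they are shaped this way

The encoder reads the *raw signed* segment (divided by a fixed 100 µV
scale) through a tanh bottleneck; the linear decoder predicts the
log-magnitude profile \(\log(|x|+1)\), and the reconstruction magnitude is
`expm1` of that prediction (clamped at zero) carrying the input's signs.
Training minimizes exactly the MSLE above.

Two design points matter:

* **The encoder must read signed raw samples.** A linear projection of
  signed samples is insensitive to the *level* of zero-mean noise: noise
  only jitters the code. If instead the encoder read log-magnitudes, the
  code could track an elevated noise floor and the decoder would happily
  reconstruct it — precisely the anomaly (a Type II event's 30 µV floor)
  the score must expose. We verified this failure mode directly before
  settling on the raw-signed encoder.
* **The decoder predicts log-magnitudes.** The MSLE-optimal reconstruction
  of the quiet parts of a spike segment is the *typical* log noise floor,
  not zero. Predicting in the log domain lets the output bias learn that
  floor in a handful of epochs; training starts from an output-bias warm
  start at the training set's mean log-magnitude profile, so 20 epochs of
  Adam (learning rate 1e-3, batch 64, Glorot-uniform initialization, fixed
  seed) converge — the convergence flag requires the last three epoch-level
  validation-loss changes to be below 1% of the loss.

Anomaly separation then has two sources: Type I events present large
log-levels and shapes far off the spike manifold (large errors across the
window); Type II events present an elevated noise floor that the code
cannot transmit, leaving a per-sample error of roughly
\((\Delta\text{floor})^2 + \mathrm{Var}\), concentrated in the segment
tails. Because the aligned centre of any event agrees with the
reconstruction's central trough, Type II scores sit closer to the
threshold than Type I scores; they are the hard class, and the score
distributions (checked by the test suite) reflect that.

The paper-facing choice between MSLE and plain MSE as the *training*
objective is resolved in favour of MSLE: the score and the objective then
coincide, and an MSE-trained raw-space model reconstructs near-zero tails,
which inflates the MSLE of perfectly good spikes.

## Preprocessing

The detection front end runs in a fixed order:

1. **Bandpass** 300–6000 Hz, 3rd-order Butterworth, applied forward and
   backward (zero phase). The corners are conventional for the spike band
   and configurable.
2. **Common median reference**: the per-sample median across channels is
   subtracted, cancelling interference shared by the array. The order
   matters: a strong common-mode hum inflates per-channel noise estimates
   enough to hide real spikes from the detector (regression-tested).
3. **Noise-floor calibration**: one global gain brings the robust noise
   estimate — median(|x|)/0.6745, insensitive to sparse spikes — to the
   training floor of 10 µV. "Normalization" is interpreted as this global
   calibration, *not* per-event amplitude normalization: the log transform
   already grants per-event amplitude robustness, and a fixed threshold of
   1.5 only transfers between recordings whose floors are commensurate.
4. **Detection**: negative threshold crossings at 5 robust SDs, one event
   per excursion at its local minimum, 1 ms dead time per channel; when
   several channels cross within the dead time the largest absolute peak
   wins.
5. **Extraction**: the 90-sample window is re-centred so the
   absolute-maximum sample sits at index 46, ties broken towards the
   earliest sample (alignment on the absolute maximum also covers
   positive-going artifacts). Other sampling rates are resampled to
   30 kHz first.

## Curation policies

* **Pre-clustering filter**: events scoring above the threshold are
  excluded before clustering; kept and removed events always partition the
  input, and the removal log is returned.
* **Post-clustering triage**: a unit's *neural fraction* is the proportion
  of its events scoring at or below the threshold. Units with fraction
  ≥ 0.95 are neural (kept intact), in [0.50, 0.95) hybrid (refined event
  by event), below 0.50 non-neural (discarded, but retained in the report
  for audit). Both boundaries are inclusive on the side written here; the
  cut points are configurable.
* **Refinement** removes exactly the events above the threshold and keeps
  time order.

Lowering the threshold never increases the number of kept events
(monotone filters), and sweeping it downward on a contaminated sorting
produces a non-decreasing sensitivity curve until spike loss dominates.

## Quality metrics

* **Matching**: a sorted event matches a ground-truth spike when their
  times differ by at most 1 ms; matching is greedy, in time order,
  one-to-one, with ties going to the earlier ground-truth event (greedy
  equals the optimal assignment on in-tolerance instances; tested against
  an exact dynamic program). For each ground-truth unit only the sorted
  unit with the highest matched fraction counts.
* **Sensitivity** of that best unit is
  \(n_\text{neural}/(n_\text{neural}+n_\text{non-neural})\).
* **ISI violations**: intervals shorter than 1.5 ms. The default
  *pairwise* rate counts every ordered pair closer than the window and
  divides by the number of events, so crowded units can exceed 100%; the
  *consecutive* variant (adjacent intervals over \(n-1\)) is available.
  Units with a rate strictly below 5% are accepted.
* **Silhouette**: \(S_i = (b_i - a_i)/\max(a_i, b_i)\) with Euclidean
  distance on the raw 90-sample segments (the feature space is not dictated
  by the method; raw segments are the least-committed choice), computed via
  `cluster::silhouette` and verified against an all-pairs brute force.

## The synthetic data generator

Everything is testable without downloads because the package generates its
own labeled data:

* **Templates**: parametric tri-phasic waveforms — an asymmetric negative
  Gaussian lobe (fast fall, slower rise) plus randomized positive pre-peak
  and repolarization lobes, Tukey-tapered to vanish at the window edges.
  Bank widths are stratified over 0.2–0.75 ms so every bank spans narrow
  and broad spikes; amplitudes are uniform on 110–250 µV, which keeps every
  neural template at SNR ≥ 10 against the 10 µV floor. Pairwise waveform
  correlation across a 20-template bank stays below 0.9 on average.
* **Firing**: homogeneous Poisson trains thinned by a 2 ms absolute
  refractory period.
* **Type I events**: sine, sawtooth or square waves, frequencies uniform
  on 0.3–3 kHz (a declared configuration choice, not a literature value),
  amplitudes uniform on 60–150 µV. The amplitude floor follows from
  detectability: a 5σ detector at a 10 µV floor cannot fire on artifacts
  much below 50 µV, so detected artifacts are at least that large.
* **Type II events**: a template attenuated to a target linear SNR drawn
  uniformly from 0.2–1.5 against 30 µV Gaussian noise. Remote neurons
  produce µV-scale deflections at the electrode; an event that is
  "spike-shaped but from a remote source" is dominated by its elevated
  noise floor, which is what the generator emulates. The single-event
  constructor `type2_event()` is more conservative — it preserves the
  template amplitude and attenuates only as needed to respect the SNR
  bound — the deep attenuation is the labeled-set default.
* **Pipeline-consistent segments**: each event is embedded in a longer
  noise trace and the 90-sample window re-centred on its absolute maximum,
  with sub-threshold draws rejected — the same geometry detection and
  alignment produce.
* **Composition**: labeled evaluation sets default to 90% neural, 5%
  Type I, 5% Type II. Threshold detection on a lightly contaminated
  ground-truth recording yields predominantly true spikes; the contaminant
  classes are deliberately injected minorities.
* **Recordings**: white Gaussian background at 10 µV SD per channel,
  templates inserted peak-aligned at Poisson times, contaminants injected
  at random times (Type II with a local 30 µV noise burst). Ground-truth
  labels are kept consistent with the SNR rule by small amplitude
  adjustments at insertion time when a noise draw would otherwise cross
  the boundary.

The evaluation template bank is always drawn with a different seed than the
training bank, so accuracy is measured on waveforms the model has not seen.

What the generator does **not** emulate: probe geometry and across-channel
amplitude decay, electrode drift, bursting or other non-Poisson firing,
overlap resolution (overlapping spikes are labeled by each contributor),
and colored or spatially correlated background noise. Passing tests
therefore demonstrate the method's behaviour under idealized, stationary,
single-channel-event conditions — not performance on real recordings. One
visible consequence of the white-noise idealization: after band-limiting
and re-calibration, residual in-band noise fluctuations occasionally cross
the 5σ detection threshold, so detection on synthetic recordings shows
extra near-threshold events; detection recall (the spec-level property) is
unaffected.

## SNR threshold reading

The class boundary is a *linear* peak-over-sigma ratio of 10 by default. A
deciBel reading ("10 dB", i.e. a linear ratio of about 3.16) is exposed via
`snr_db = TRUE` in `sim_config()`; the two readings differ by a factor of
~3 and the linear reading is the one consistent with the event taxonomy
used throughout.

## Fixture scales and numerical conventions

* Study-scale checks train on 5000 clean spike segments for 20 epochs and
  evaluate 5000 labeled events; headline accuracy averages five
  independent train/evaluate replicates.
* Unit-triage checks use 100 units per composition at 600 events per unit:
  at a neural fraction of 0.40 the observed sub-threshold fraction sits
  near 0.45 (contaminant misclassification pushes it up), so units need
  enough events for the binomial spread not to cross the 0.50 cut. Triage
  fixtures use Type I contaminants so the unit-level boundaries are tested
  without being confounded by the near-threshold scores of deep-noise
  Type II events (an event-level, not unit-level, property).
* Hybrid-refinement checks use 400-event, 10-second units (~13 expected
  pairwise violations), so the refined-vs-random comparison measures the
  effect rather than shot noise.
* All randomness is seeded; identical configurations reproduce
  bit-identical recordings, fits and reports. Degenerate inputs behave
  conservatively: empty units refuse classification, refinement that
  empties a unit warns and returns the empty unit, a single-channel
  recording passes through referencing with a warning, and zero-noise
  normalization is an error.

## Known limitations

* Type II separation rests on the noise-floor gap alone, so scores
  concentrate just above the threshold and a fraction of deep-noise events
  is inevitably kept; overall accuracy is dominated by the neural and
  Type I classes.
* The 1.5 threshold transfers only to recordings calibrated to the 10 µV
  training floor; recalibrate or retrain otherwise.
* The model consumes single-channel segments; multi-channel waveform
  context is not used.
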