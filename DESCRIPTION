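Package: aecurate
Title: Autoencoder-Based Curation of Extracellular Spike Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automatic curation of extracellular spike-sorting output using a
    90-8-90 fully connected autoencoder trained on simulated neural spike
    waveforms. Detected events are scored by the mean squared logarithmic
    error (MSLE) between a 3 ms peak-aligned segment and its reconstruction;
    high-error events are flagged as non-neural. Curation is supported both
    before clustering (event filtering) and after clustering (unit triage into
    neural, hybrid and non-neural units, plus event-level refinement of hybrid
    units). Includes a labeled synthetic-data generator (parametric tri-phasic
    spike templates, Poisson spike trains, periodic artifacts and low-SNR
    events), a detection/segmentation front end, and quality metrics:
    ground-truth event matching, sorting sensitivity, ISI-violation rates and
    silhouette scores.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
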