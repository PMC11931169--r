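#' Run the full simulate-detect-train-score-curate-evaluate pipeline
#'
#' Executes the configured stages end to end and writes every artifact into
#' `out_dir`: the simulated recording (binary + sidecar + ground-truth CSV),
#' detected events, the trained model, per-event scores and decisions, the
#' curated sorting with its report, evaluation metrics, and the resolved
#' configuration with all derived stage seeds — enough to regenerate the
#' directory bit for bit.
#'
#' The single `seed` fans out deterministically to the stages
#' (`seed + 1000 k` for stage `k`) so each stage is independently
#' reproducible.
#'
#' @param config list of parameters; see [pipeline_config()] for defaults.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory artifacts
#'   (`recording`, `model`, `events`, `scores`, `curated`, `metrics`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(pipeline_config(), config)
  seeds <- list(sim = cfg$seed + 1000L, train = cfg$seed + 2000L,
                train_data = cfg$seed + 3000L)
  cfg$stage_seeds <- seeds
  write_config(cfg, file.path(out_dir, "config.yaml"))

  ## stage 1: simulate
  sc <- sim_config(n_channels = cfg$n_channels, duration = cfg$duration,
                   noise_sigma = cfg$noise_sigma, firing_rate = cfg$firing_rate,
                   n_cells = cfg$n_cells, type1_rate = cfg$type1_rate,
                   type2_rate = cfg$type2_rate, seed = seeds$sim)
  rec <- simulate_recording(sc)
  write_recording(rec, file.path(out_dir, "recording"))

  ## stage 2: preprocess + detect
  pp <- preprocess_recording(rec, low = cfg$band[1], high = cfg$band[2],
                             target_sigma = cfg$target_sigma,
                             k_sigma = cfg$k_sigma,
                             dead_time_ms = cfg$dead_time_ms)
  ev <- pp$events
  ev$event_id <- seq_len(nrow(ev))
  utils::write.csv(ev[c("event_id", "time_s", "channel", "peak_uV")],
                   file.path(out_dir, "events.csv"), row.names = FALSE)

  ## stage 3: train on spikes from a disjoint simulated recording, passed
  ## through the identical preprocessing so training and scoring see the
  ## same waveform statistics (filter shape, referencing, calibration)
  train_segs <- pipeline_training_spikes(cfg, seeds$train_data)
  n_val <- max(1L, nrow(train_segs) %/% 5)
  val_idx <- seq_len(n_val)
  model <- spike_autoencoder(train_segs[-val_idx, , drop = FALSE],
                             validation = train_segs[val_idx, , drop = FALSE],
                             epochs = cfg$epochs, threshold = cfg$threshold,
                             target_sigma = cfg$target_sigma,
                             seed = seeds$train)
  write_model(model, file.path(out_dir, "model.json"))

  ## stage 4: score detected events
  scores <- predict(model, pp$segments)
  decisions <- classify_events(scores, cfg$threshold)
  utils::write.csv(data.frame(event_id = ev$event_id, msle = scores,
                              decision = as.character(decisions)),
                   file.path(out_dir, "scores.csv"), row.names = FALSE)

  ## stage 5: curate — group detected events into units by true source when
  ## ground truth is available (no clustering of its own), else one unit per
  ## channel
  units <- events_to_units(rec, ev, pp$segments, tol = cfg$match_tol)
  curated <- curate_sorting(units, model, threshold = cfg$threshold)
  write_sorting(curated$units, file.path(out_dir, "curated_sorting.csv"))
  utils::write.csv(as.data.frame(curated$report),
                   file.path(out_dir, "curation_report.csv"), row.names = FALSE)

  ## stage 6: evaluate against ground truth
  metrics <- NULL
  if (inherits(rec, "labeled_recording")) {
    rep_before <- match_events(rec$true_units, units, tol = cfg$match_tol)
    rep_after <- match_events(rec$true_units, curated$units, tol = cfg$match_tol)
    metrics <- list(
      n_detected = nrow(ev),
      n_true_events = nrow(rec$true_events),
      sensitivity_before = mean(sensitivity(rep_before), na.rm = TRUE),
      sensitivity_after = mean(sensitivity(rep_after), na.rm = TRUE),
      isi_violation = vapply(curated$units,
                             function(u) isi_violation_rate(u$times),
                             numeric(1)))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(recording = rec, model = model, events = ev,
                 scores = scores, curated = curated, metrics = metrics))
}

#' Default pipeline configuration
#'
#' @return named list of every pipeline parameter with its default.
#' @export
pipeline_config <- function() {
  list(n_channels = 4, duration = 30, noise_sigma = 10, firing_rate = 5,
       n_cells = 8, type1_rate = 0.2, type2_rate = 0.2,
       band = c(300, 6000), target_sigma = 10, k_sigma = 5,
       dead_time_ms = 1, n_train = 2000, epochs = 20, threshold = 1.5,
       match_tol = 1e-3, seed = 0L)
}

## simulate a clean training recording (no contaminants), preprocess it the
## standard way, and keep the detected segments that match true neural spike
## times -- the pipeline's source of "clean spikes" for training
pipeline_training_spikes <- function(cfg, seed) {
  duration <- min(60, max(10, ceiling(cfg$n_train /
                                      max(1, cfg$n_cells * cfg$firing_rate))))
  sc <- sim_config(n_channels = cfg$n_channels, duration = duration,
                   noise_sigma = cfg$noise_sigma,
                   firing_rate = cfg$firing_rate, n_cells = cfg$n_cells,
                   type1_rate = 0, type2_rate = 0, seed = seed)
  rec <- simulate_recording(sc)
  pp <- preprocess_recording(rec, low = cfg$band[1], high = cfg$band[2],
                             target_sigma = cfg$target_sigma,
                             k_sigma = cfg$k_sigma,
                             dead_time_ms = cfg$dead_time_ms)
  gt <- rec$true_events$time_s[rec$true_events$kind == "NEURAL"]
  is_spike <- vapply(pp$events$time_s,
                     function(t) any(abs(gt - t) <= 5e-4), logical(1))
  segs <- pp$segments[is_spike, , drop = FALSE]
  if (nrow(segs) < 50)
    stop("training recording yielded too few spike segments")
  segs[seq_len(min(nrow(segs), cfg$n_train)), , drop = FALSE]
}

## group detected events into sorted units by nearest ground-truth source
## (within tol); unmatched events fall into per-channel "noise" units
events_to_units <- function(rec, events, segments, tol = 1e-3) {
  n <- nrow(events)
  assign <- rep(NA_integer_, n)
  if (inherits(rec, "labeled_recording")) {
    for (uid in names(rec$true_units)) {
      ut <- rec$true_units[[uid]]
      if (!length(ut)) next
      near <- vapply(events$time_s, function(t) min(abs(ut - t)), numeric(1))
      hit <- which(is.na(assign) & near <= tol)
      assign[hit] <- as.integer(uid)
    }
  }
  max_id <- max(c(0L, assign), na.rm = TRUE)
  assign[is.na(assign)] <- max_id + events$channel[is.na(assign)]
  out <- list()
  for (uid in sort(unique(assign))) {
    sel <- which(assign == uid)
    sel <- sel[order(events$time_s[sel])]
    out[[length(out) + 1L]] <- sorted_unit(
      uid, events$time_s[sel], segments = segments[sel, , drop = FALSE],
      channel = events$channel[sel])
  }
  out
}
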