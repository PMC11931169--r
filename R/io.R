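#' Write a recording as flat binary plus JSON sidecar
#'
#' Samples are stored channel-major (all samples of channel 1, then channel
#' 2, ...) as little-endian float32; the sidecar records sampling rate,
#' channel count, dtype and units. Ground truth, when present, is written as
#' a CSV (`time_s, channel, kind, unit_id`) next to the binary.
#'
#' @param rec a [recording()] (possibly a `labeled_recording`).
#' @param prefix path prefix; writes `<prefix>.bin`, `<prefix>.json` and,
#'   for labeled recordings, `<prefix>_ground_truth.csv`.
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "recording"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  meta <- list(sampling_rate_hz = rec$sampling_rate,
               n_channels = nrow(rec$samples),
               n_samples = ncol(rec$samples),
               dtype = "float32", units = "uV", order = "channel-major")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  if (inherits(rec, "labeled_recording"))
    utils::write.csv(rec$true_events, paste0(prefix, "_ground_truth.csv"),
                     row.names = FALSE)
  invisible(prefix)
}

#' Read a flat-binary recording
#'
#' @param prefix path prefix as used by [write_recording()].
#' @return a [recording()].
#' @export
read_recording <- function(prefix) {
  bin <- paste0(prefix, ".bin")
  sidecar <- paste0(prefix, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar file: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz) || meta$sampling_rate_hz <= 0)
    stop("sidecar ", sidecar, ": sampling_rate_hz must be > 0")
  if (!identical(meta$dtype, "float32"))
    stop("sidecar ", sidecar, ": unsupported dtype '", meta$dtype, "'")
  expected <- meta$n_channels * meta$n_samples
  actual <- file.info(bin)$size / 4
  if (is.na(actual) || actual != expected)
    stop(sprintf("binary %s: expected %d float32 values (%d bytes), found %s bytes",
                 bin, expected, expected * 4,
                 ifelse(is.na(actual), "no", as.character(actual * 4))))
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = expected, size = 4, endian = "little")
  recording(matrix(vals, nrow = meta$n_channels, byrow = TRUE),
            meta$sampling_rate_hz)
}

#' Read / write sorting interchange CSV
#'
#' The interchange schema is `unit_id, time_s, channel`, compatible with
#' common sorter exports. Times are seconds; within each unit they must be
#' sorted (reading sorts them and warns on duplicates, which are kept).
#'
#' @param path CSV file path.
#' @return `read_sorting`: list of [sorted_unit()] objects (no segments).
#' @export
read_sorting <- function(path) {
  df <- utils::read.csv(path)
  need <- c("unit_id", "time_s", "channel")
  if (!all(need %in% names(df)))
    stop("sorting CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) return(list())
  if (anyDuplicated(df[c("unit_id", "time_s")]))
    warning("duplicate (unit_id, time_s) rows found; keeping all")
  lapply(split(df, df$unit_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    sorted_unit(d$unit_id[1], d$time_s, channel = d$channel)
  })
}

#' @rdname read_sorting
#' @param units list of [sorted_unit()] objects.
#' @export
write_sorting <- function(units, path) {
  rows <- lapply(units, function(u) data.frame(
    unit_id = rep(u$unit_id, length(u$times)), time_s = u$times,
    channel = if (length(u$channel) == length(u$times)) u$channel
              else rep(u$channel[1], length(u$times))))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = integer(0), time_s = numeric(0), channel = integer(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted autoencoder
#'
#' Single-file JSON container holding the four weight arrays plus the
#' metadata needed for threshold transfer (input/code dimensions, input
#' scale, training seed, target noise floor and decision threshold).
#'
#' @param model a [spike_autoencoder()].
#' @param path file path (`.json`).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "spike_autoencoder"))
  payload <- list(
    enc_w = model$enc_w, enc_b = model$enc_b,
    dec_w = model$dec_w, dec_b = model$dec_b,
    attrs = list(input_dim = model$input_dim, code_dim = model$code_dim,
                 input_scale = model$input_scale, train_seed = model$seed,
                 target_sigma_uv = model$target_sigma,
                 threshold = model$threshold, epochs = model$epochs,
                 loss = model$loss, val_loss = model$val_loss,
                 converged = model$converged, n_train = model$n_train))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- p$attrs
  as_mat <- function(m, nr, nc)
    if (is.matrix(m)) m else matrix(unlist(m), nr, nc, byrow = TRUE)
  structure(
    list(enc_w = as_mat(p$enc_w, a$input_dim, a$code_dim),
         enc_b = as.numeric(p$enc_b),
         dec_w = as_mat(p$dec_w, a$code_dim, a$input_dim),
         dec_b = as.numeric(p$dec_b),
         input_dim = a$input_dim, code_dim = a$code_dim,
         loss = as.numeric(a$loss), val_loss = as.numeric(a$val_loss),
         converged = isTRUE(a$converged), epochs = a$epochs,
         batch_size = NA_integer_, learning_rate = NA_real_,
         input_scale = a$input_scale, threshold = a$threshold,
         target_sigma = a$target_sigma_uv, seed = a$train_seed,
         n_train = a$n_train),
    class = "spike_autoencoder")
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the resolved parameter list; every pipeline run writes
#' its resolved configuration next to its outputs.
#'
#' @param config named list of parameters.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
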