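#' Read / write the spike CSV format
#'
#' Columns `electrode_id, time_s`, times sorted within electrode.
#'
#' @param spikes data.frame `(electrode_id, time_s)`.
#' @param path file path.
#' @return `read_spike_csv` returns the spike data.frame; writers return the
#'   path invisibly.
#' @export
write_spike_csv <- function(spikes, path) {
  stopifnot(all(c("electrode_id", "time_s") %in% names(spikes)))
  spikes <- spikes[order(spikes$electrode_id, spikes$time_s),
                   c("electrode_id", "time_s"), drop = FALSE]
  utils::write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("electrode_id", "time_s") %in% names(df)))
  df <- df[order(df$electrode_id, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read / write the bursts CSV format
#'
#' Columns `electrode_id, t_start_s, t_end_s, n_spikes, duration_ms`.
#'
#' @param bursts a `burst_train` or compatible data.frame.
#' @param path file path.
#' @param params [burst_params()] reattached on read.
#' @return `read_bursts_csv` returns a `burst_train`; the writer returns the
#'   path invisibly.
#' @export
write_bursts_csv <- function(bursts, path) {
  df <- as.data.frame(bursts)
  cols <- c("electrode_id", "t_start_s", "t_end_s", "n_spikes", "duration_ms")
  stopifnot(all(cols %in% names(df)))
  utils::write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bursts_csv
#' @export
read_bursts_csv <- function(path, params = burst_params()) {
  df <- utils::read.csv(path)
  burst_train(df, params)
}

#' Read / write the spine CSV format
#'
#' Columns `cell_id, condition, shape_class, psd95` (`psd95` logical or
#' empty for missing).
#'
#' @param records spine record data.frame.
#' @param path file path.
#' @return `read_spine_csv` returns the record data.frame; the writer returns
#'   the path invisibly.
#' @export
write_spine_csv <- function(records, path) {
  stopifnot(all(c("cell_id", "condition", "shape_class") %in% names(records)))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spine_csv
#' @export
read_spine_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "condition", "shape_class") %in% names(df)))
  if ("psd95" %in% names(df)) df$psd95 <- as.logical(df$psd95)
  df
}

#' Write / read a raw voltage recording
#'
#' Stores the channels x samples voltage matrix as little-endian float64 in
#' `voltage.bin` with a `meta.json` sidecar carrying the sampling rate,
#' dimensions and electrode grid, under one directory.
#'
#' @param rec a `raw_recording`.
#' @param dir directory to create/use.
#' @return `read_recording` returns the `raw_recording`; the writer returns
#'   the directory invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "raw_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sampling_rate_hz = rec$config$sampling_rate_hz,
               n_electrodes = rec$config$n_electrodes,
               duration_s = rec$config$duration_s,
               grid = rec$config$grid,
               n_channels = nrow(rec$voltage),
               n_samples = ncol(rec$voltage),
               dtype = "float64le", layout = "channel-major")
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  con <- file(file.path(dir, "voltage.bin"), "wb")
  on.exit(close(con))
  ## channel-major: each channel's samples contiguous
  writeBin(as.numeric(t(rec$voltage)), con, size = 8, endian = "little")
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(file.path(dir, "voltage.bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 8, endian = "little")
  voltage <- matrix(v, nrow = meta$n_channels, byrow = TRUE)
  cfg <- recording_config(sampling_rate_hz = meta$sampling_rate_hz,
                          n_electrodes = meta$n_electrodes,
                          duration_s = meta$duration_s,
                          grid = meta$grid)
  structure(list(voltage = voltage, config = cfg), class = "raw_recording")
}

#' Write a ground-truth sidecar
#'
#' @param sim an `mea_simulation` (see [generate_spike_trains()]).
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "mea_simulation"))
  jsonlite::write_json(list(condition = sim$params$condition_label,
                            seed = sim$params$seed,
                            bursts = sim$ground_truth),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load simulation conditions from a YAML config
#'
#' The config has one block per condition; each block may set any
#' [sim_params()] argument plus either `burst_duration: {mean_ms, shape}` or
#' a calibration triple `burst_duration: {mean_ms, frac_le_cutoff, cutoff_ms}`,
#' and `spikes_per_burst: {mean, size}`.
#'
#' @param path YAML file.
#' @param duration_s,n_electrodes,seed overrides applied to every condition.
#' @return named list of `sim_params`.
#' @export
read_condition_config <- function(path, duration_s = NULL, n_electrodes = NULL,
                                  seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) stop_param("empty condition config: %s", path)
  out <- lapply(names(cfg), function(label) {
    blk <- cfg[[label]]
    dur <- blk$burst_duration
    burst_duration <- if (!is.null(dur$frac_le_cutoff)) {
      calibrate_burst_duration_dist(dur$mean_ms, dur$frac_le_cutoff, dur$cutoff_ms)
    } else {
      burst_duration_dist(dur$mean_ms, dur$shape)
    }
    spb <- blk$spikes_per_burst
    args <- list(
      condition_label = label,
      burst_duration = burst_duration,
      spikes_per_burst = spikes_per_burst_dist(
        mean = spb$mean, size = if (is.null(spb$size)) 1.5 else spb$size)
    )
    for (nm in c("duration_s", "n_electrodes", "long_ibi_median_s",
                 "long_ibi_log_sd", "motif_prob_doublet", "motif_prob_triplet",
                 "network_jitter_ms", "seed")) {
      if (!is.null(blk[[nm]])) args[[nm]] <- blk[[nm]]
    }
    if (!is.null(blk$motif_gap_ms_range)) {
      args$motif_gap_ms_range <- unlist(blk$motif_gap_ms_range)
    }
    if (!is.null(duration_s)) args$duration_s <- duration_s
    if (!is.null(n_electrodes)) args$n_electrodes <- n_electrodes
    if (!is.null(seed)) args$seed <- seed
    p <- do.call(sim_params, args)
    if (!is.null(blk$div)) attr(p, "div") <- blk$div
    p
  })
  names(out) <- names(cfg)
  out
}
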