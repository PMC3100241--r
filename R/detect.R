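#' Recording configuration
#'
#' Geometry and timing of the MEA recording: by default an 8 x 8 grid of
#' 30 um titanium-nitride electrodes at 200 um pitch, 60 recording channels,
#' sampled at 25 kHz.
#'
#' @param sampling_rate_hz sampling rate, Hz.
#' @param n_electrodes recording channels (must fit on the grid).
#' @param duration_s recording length, seconds.
#' @param grid integer (rows, cols) of the electrode grid.
#' @param electrode_diameter_um,pitch_um electrode geometry, microns.
#' @return object of class `recording_config`.
#' @export
recording_config <- function(sampling_rate_hz = 25000, n_electrodes = 60,
                             duration_s = 600, grid = c(8, 8),
                             electrode_diameter_um = 30, pitch_um = 200) {
  check_pos(sampling_rate_hz, "sampling_rate_hz")
  check_pos(duration_s, "duration_s")
  if (n_electrodes > prod(grid)) {
    stop_param("n_electrodes (%d) exceeds grid capacity (%d)",
               n_electrodes, prod(grid))
  }
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 n_electrodes = as.integer(n_electrodes),
                 duration_s = duration_s, grid = as.integer(grid),
                 electrode_diameter_um = electrode_diameter_um,
                 pitch_um = pitch_um),
            class = "recording_config")
}

#' Spike-detection parameters
#'
#' @param hp_cutoff_hz high-pass cutoff, Hz (default 25).
#' @param threshold_k threshold in multiples of the per-channel noise SD
#'   (default 5).
#' @param dead_time_ms refractory window after a detected spike within which
#'   further crossings are suppressed (default 1 ms).
#' @param polarity `"negative"` (default), `"positive"` or `"both"`.
#' @param filter_order Butterworth order (default 2).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(hp_cutoff_hz = 25, threshold_k = 5,
                             dead_time_ms = 1.0, polarity = "negative",
                             filter_order = 2) {
  check_pos(hp_cutoff_hz, "hp_cutoff_hz")
  check_pos(threshold_k, "threshold_k")
  check_pos(dead_time_ms, "dead_time_ms", strict = FALSE)
  polarity <- match.arg(polarity, c("negative", "positive", "both"))
  structure(list(hp_cutoff_hz = hp_cutoff_hz, threshold_k = threshold_k,
                 dead_time_ms = dead_time_ms, polarity = polarity,
                 filter_order = as.integer(filter_order)),
            class = "detection_params")
}

#' Zero-phase high-pass filter a recording
#'
#' Applies an order-`filter_order` Butterworth high-pass forward and backward
#' (zero phase, so spike timestamps are not shifted) to every channel.
#'
#' @param rec a `raw_recording` (see [synthesize_voltage()] /
#'   [read_recording()]).
#' @param params a [detection_params()].
#' @return the filtered `raw_recording`, same shape.
#' @export
highpass_filter <- function(rec, params = detection_params()) {
  stopifnot(inherits(rec, "raw_recording"))
  nyq <- rec$config$sampling_rate_hz / 2
  if (params$hp_cutoff_hz >= nyq) {
    stop_param("high-pass cutoff (%g Hz) must be below Nyquist (%g Hz)",
               params$hp_cutoff_hz, nyq)
  }
  bf <- signal::butter(params$filter_order, params$hp_cutoff_hz / nyq,
                       type = "high")
  out <- rec
  for (ch in seq_len(nrow(rec$voltage))) {
    out$voltage[ch, ] <- signal::filtfilt(bf, rec$voltage[ch, ])
  }
  out
}

#' Robust per-channel noise SD
#'
#' Estimates the noise standard deviation of a trace as
#' `median(|x - median(x)|) / 0.6745` (the Gaussian-consistent MAD). Unlike
#' the plain SD this is nearly unaffected by the spikes riding on the noise
#' floor, so the threshold tracks the biological noise rather than the
#' activity level.
#'
#' @param trace numeric vector of samples (at least 100).
#' @return estimated SD (microvolts); 0 for a constant trace.
#' @export
estimate_noise_sd <- function(trace) {
  if (length(trace) < 100) stop_param("need >= 100 samples to estimate noise")
  stats::mad(trace)   # constant 1.4826 = 1/0.6745
}

#' Detect spikes on one channel by noise-scaled thresholding
#'
#' Emits a spike where the (already filtered) trace crosses
#' `-threshold_k * noise_sd` (negative polarity; mirrored for positive, either
#' for `"both"`). The timestamp is placed at the extremal sample within the
#' dead-time window after the crossing, and any further crossings inside that
#' window are suppressed.
#'
#' @param trace numeric vector, one channel, microvolts.
#' @param noise_sd per-channel noise SD (> 0), e.g. from
#'   [estimate_noise_sd()].
#' @param params a [detection_params()].
#' @param config a [recording_config()] supplying the sampling rate.
#' @return a `spike_train`: list with `electrode_id` (NA here) and sorted
#'   `times_s`.
#' @export
detect_spikes <- function(trace, noise_sd, params = detection_params(),
                          config = recording_config()) {
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop_param("noise_sd must be > 0 (got %g); channel undetectable", noise_sd)
  }
  thr <- params$threshold_k * noise_sd
  x <- switch(params$polarity,
              negative = -trace,
              positive = trace,
              both = abs(trace))
  fs <- config$sampling_rate_hz
  dead <- max(1L, round(params$dead_time_ms / 1000 * fs))
  over <- x > thr
  ## rising edges of the supra-threshold indicator
  cross <- which(over & !c(FALSE, over[-length(over)]))
  times <- numeric(0)
  i <- 1L
  while (i <= length(cross)) {
    j0 <- cross[i]
    j1 <- min(j0 + dead - 1L, length(x))
    peak <- j0 + which.max(x[j0:j1]) - 1L
    times <- c(times, (peak - 1L) / fs)
    ## suppress crossings within the dead time after the emitted peak,
    ## so emitted timestamps themselves respect the dead-time spacing
    nxt <- peak + dead
    while (i <= length(cross) && cross[i] < nxt) i <- i + 1L
  }
  spike_train(times_s = times, electrode_id = NA_integer_)
}

#' Detect spikes on every channel of a recording
#'
#' High-pass filters the recording once, then per channel estimates the noise
#' SD and runs threshold detection — each channel gets its own threshold
#' since the noise floor varies from electrode to electrode. Channels whose
#' noise estimate is zero (dead/constant) are reported in the
#' `undetectable` attribute and yield empty trains.
#'
#' @param rec a `raw_recording`.
#' @param params a [detection_params()].
#' @return list of `spike_train` (one per channel, possibly empty), with
#'   attribute `undetectable` (integer channel indices).
#' @export
detect_all <- function(rec, params = detection_params()) {
  stopifnot(inherits(rec, "raw_recording"))
  filt <- highpass_filter(rec, params)
  nch <- nrow(filt$voltage)
  trains <- vector("list", nch)
  undet <- integer(0)
  for (ch in seq_len(nch)) {
    sdhat <- estimate_noise_sd(filt$voltage[ch, ])
    if (sdhat <= 0) {
      undet <- c(undet, ch)
      trains[[ch]] <- spike_train(numeric(0), electrode_id = ch)
    } else {
      tr <- detect_spikes(filt$voltage[ch, ], sdhat, params, rec$config)
      tr$electrode_id <- ch
      trains[[ch]] <- tr
    }
  }
  attr(trains, "undetectable") <- undet
  trains
}

#' Spike train container
#'
#' @param times_s sorted spike timestamps, seconds.
#' @param electrode_id electrode index (may be NA for a bare trace).
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times_s, electrode_id = NA_integer_) {
  times_s <- as.numeric(times_s)
  if (is.unsorted(times_s)) stop_param("spike times must be sorted")
  structure(list(electrode_id = electrode_id, times_s = times_s),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train (electrode %s): %d spikes%s\n",
              ifelse(is.na(x$electrode_id), "?", x$electrode_id),
              length(x$times_s),
              if (length(x$times_s)) sprintf(" over [%.3f, %.3f] s",
                                             min(x$times_s), max(x$times_s)) else ""))
  invisible(x)
}

#' Convert a list of spike trains to the tidy spike table
#'
#' @param trains list of `spike_train`.
#' @return data.frame `(electrode_id, time_s)` sorted by electrode then time.
#' @export
spike_table <- function(trains) {
  parts <- lapply(trains, function(tr) {
    if (!length(tr$times_s)) return(NULL)
    data.frame(electrode_id = tr$electrode_id, time_s = tr$times_s)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) return(data.frame(electrode_id = integer(), time_s = numeric()))
  out <- out[order(out$electrode_id, out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
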