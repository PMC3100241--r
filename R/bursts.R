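#' Burst-detection parameters
#'
#' The operational burst definition: a maximal run of at least `min_spikes`
#' consecutive spikes whose interspike intervals are all at or below
#' `max_isi_ms`. The 20-spike / 20-ms defaults are the standard criterion for
#' dissociated cortical cultures. `motif_gap_max_ms` bounds the interburst
#' gap that still groups bursts into doublet/triplet motifs.
#'
#' @param min_spikes minimum spikes per burst (>= 2; default 20).
#' @param max_isi_ms maximum intra-burst ISI, ms (default 20). The boundary is
#'   inclusive: an ISI of exactly `max_isi_ms` stays inside the burst.
#' @param motif_gap_max_ms maximum interburst gap (ms) joining bursts into a
#'   motif (default 50; must exceed `max_isi_ms`).
#' @return object of class `burst_params`.
#' @export
burst_params <- function(min_spikes = 20, max_isi_ms = 20, motif_gap_max_ms = 50) {
  if (min_spikes < 2) stop_param("min_spikes must be >= 2")
  check_pos(max_isi_ms, "max_isi_ms")
  if (motif_gap_max_ms <= max_isi_ms) {
    stop_param("motif_gap_max_ms must exceed max_isi_ms")
  }
  structure(list(min_spikes = as.integer(min_spikes), max_isi_ms = max_isi_ms,
                 motif_gap_max_ms = motif_gap_max_ms),
            class = "burst_params")
}

#' Segment a spike train into bursts
#'
#' Partitions the train into maximal runs of consecutive spikes whose ISIs
#' are all `<= max_isi_ms`; runs with at least `min_spikes` spikes become
#' bursts. Burst start/end are the first/last spike times (no padding), so
#' `duration_ms <= (n_spikes - 1) * max_isi_ms` always holds.
#'
#' @param x a `spike_train`, or a sorted numeric vector of spike times in
#'   seconds.
#' @param params a [burst_params()].
#' @param electrode_id electrode index recorded into the result when `x` is a
#'   bare numeric vector.
#' @return a `burst_train`: data.frame
#'   `(electrode_id, t_start_s, t_end_s, n_spikes, duration_ms)` with
#'   attribute `params`.
#' @export
detect_bursts <- function(x, params = burst_params(), electrode_id = NA_integer_) {
  if (inherits(x, "spike_train")) {
    times <- x$times_s
    electrode_id <- x$electrode_id
  } else {
    times <- as.numeric(x)
  }
  if (is.unsorted(times)) stop_param("spike times must be sorted")
  empty <- data.frame(electrode_id = integer(), t_start_s = numeric(),
                      t_end_s = numeric(), n_spikes = integer(),
                      duration_ms = numeric())
  if (length(times) == 0) return(burst_train(empty, params))
  ## run boundaries where the ISI exceeds the ceiling; the relative tolerance
  ## keeps an ISI of exactly max_isi_ms inside the burst despite float
  ## round-off in time arithmetic
  brk <- which(diff(times) > params$max_isi_ms / 1000 * (1 + 1e-9))
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(times))
  n <- ends - starts + 1L
  keep <- n >= params$min_spikes
  out <- data.frame(electrode_id = rep(electrode_id, sum(keep)),
                    t_start_s = times[starts[keep]],
                    t_end_s = times[ends[keep]],
                    n_spikes = n[keep],
                    duration_ms = (times[ends[keep]] - times[starts[keep]]) * 1000)
  burst_train(out, params)
}

burst_train <- function(df, params) {
  rownames(df) <- NULL
  structure(df, params = params, class = c("burst_train", "data.frame"))
}

#' @export
print.burst_train <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Burst train: %d bursts (>= %d spikes, ISI <= %g ms)\n",
              nrow(x), p$min_spikes, p$max_isi_ms))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Detect bursts on every electrode of a spike table
#'
#' @param spikes data.frame `(electrode_id, time_s)` or a list of
#'   `spike_train`.
#' @param params a [burst_params()].
#' @return a pooled `burst_train` ordered by (electrode, time).
#' @export
detect_bursts_all <- function(spikes, params = burst_params()) {
  if (is.list(spikes) && !is.data.frame(spikes)) spikes <- spike_table(spikes)
  stopifnot(all(c("electrode_id", "time_s") %in% names(spikes)))
  parts <- lapply(split(spikes$time_s, spikes$electrode_id), sort)
  ids <- as.integer(names(parts))
  out <- mapply(function(tt, id) as.data.frame(detect_bursts(tt, params, id)),
                parts, ids, SIMPLIFY = FALSE)
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(electrode_id = integer(), t_start_s = numeric(),
                      t_end_s = numeric(), n_spikes = integer(),
                      duration_ms = numeric())
  }
  out <- out[order(out$electrode_id, out$t_start_s), , drop = FALSE]
  burst_train(out, params)
}

#' Per-burst metric table
#'
#' One row per burst pooled across electrodes, order-stable by
#' (electrode, time).
#'
#' @param trains a `burst_train` or a list of them.
#' @return data.frame `(electrode_id, duration_ms, n_spikes)`.
#' @export
burst_metric_table <- function(trains) {
  if (inherits(trains, "burst_train")) trains <- list(trains)
  parts <- lapply(trains, function(bt) {
    as.data.frame(bt)[, c("electrode_id", "t_start_s", "duration_ms", "n_spikes")]
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$electrode_id, out$t_start_s), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("electrode_id", "duration_ms", "n_spikes")]
}

#' Interburst intervals of one electrode's burst train
#'
#' End-of-burst to start-of-next gaps in milliseconds. Defined end-to-start
#' (not start-to-start): the short first peak of the IBI distribution sits
#' just above the 20 ms ISI ceiling, which only end-to-start gaps produce.
#'
#' @param train a `burst_train` for a single electrode.
#' @return numeric vector of IBIs, ms (empty with fewer than 2 bursts).
#' @export
interburst_intervals <- function(train) {
  stopifnot(inherits(train, "burst_train"))
  if (nrow(train) < 2) return(numeric(0))
  if (length(unique(train$electrode_id)) > 1) {
    stop_param("interburst_intervals expects a single electrode's bursts")
  }
  (train$t_start_s[-1] - train$t_end_s[-nrow(train)]) * 1000
}

#' Pool interburst intervals across electrodes
#'
#' @param trains a pooled `burst_train` (as from [detect_bursts_all()]).
#' @param params a [burst_params()] (kept for the returned attribute).
#' @return numeric vector of all per-electrode IBIs, ms, pooled.
#' @export
pooled_ibis <- function(trains, params = attr(trains, "params")) {
  stopifnot(inherits(trains, "burst_train"))
  unlist(lapply(split(as.data.frame(trains), trains$electrode_id), function(df) {
    if (nrow(df) < 2) return(numeric(0))
    (df$t_start_s[-1] - df$t_end_s[-nrow(df)]) * 1000
  }), use.names = FALSE)
}

#' Label doublet/triplet burst motifs
#'
#' Groups consecutive bursts on one electrode whose connecting IBIs are
#' `<= motif_gap_max_ms`; groups of size 1/2/3 are singletons/doublets/
#' triplets, and larger groups are split greedily left-to-right into triplets
#' plus a remainder.
#'
#' @param train a single-electrode `burst_train`.
#' @param params a [burst_params()].
#' @return object of class `motif_summary`: counts `n_singletons`,
#'   `n_doublets`, `n_triplets`.
#' @export
label_motifs <- function(train, params = attr(train, "params")) {
  stopifnot(inherits(train, "burst_train"))
  if (is.null(params)) params <- burst_params()
  counts <- c(singleton = 0L, doublet = 0L, triplet = 0L)
  if (nrow(train) > 0) {
    ibis <- interburst_intervals(train)
    grp <- cumsum(c(1L, as.integer(ibis > params$motif_gap_max_ms)))
    for (size in tabulate(grp)) {
      counts["triplet"] <- counts["triplet"] + size %/% 3L
      r <- size %% 3L
      if (r == 1L) counts["singleton"] <- counts["singleton"] + 1L
      if (r == 2L) counts["doublet"] <- counts["doublet"] + 1L
    }
  }
  structure(list(n_singletons = counts[["singleton"]],
                 n_doublets = counts[["doublet"]],
                 n_triplets = counts[["triplet"]]),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat(sprintf("Burst motifs: %d singletons, %d doublets, %d triplets\n",
              x$n_singletons, x$n_doublets, x$n_triplets))
  invisible(x)
}
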