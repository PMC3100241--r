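#' Simulation parameters for a synthetic MEA culture
#'
#' Bundles the statistical description of one recording condition: spontaneous
#' activity is modelled as long silences (log-normal) punctuated by network
#' burst events shared across the electrode grid, where an event is a single
#' burst or a doublet/triplet motif of bursts separated by gaps just above the
#' burst-defining maximum ISI.
#'
#' @param condition_label character tag, e.g. `"control_7div"`.
#' @param duration_s recording length in seconds (default 600, i.e. 10 min).
#' @param n_electrodes number of electrodes (default 60, an 8 x 8 grid minus
#'   the reference corners).
#' @param long_ibi_median_s median of the long-silence distribution between
#'   burst events, seconds. `Inf` schedules no events.
#' @param long_ibi_log_sd log-scale SD of the long-silence log-normal.
#' @param motif_prob_doublet,motif_prob_triplet probability that a burst event
#'   is a doublet / triplet; their sum must be <= 1.
#' @param motif_gap_ms_range length-2 numeric, uniform range (ms) for the gap
#'   between motif member bursts; the lower bound must exceed `max_isi_ms`.
#' @param spikes_per_burst distribution of spike counts per burst, from
#'   [spikes_per_burst_dist()]; support must start at or above the burst
#'   detector's minimum spike count.
#' @param burst_duration duration distribution (ms), from
#'   [burst_duration_dist()] or [calibrate_burst_duration_dist()].
#' @param network_jitter_ms SD (ms) of the Gaussian jitter applied to each
#'   electrode's copy of a shared network event onset.
#' @param sync if `TRUE` (default) burst events are network-wide with
#'   per-electrode jitter; if `FALSE` each electrode runs an independent
#'   event schedule.
#' @param max_isi_ms intra-burst ISI ceiling the generated bursts must obey
#'   (default 20 ms, matching the burst definition).
#' @param seed integer seed; same parameters and seed give identical output.
#' @return an object of class `sim_params`.
#' @seealso [generate_spike_trains()], [fixture_conditions()]
#' @export
sim_params <- function(condition_label = "condition",
                       duration_s = 600,
                       n_electrodes = 60,
                       long_ibi_median_s = 20,
                       long_ibi_log_sd = 0.8,
                       motif_prob_doublet = 0,
                       motif_prob_triplet = 0,
                       motif_gap_ms_range = c(22, 50),
                       spikes_per_burst = spikes_per_burst_dist(mean = 48),
                       burst_duration = burst_duration_dist(mean_ms = 180, shape = 2),
                       network_jitter_ms = 10,
                       sync = TRUE,
                       max_isi_ms = 20,
                       seed = NULL) {
  check_pos(duration_s, "duration_s")
  check_pos(n_electrodes, "n_electrodes")
  if (!is.numeric(long_ibi_median_s) || length(long_ibi_median_s) != 1 ||
      is.na(long_ibi_median_s) || long_ibi_median_s <= 0) {
    stop_param("'long_ibi_median_s' must be > 0 (Inf schedules no events)")
  }
  if (!is.infinite(long_ibi_median_s)) check_pos(long_ibi_log_sd, "long_ibi_log_sd", strict = FALSE)
  check_prob(motif_prob_doublet, "motif_prob_doublet")
  check_prob(motif_prob_triplet, "motif_prob_triplet")
  if (motif_prob_doublet + motif_prob_triplet > 1) {
    stop_param("motif_prob_doublet + motif_prob_triplet must be <= 1")
  }
  if (length(motif_gap_ms_range) != 2 || motif_gap_ms_range[1] <= max_isi_ms ||
      diff(motif_gap_ms_range) < 0) {
    stop_param("motif_gap_ms_range must be (low, high) with low > max_isi_ms (%g ms)",
               max_isi_ms)
  }
  stopifnot(inherits(spikes_per_burst, "spb_dist"),
            inherits(burst_duration, "dur_dist"))
  if (spikes_per_burst$min < 2) {
    stop_param("spikes_per_burst support must start at >= 2 spikes")
  }
  check_pos(network_jitter_ms, "network_jitter_ms", strict = FALSE)
  structure(list(
    condition_label = condition_label,
    duration_s = duration_s,
    n_electrodes = as.integer(n_electrodes),
    long_ibi_median_s = long_ibi_median_s,
    long_ibi_log_sd = long_ibi_log_sd,
    motif_prob_doublet = motif_prob_doublet,
    motif_prob_triplet = motif_prob_triplet,
    motif_gap_ms_range = motif_gap_ms_range,
    spikes_per_burst = spikes_per_burst,
    burst_duration = burst_duration,
    network_jitter_ms = network_jitter_ms,
    sync = isTRUE(sync),
    max_isi_ms = max_isi_ms,
    seed = seed
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Simulation parameters: %s\n", x$condition_label))
  cat(sprintf("  %g s x %d electrodes; long-IBI median %g s (log-SD %g)\n",
              x$duration_s, x$n_electrodes, x$long_ibi_median_s, x$long_ibi_log_sd))
  cat(sprintf("  motifs: P(doublet) %g, P(triplet) %g, gaps U(%g, %g) ms\n",
              x$motif_prob_doublet, x$motif_prob_triplet,
              x$motif_gap_ms_range[1], x$motif_gap_ms_range[2]))
  cat(sprintf("  spikes/burst: %s (mean %.2f, min %d); duration: %s (mean %.1f ms)\n",
              x$spikes_per_burst$dist, x$spikes_per_burst$mean, x$spikes_per_burst$min,
              x$burst_duration$dist, x$burst_duration$mean_ms))
  invisible(x)
}

#' Spikes-per-burst distribution
#'
#' A shifted negative binomial: `min + NB(size, mu = mean - min)`, giving the
#' exponential-like right tail seen in spikes-per-burst histograms while
#' respecting the burst detector's minimum spike count.
#'
#' @param mean target mean spike count (must exceed `min`).
#' @param size negative-binomial dispersion; smaller is more dispersed.
#'   `Inf` gives a (shifted) Poisson-like concentration via large size.
#' @param min minimum spike count (default 20, the burst definition).
#' @return an object of class `spb_dist` with a `$sample(n)` draw function.
#' @export
spikes_per_burst_dist <- function(mean, size = 1.5, min = 20) {
  check_pos(mean, "mean"); check_pos(size, "size"); check_pos(min, "min")
  if (mean <= min) stop_param("mean spikes per burst must exceed the minimum (%g)", min)
  mu <- mean - min
  structure(list(dist = "shifted negative binomial", mean = mean, size = size,
                 min = as.integer(min),
                 sample = function(n) {
                   as.integer(min) + if (is.finite(size)) {
                     stats::rnbinom(n, size = size, mu = mu)
                   } else {
                     stats::rpois(n, lambda = mu)
                   }
                 }),
            class = "spb_dist")
}

#' Burst-duration distribution
#'
#' Gamma distribution of burst durations in milliseconds, parameterized by
#' its mean and shape.
#'
#' @param mean_ms mean duration, ms.
#' @param shape gamma shape; small values give a right-skewed distribution,
#'   large values an approximately symmetric one.
#' @return an object of class `dur_dist` with a `$sample(n)` draw function.
#' @seealso [calibrate_burst_duration_dist()] to fix the shape from a
#'   quantile constraint.
#' @export
burst_duration_dist <- function(mean_ms, shape) {
  check_pos(mean_ms, "mean_ms"); check_pos(shape, "shape")
  scale <- mean_ms / shape
  structure(list(dist = "gamma", mean_ms = mean_ms, shape = shape, scale = scale,
                 sample = function(n) stats::rgamma(n, shape = shape, scale = scale),
                 quantile = function(p) stats::qgamma(p, shape = shape, scale = scale)),
            class = "dur_dist")
}

#' Calibrate a gamma burst-duration distribution to a mean and a quantile
#'
#' Finds gamma (shape, scale) such that the mean equals `target_mean_ms` and
#' the CDF at `cutoff_ms` equals `target_frac_le_cutoff`, by a root search
#' over the shape (scale = mean/shape keeps the mean exact). Shapes are
#' restricted to \[0.01, 1e6\]: below that the gamma degenerates into a spike
#' at zero, a regime useless for burst durations. When the constraint pair
#' admits two shape roots (cutoff slightly above the mean), the smaller,
#' right-skewed root is returned, matching the skewed duration histograms of
#' immature cultures.
#'
#' @param target_mean_ms target mean duration, ms.
#' @param target_frac_le_cutoff target CDF value at `cutoff_ms`, in (0, 1).
#' @param cutoff_ms the duration cutoff, ms.
#' @return a `dur_dist` (see [burst_duration_dist()]) with the calibrated
#'   shape; both residuals are below 1e-6.
#' @examples
#' d <- calibrate_burst_duration_dist(182.5, 0.65, 200)
#' d$mean_ms                                  # 182.5
#' pgamma(200, d$shape, scale = d$scale)      # 0.65
#' @export
calibrate_burst_duration_dist <- function(target_mean_ms, target_frac_le_cutoff,
                                          cutoff_ms) {
  check_pos(target_mean_ms, "target_mean_ms")
  check_pos(cutoff_ms, "cutoff_ms")
  if (!is.numeric(target_frac_le_cutoff) || target_frac_le_cutoff <= 0 ||
      target_frac_le_cutoff >= 1) {
    stop_param("target_frac_le_cutoff must lie strictly in (0, 1)")
  }
  f <- function(log_shape) {
    shape <- exp(log_shape)
    stats::pgamma(cutoff_ms, shape = shape, scale = target_mean_ms / shape) -
      target_frac_le_cutoff
  }
  lo <- log(0.01); hi <- log(1e6)
  ## scan for the first sign change from the small-shape end
  grid <- seq(lo, hi, length.out = 400)
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-length(sgn)] != 0)
  if (length(flip) == 0) {
    stop_param(paste0("no gamma with mean %g has CDF(%g) = %g ",
                      "(infeasible constraint pair)"),
               target_mean_ms, cutoff_ms, target_frac_le_cutoff)
  }
  root <- stats::uniroot(f, lower = grid[flip[1]], upper = grid[flip[1] + 1],
                         tol = 1e-12)
  shape <- exp(root$root)
  out <- burst_duration_dist(mean_ms = target_mean_ms, shape = shape)
  resid <- abs(stats::pgamma(cutoff_ms, shape = shape, scale = out$scale) -
                 target_frac_le_cutoff)
  if (resid > 1e-6) {
    stop_param("calibration did not converge (quantile residual %.2g)", resid)
  }
  out
}

## Place n spikes spanning exactly duration_ms with every ISI in (0, max_isi_ms].
## ISIs are drawn exponential with the matching mean, rescaled to sum to the
## duration, and redrawn if rescaling pushes any ISI above the ceiling. When
## the mean ISI sits close to the ceiling that rejection rarely accepts, so
## after `max_tries` draws a bounded-jitter scheme takes over: equal spacing
## plus zero-sum uniform jitter scaled to keep every ISI strictly inside
## (0, max_isi_ms). Both schemes span the duration exactly.
place_burst_spikes <- function(n, duration_ms, max_isi_ms = 20, max_tries = 50) {
  stopifnot(n >= 2)
  if (duration_ms > (n - 1) * max_isi_ms) {
    stop_param("burst of %d spikes cannot span %.1f ms without an ISI > %g ms",
               n, duration_ms, max_isi_ms)
  }
  if (duration_ms <= 0) stop_param("burst duration must be positive")
  ceiling_ms <- max_isi_ms * (1 - 1e-9)   # guard float round-off in later diffs
  m <- n - 1L
  if (m == 1L) {
    if (duration_ms > ceiling_ms) {
      stop_param("2-spike burst of %.3f ms exceeds the %g ms ISI ceiling",
                 duration_ms, max_isi_ms)
    }
    return(c(0, duration_ms / 1000))
  }
  for (i in seq_len(max_tries)) {
    isi <- stats::rexp(m, rate = m / duration_ms)
    isi <- isi * (duration_ms / sum(isi))
    if (max(isi) <= ceiling_ms && min(isi) > 0) {
      return(cumsum(c(0, isi)) / 1000)    # seconds, relative to burst onset
    }
  }
  base <- duration_ms / m
  amp <- 0.98 * min(base, ceiling_ms - base)
  if (amp <= 0) {
    stop_param("could not place %d spikes in %.1f ms with ISIs <= %g ms",
               n, duration_ms, max_isi_ms)
  }
  e <- stats::runif(m, -1, 1)
  e <- e - mean(e)
  isi <- base + e * (amp / max(abs(e)))
  isi <- isi * (duration_ms / sum(isi))   # exact span despite float drift
  cumsum(c(0, isi)) / 1000
}

## Minimum spike count able to span duration d under the ISI ceiling,
## never below the configured support minimum.
spike_floor <- function(d_ms, min_spikes, max_isi_ms) {
  pmax(min_spikes, ceiling(d_ms / (max_isi_ms * (1 - 1e-6))) + 1)
}

## Mean of the duration-imposed spike floor under the duration distribution,
## by midpoint quadrature on the quantile scale. Used to calibrate the
## negative-binomial excess so the marginal spike-count mean hits its target.
expected_spike_floor <- function(dur_dist, min_spikes, max_isi_ms, k = 20000L) {
  q <- dur_dist$quantile((seq_len(k) - 0.5) / k)
  mean(spike_floor(q, min_spikes, max_isi_ms))
}

## Draw one burst: duration from its configured distribution untouched (so
## the duration mean is exact), spike count = duration-imposed floor plus a
## negative-binomial excess with mean mu_extra. Longer bursts therefore carry
## more spikes, and duration <= (n-1) * max_isi holds by construction.
draw_burst <- function(params, mu_extra) {
  d <- params$burst_duration$sample(1)
  n <- spike_floor(d, params$spikes_per_burst$min, params$max_isi_ms) +
    stats::rnbinom(1, size = params$spikes_per_burst$size, mu = mu_extra)
  list(n = n, duration_ms = d)
}

#' Generate synthetic spike trains with ground truth
#'
#' Simulates spontaneous MEA activity as long silences punctuated by network
#' burst events. Event onsets follow a log-normal interval distribution with
#' the configured median; each event is a singleton, doublet or triplet of
#' bursts whose member gaps are uniform in `motif_gap_ms_range`; each burst
#' draws a spike count and a duration and places spikes so every intra-burst
#' ISI stays at or below the ISI ceiling. In synchronized mode the event
#' schedule is shared across electrodes with Gaussian onset jitter.
#'
#' @param params a [sim_params()] object.
#' @return a list of class `mea_simulation` with elements
#'   \describe{
#'     \item{spikes}{data.frame `(electrode_id, time_s)`, times sorted within
#'       electrode — the spike-train table consumed by [detect_bursts()].}
#'     \item{ground_truth}{data.frame of true bursts
#'       `(electrode_id, t_start_s, t_end_s, n_spikes, duration_ms, event, member)`.}
#'     \item{params}{the parameters used.}
#'   }
#' @export
generate_spike_trains <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    n_el <- params$n_electrodes
    empty <- list(
      spikes = data.frame(electrode_id = integer(), time_s = numeric()),
      ground_truth = data.frame(electrode_id = integer(), t_start_s = numeric(),
                                t_end_s = numeric(), n_spikes = integer(),
                                duration_ms = numeric(), event = integer(),
                                member = integer()),
      params = params
    )
    if (is.infinite(params$long_ibi_median_s)) {
      return(structure(empty, class = "mea_simulation"))
    }
    meanlog <- log(params$long_ibi_median_s)
    sdlog <- params$long_ibi_log_sd
    floor_mean <- expected_spike_floor(params$burst_duration,
                                       params$spikes_per_burst$min,
                                       params$max_isi_ms)
    mu_extra <- params$spikes_per_burst$mean - floor_mean
    if (mu_extra <= 0) {
      stop_param(paste0("infeasible parameters: mean spikes per burst (%.2f) ",
                        "does not exceed the mean spike count (%.2f) the ",
                        "duration distribution forces under a %g ms ISI ceiling"),
                 params$spikes_per_burst$mean, floor_mean, params$max_isi_ms)
    }
    schedule_events <- function() {
      t <- 0; onsets <- numeric(0)
      repeat {
        t <- t + stats::rlnorm(1, meanlog = meanlog, sdlog = sdlog)
        if (t >= params$duration_s) break
        onsets <- c(onsets, t)
      }
      onsets
    }
    p_d <- params$motif_prob_doublet; p_t <- params$motif_prob_triplet
    shared <- if (params$sync) {
      on <- schedule_events()
      list(onsets = on,
           sizes = sample.int(3, length(on), replace = TRUE,
                              prob = c(1 - p_d - p_t, p_d, p_t)))
    } else NULL

    spk_el <- vector("list", n_el); gt_el <- vector("list", n_el)
    for (el in seq_len(n_el)) {
      if (params$sync) {
        onsets <- shared$onsets +
          stats::rnorm(length(shared$onsets), sd = params$network_jitter_ms / 1000)
        sizes <- shared$sizes
        keep <- onsets >= 0 & onsets < params$duration_s
        onsets <- onsets[keep]; sizes <- sizes[keep]
        ord <- order(onsets); onsets <- onsets[ord]; sizes <- sizes[ord]
      } else {
        onsets <- schedule_events()
        sizes <- sample.int(3, length(onsets), replace = TRUE,
                            prob = c(1 - p_d - p_t, p_d, p_t))
      }
      times <- vector("list", length(onsets)); gts <- vector("list", length(onsets))
      for (ev in seq_along(onsets)) {
        t0 <- onsets[ev]
        member_times <- vector("list", sizes[ev])
        member_gt <- vector("list", sizes[ev])
        for (m in seq_len(sizes[ev])) {
          b <- draw_burst(params, mu_extra)
          rel <- place_burst_spikes(b$n, b$duration_ms, params$max_isi_ms)
          st <- t0 + rel
          if (st[length(st)] >= params$duration_s) { member_times[m] <- list(NULL); break }
          member_times[[m]] <- st
          member_gt[[m]] <- data.frame(electrode_id = el, t_start_s = st[1],
                                       t_end_s = st[length(st)], n_spikes = b$n,
                                       duration_ms = b$duration_ms,
                                       event = ev, member = m)
          t0 <- st[length(st)] + stats::runif(1, params$motif_gap_ms_range[1],
                                              params$motif_gap_ms_range[2]) / 1000
        }
        times[[ev]] <- unlist(member_times)
        gts[[ev]] <- do.call(rbind, member_gt)
      }
      tt <- unlist(times)
      spk_el[[el]] <- if (length(tt)) data.frame(electrode_id = el, time_s = tt) else NULL
      gt_el[[el]] <- do.call(rbind, gts)
    }
    spikes <- do.call(rbind, spk_el)
    gt <- do.call(rbind, gt_el)
    if (is.null(spikes)) return(structure(empty, class = "mea_simulation"))
    spikes <- spikes[order(spikes$electrode_id, spikes$time_s), , drop = FALSE]
    rownames(spikes) <- NULL
    gt <- gt[order(gt$electrode_id, gt$t_start_s), , drop = FALSE]
    rownames(gt) <- NULL
    structure(list(spikes = spikes, ground_truth = gt, params = params),
              class = "mea_simulation")
  })
}

#' @export
print.mea_simulation <- function(x, ...) {
  cat(sprintf("Synthetic MEA culture: %s\n", x$params$condition_label))
  cat(sprintf("  %d spikes on %d electrodes, %d true bursts over %g s\n",
              nrow(x$spikes), length(unique(x$spikes$electrode_id)),
              nrow(x$ground_truth), x$params$duration_s))
  invisible(x)
}

#' Extracellular spike waveform template
#'
#' A deterministic biphasic template (sharp negative deflection followed by a
#' smaller positive overshoot), used to synthesize raw voltage for exercising
#' threshold detection. The waveform minimum equals `peak_uv`.
#'
#' @param sampling_rate_hz sampling rate, Hz.
#' @param peak_uv negative-going peak amplitude, microvolts (must be < 0).
#' @param duration_ms template length, ms (default 1.5).
#' @return list of class `spike_template` with `waveform` (microvolts),
#'   `peak_uv`, `peak_offset_s` (time of the minimum relative to template
#'   start) and `sampling_rate_hz`.
#' @export
spike_template <- function(sampling_rate_hz = 25000, peak_uv = -100,
                           duration_ms = 1.5) {
  check_pos(sampling_rate_hz, "sampling_rate_hz")
  if (peak_uv >= 0) stop_param("peak_uv must be negative (extracellular convention)")
  n <- max(2L, round(duration_ms / 1000 * sampling_rate_hz))
  t <- seq(0, duration_ms, length.out = n)
  w <- -exp(-((t - 0.3 * duration_ms)^2) / (2 * (0.08 * duration_ms)^2)) +
    0.35 * exp(-((t - 0.65 * duration_ms)^2) / (2 * (0.18 * duration_ms)^2))
  w <- w * abs(peak_uv) / abs(min(w))
  structure(list(waveform = w, peak_uv = peak_uv,
                 peak_offset_s = t[which.min(w)] / 1000,
                 sampling_rate_hz = sampling_rate_hz),
            class = "spike_template")
}

#' Synthesize a raw voltage recording from spike trains
#'
#' Adds the spike template (starting at the sample nearest each spike time)
#' to white Gaussian noise on every channel. Overlapping templates are
#' summed.
#'
#' @param spikes data.frame `(electrode_id, time_s)` (e.g. the `spikes`
#'   element of [generate_spike_trains()] output).
#' @param template a [spike_template()]; its sampling rate must match the
#'   recording config.
#' @param noise_sd Gaussian noise SD, microvolts (may be 0).
#' @param config a [recording_config()].
#' @param seed integer seed for the noise.
#' @return a `raw_recording`: list with `voltage` (channels x samples matrix,
#'   microvolts) and `config`.
#' @export
synthesize_voltage <- function(spikes, template, noise_sd, config, seed = NULL) {
  stopifnot(inherits(template, "spike_template"), inherits(config, "recording_config"))
  if (template$sampling_rate_hz != config$sampling_rate_hz) {
    stop_param("template sampling rate (%g) != recording rate (%g)",
               template$sampling_rate_hz, config$sampling_rate_hz)
  }
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (nrow(spikes) && any(spikes$time_s >= config$duration_s)) {
    stop_param("spike time beyond trace end (duration %g s)", config$duration_s)
  }
  ns <- round(config$duration_s * config$sampling_rate_hz)
  nch <- config$n_electrodes
  w <- template$waveform; lw <- length(w)
  with_seed(seed, {
    v <- if (noise_sd > 0) {
      matrix(stats::rnorm(nch * ns, sd = noise_sd), nrow = nch)
    } else {
      matrix(0, nrow = nch, ncol = ns)
    }
    for (ch in seq_len(nch)) {
      tt <- spikes$time_s[spikes$electrode_id == ch]
      for (t in tt) {
        i0 <- round(t * config$sampling_rate_hz) + 1
        i1 <- min(i0 + lw - 1, ns)
        v[ch, i0:i1] <- v[ch, i0:i1] + w[seq_len(i1 - i0 + 1)]
      }
    }
    structure(list(voltage = v, config = config), class = "raw_recording")
  })
}

#' Spine-population simulation parameters
#'
#' @param n_cells number of cells.
#' @param mean_spines_per_cell mean spine count per cell; per-cell counts are
#'   Poisson with this mean, truncated to at least 1 (default 13, the typical
#'   count on the second apical branch).
#' @param shape_probs probability vector over the 8 spine shape classes
#'   (must sum to 1).
#' @param psd95_prob probability that a spine carries a PSD-95 punctum;
#'   `NA` omits PSD-95 flags.
#' @param condition_label character tag.
#' @param seed integer seed.
#' @return object of class `spine_sim_params`.
#' @export
spine_sim_params <- function(n_cells, mean_spines_per_cell = 13,
                             shape_probs, psd95_prob = NA,
                             condition_label = "condition", seed = NULL) {
  check_pos(n_cells, "n_cells")
  check_pos(mean_spines_per_cell, "mean_spines_per_cell")
  if (length(shape_probs) != 8 || any(shape_probs < 0) ||
      abs(sum(shape_probs) - 1) > 1e-9) {
    stop_param("shape_probs must be 8 non-negative probabilities summing to 1")
  }
  if (!is.na(psd95_prob)) check_prob(psd95_prob, "psd95_prob")
  structure(list(n_cells = as.integer(n_cells),
                 mean_spines_per_cell = mean_spines_per_cell,
                 shape_probs = as.numeric(shape_probs),
                 psd95_prob = psd95_prob,
                 condition_label = condition_label, seed = seed),
            class = "spine_sim_params")
}

#' Generate a synthetic spine population
#'
#' Spine counts per cell are Poisson (truncated >= 1), shape classes are
#' i.i.d. categorical over the 8-class scheme, and PSD-95 flags are i.i.d.
#' Bernoulli.
#'
#' @param params a [spine_sim_params()].
#' @return data.frame `(cell_id, condition, shape_class, psd95)`; `psd95` is
#'   logical, all-`NA` when `psd95_prob` is `NA`.
#' @export
generate_spine_population <- function(params) {
  stopifnot(inherits(params, "spine_sim_params"))
  with_seed(params$seed, {
    counts <- stats::rpois(params$n_cells, params$mean_spines_per_cell)
    counts[counts == 0] <- 1L
    total <- sum(counts)
    classes <- sample.int(8, total, replace = TRUE, prob = params$shape_probs)
    psd <- if (is.na(params$psd95_prob)) rep(NA, total) else
      stats::runif(total) < params$psd95_prob
    data.frame(cell_id = rep(seq_len(params$n_cells), counts),
               condition = params$condition_label,
               shape_class = classes,
               psd95 = psd)
  })
}
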