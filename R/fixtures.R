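#' Built-in condition fixtures
#'
#' Returns the four standard culture conditions (control / EphA4 transfection
#' at 7 and 14 days in vitro) as ready-to-use [sim_params()] objects. Mean
#' burst durations and mean spikes per burst are set to the reported group
#' means; the 7 DIV duration gammas are additionally calibrated to the
#' reported fraction of bursts at or below 200 ms (65% control, 53% EphA4),
#' while the 14 DIV shapes encode the qualitative histogram forms (control
#' approximately symmetric, EphA4 right-skewed). Long-silence medians are
#' 20 s at 7 DIV and 10 s at 14 DIV, matching the observed second peak of
#' the interburst-interval distribution; motif probabilities and log-SDs are
#' calibration choices reflecting the relative first-peak heights and
#' second-peak spreads.
#'
#' @param duration_s recording length per culture (default 600 s).
#' @param n_electrodes electrode count (default 60).
#' @param seed optional seed stored into every condition's params.
#' @return named list of `sim_params`: `control_7div`, `epha4_7div`,
#'   `control_14div`, `epha4_14div`. Each carries a `div` attribute.
#' @export
fixture_conditions <- function(duration_s = 600, n_electrodes = 60, seed = NULL) {
  mk <- function(label, div, dur, spb, median_s, log_sd, p_d, p_t) {
    p <- sim_params(condition_label = label,
                    duration_s = duration_s, n_electrodes = n_electrodes,
                    long_ibi_median_s = median_s, long_ibi_log_sd = log_sd,
                    motif_prob_doublet = p_d, motif_prob_triplet = p_t,
                    spikes_per_burst = spb, burst_duration = dur,
                    seed = seed)
    attr(p, "div") <- div
    p
  }
  list(
    control_7div = mk("control_7div", 7,
                      calibrate_burst_duration_dist(182.5, 0.65, 200),
                      spikes_per_burst_dist(mean = 47.69, size = 1.5),
                      median_s = 20, log_sd = 0.8, p_d = 0.15, p_t = 0.05),
    epha4_7div = mk("epha4_7div", 7,
                    calibrate_burst_duration_dist(211.2, 0.53, 200),
                    spikes_per_burst_dist(mean = 48.57, size = 0.8),
                    median_s = 20, log_sd = 1.0, p_d = 0.25, p_t = 0.10),
    control_14div = mk("control_14div", 14,
                       burst_duration_dist(mean_ms = 214.2, shape = 12),
                       spikes_per_burst_dist(mean = 59.8, size = 1.0),
                       median_s = 10, log_sd = 0.5, p_d = 0.10, p_t = 0.03),
    epha4_14div = mk("epha4_14div", 14,
                     burst_duration_dist(mean_ms = 248.9, shape = 4),
                     spikes_per_burst_dist(mean = 73.2, size = 1.0),
                     median_s = 10, log_sd = 0.8, p_d = 0.25, p_t = 0.12)
  )
}

#' Built-in spine-population fixtures
#'
#' Control and EphA4 spine-shape class distributions. Classes 6 and 7 are set
#' to the reported per-class group means (control 0.16 and 0.08; EphA4 0.22
#' and 0.12); class 8 takes the remainder of the reported mature totals (0.30
#' control, 0.44 EphA4). The immature mass is spread over classes 1-5 with a
#' mild decreasing profile (a calibration choice; the per-class immature
#' proportions are not reported).
#'
#' @param n_cells cells per condition (default 75 = 25 cells x 3 experiments).
#' @param seed optional seed stored into the params.
#' @return named list of [spine_sim_params()]: `control`, `epha4`.
#' @export
fixture_spine_conditions <- function(n_cells = 75, seed = NULL) {
  immature_profile <- c(0.30, 0.25, 0.20, 0.15, 0.10)   # relative weights, classes 1-5
  mk <- function(label, p6, p7, mature_total, psd95) {
    p8 <- mature_total - p6 - p7
    probs <- c(immature_profile / sum(immature_profile) * (1 - mature_total),
               p6, p7, p8)
    spine_sim_params(n_cells = n_cells, mean_spines_per_cell = 13,
                     shape_probs = probs, psd95_prob = psd95,
                     condition_label = label, seed = seed)
  }
  list(control = mk("control", 0.16, 0.08, 0.30, psd95 = 0.50),
       epha4 = mk("epha4", 0.22, 0.12, 0.44, psd95 = 0.60))
}
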