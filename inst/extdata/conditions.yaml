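# Standard culture conditions: control / EphA4 transfection at 7 and 14 DIV.
# Duration gammas at 7 DIV are calibrated from (mean, fraction <= cutoff);
# at 14 DIV shapes encode the qualitative histogram forms (control roughly
# symmetric, EphA4 right-skewed).
control_7div:
  div: 7
  duration_s: 600
  n_electrodes: 60
  long_ibi_median_s: 20
  long_ibi_log_sd: 0.8
  motif_prob_doublet: 0.15
  motif_prob_triplet: 0.05
  burst_duration: {mean_ms: 182.5, frac_le_cutoff: 0.65, cutoff_ms: 200}
  spikes_per_burst: {mean: 47.69, size: 1.5}
epha4_7div:
  div: 7
  duration_s: 600
  n_electrodes: 60
  long_ibi_median_s: 20
  long_ibi_log_sd: 1.0
  motif_prob_doublet: 0.25
  motif_prob_triplet: 0.10
  burst_duration: {mean_ms: 211.2, frac_le_cutoff: 0.53, cutoff_ms: 200}
  spikes_per_burst: {mean: 48.57, size: 0.8}
control_14div:
  div: 14
  duration_s: 600
  n_electrodes: 60
  long_ibi_median_s: 10
  long_ibi_log_sd: 0.5
  motif_prob_doublet: 0.10
  motif_prob_triplet: 0.03
  burst_duration: {mean_ms: 214.2, shape: 12}
  spikes_per_burst: {mean: 59.8, size: 1.0}
epha4_14div:
  div: 14
  duration_s: 600
  n_electrodes: 60
  long_ibi_median_s: 10
  long_ibi_log_sd: 0.8
  motif_prob_doublet: 0.25
  motif_prob_triplet: 0.12
  burst_duration: {mean_ms: 248.9, shape: 4}
  spikes_per_burst: {mean: 73.2, size: 1.0}
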