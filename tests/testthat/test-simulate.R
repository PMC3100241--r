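test_that("generator is deterministic and degenerate rates give empty output", {
  p <- small_sim(seed = 11)
  a <- generate_spike_trains(p)
  b <- generate_spike_trains(p)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$ground_truth, b$ground_truth)

  p_inf <- sim_params(long_ibi_median_s = Inf, duration_s = 60,
                      n_electrodes = 4, seed = 1)
  empty <- generate_spike_trains(p_inf)
  expect_equal(nrow(empty$spikes), 0)
  expect_equal(nrow(empty$ground_truth), 0)
})

test_that("generated bursts obey the ISI ceiling and gap structure", {
  for (seed in c(3, 17)) {
    sim <- generate_spike_trains(small_sim(seed))
    gt <- sim$ground_truth
    expect_gt(nrow(gt), 10)
    for (el in unique(sim$spikes$electrode_id)) {
      tt <- sim$spikes$time_s[sim$spikes$electrode_id == el]
      g <- gt[gt$electrode_id == el, ]
      ## every intra-burst ISI at or below 20 ms
      for (i in seq_len(nrow(g))) {
        inb <- tt[tt >= g$t_start_s[i] & tt <= g$t_end_s[i]]
        expect_equal(length(inb), g$n_spikes[i])
        expect_lte(max(diff(inb)), 0.020)
      }
      ## every gap between consecutive true bursts exceeds 20 ms
      if (nrow(g) > 1) {
        gaps <- g$t_start_s[-1] - g$t_end_s[-nrow(g)]
        expect_gt(min(gaps), 0.020)
      }
      ## every spike lies in exactly one or zero true bursts
      hits <- vapply(tt, function(t) sum(t >= g$t_start_s & t <= g$t_end_s), 0)
      expect_true(all(hits <= 1))
    }
  }
})

test_that("event rate matches the configured long-silence median", {
  ## ~600/20 = 30 events per electrode when gaps are (nearly) deterministic
  counts <- vapply(1:3, function(seed) {
    p <- sim_params(duration_s = 600, n_electrodes = 60,
                    long_ibi_median_s = 20, long_ibi_log_sd = 1e-9,
                    spikes_per_burst = spikes_per_burst_dist(mean = 45, size = 1.5),
                    burst_duration = burst_duration_dist(mean_ms = 180, shape = 2),
                    seed = seed)
    nrow(generate_spike_trains(p)$ground_truth) / 60
  }, numeric(1))
  expect_lt(abs(mean(counts) - 30), 5)
})

test_that("burst duration and spike-count means match the configuration", {
  p <- sim_params(duration_s = 300, n_electrodes = 30,
                  long_ibi_median_s = 5, long_ibi_log_sd = 0.5,
                  spikes_per_burst = spikes_per_burst_dist(mean = 50, size = 1.5),
                  burst_duration = burst_duration_dist(mean_ms = 200, shape = 3),
                  seed = 5)
  gt <- generate_spike_trains(p)$ground_truth
  expect_gt(nrow(gt), 1000)
  se_d <- sd(gt$duration_ms) / sqrt(nrow(gt))
  se_n <- sd(gt$n_spikes) / sqrt(nrow(gt))
  expect_lt(abs(mean(gt$duration_ms) - 200), 3 * se_d)
  expect_lt(abs(mean(gt$n_spikes) - 50), 3 * se_n)
})

test_that("duration calibration hits mean and quantile to 1e-6", {
  d <- calibrate_burst_duration_dist(182.5, 0.65, 200)
  expect_equal(d$shape * d$scale, 182.5, tolerance = 1e-9)
  expect_lt(abs(pgamma(200, d$shape, scale = d$scale) - 0.65), 1e-6)

  ## approach to symmetry: as the target fraction at the mean drops toward
  ## 1/2 the calibrated gamma must become ever more symmetric (larger shape,
  ## median approaching the mean)
  shapes <- vapply(c(0.60, 0.55, 0.52),
                   function(f) calibrate_burst_duration_dist(100, f, 100)$shape,
                   numeric(1))
  expect_true(all(diff(shapes) > 0))
  med <- qgamma(0.5, shapes[3], scale = 100 / shapes[3])
  expect_lt(abs(med - 100) / 100, 0.03)

  ## no gamma puts 99% of its mass below its mean (within the supported
  ## non-degenerate shape range)
  expect_error(calibrate_burst_duration_dist(100, 0.99, 100), "infeasible")
})

test_that("parameter invariants are enforced", {
  expect_error(sim_params(motif_prob_doublet = 0.7, motif_prob_triplet = 0.5),
               "<= 1")
  expect_error(sim_params(motif_gap_ms_range = c(15, 50)), "low > max_isi")
  expect_error(spikes_per_burst_dist(mean = 15, min = 20), "exceed")
  expect_error(place_burst_spikes(20, 20 * 19 + 1), "ISI")
  ## a duration distribution far beyond what the spike-count mean can span
  p_bad <- sim_params(duration_s = 10, n_electrodes = 1, long_ibi_median_s = 2,
                      spikes_per_burst = spikes_per_burst_dist(mean = 21, size = 1),
                      burst_duration = burst_duration_dist(mean_ms = 2000, shape = 20),
                      seed = 1)
  expect_error(generate_spike_trains(p_bad), "infeasible")
})

test_that("spike placement spans the duration with ISIs inside the ceiling", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(20:80, 1)
    d <- runif(1, 30, (n - 1) * 20 * 0.999)
    rel <- place_burst_spikes(n, d)
    expect_equal(length(rel), n)
    expect_equal((rel[n] - rel[1]) * 1000, d, tolerance = 1e-9)
    expect_lte(max(diff(rel)), 0.020)
    expect_gt(min(diff(rel)), 0)
  }
  ## near-ceiling case that defeats rejection sampling alone
  rel <- place_burst_spikes(20, 370)
  expect_lte(max(diff(rel)), 0.020)
  expect_equal((rel[20] - rel[1]) * 1000, 370, tolerance = 1e-9)
})

test_that("voltage synthesis places templates and honours the noise level", {
  cfg <- recording_config(duration_s = 1, n_electrodes = 2)
  tpl <- spike_template(cfg$sampling_rate_hz, peak_uv = -80)
  no_spikes <- data.frame(electrode_id = integer(), time_s = numeric())

  silent <- synthesize_voltage(no_spikes, tpl, noise_sd = 0, cfg)
  expect_true(all(silent$voltage == 0))

  one <- synthesize_voltage(data.frame(electrode_id = 1, time_s = 0.5),
                            tpl, noise_sd = 0, cfg)
  i0 <- round(0.5 * cfg$sampling_rate_hz) + 1
  w <- tpl$waveform
  expect_equal(one$voltage[1, i0:(i0 + length(w) - 1)], w)
  expect_true(all(one$voltage[1, seq_len(i0 - 1)] == 0))
  expect_true(all(one$voltage[2, ] == 0))

  noisy <- synthesize_voltage(no_spikes, tpl, noise_sd = 10,
                              recording_config(duration_s = 20, n_electrodes = 2),
                              seed = 9)
  sds <- apply(noisy$voltage, 1, sd)
  expect_true(all(abs(sds - 10) / 10 < 0.02))

  expect_error(synthesize_voltage(data.frame(electrode_id = 1, time_s = 2),
                                  tpl, 0, cfg), "beyond")
})

test_that("spine population generator matches its categorical law", {
  one_hot <- c(0, 0, 0, 0, 0, 1, 0, 0)
  p <- spine_sim_params(n_cells = 20, shape_probs = one_hot, seed = 2)
  pop <- generate_spine_population(p)
  expect_true(all(pop$shape_class == 6))
  expect_identical(pop, generate_spine_population(p))

  ## class-6 mass 0.22 recovered within 3 binomial SDs, Monte-Carlo pooled
  ## over 10 populations of ~10,000 spines each
  probs <- c(0.18, 0.14, 0.12, 0.08, 0.04, 0.22, 0.12, 0.10)
  pops <- lapply(1:10, function(s) {
    generate_spine_population(
      spine_sim_params(n_cells = 770, mean_spines_per_cell = 13,
                       shape_probs = probs, psd95_prob = 0.6, seed = s))
  })
  pop <- do.call(rbind, pops)
  expect_gt(nrow(pop), 90000)
  phat <- mean(pop$shape_class == 6)
  se <- sqrt(0.22 * 0.78 / nrow(pop))
  expect_lt(abs(phat - 0.22), 3 * se)
  se_psd <- sqrt(0.6 * 0.4 / nrow(pop))
  expect_lt(abs(mean(pop$psd95) - 0.6), 3 * se_psd)
})
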