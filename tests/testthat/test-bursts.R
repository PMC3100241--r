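test_that("burst definition boundaries are honoured", {
  bp <- burst_params()
  reg <- function(n, isi_s = 0.010, t0 = 0) t0 + (seq_len(n) - 1) * isi_s

  one <- detect_bursts(reg(20), bp)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_spikes, 20L)
  expect_equal(one$duration_ms, 190, tolerance = 1e-9)

  expect_equal(nrow(detect_bursts(reg(19), bp)), 0)

  ## an ISI of exactly 20 ms stays inside the burst (inclusive boundary)
  joined <- detect_bursts(c(reg(10), reg(10, t0 = 0.09 + 0.020)), bp)
  expect_equal(nrow(joined), 1)
  expect_equal(joined$n_spikes, 20L)

  ## 25 + 25 spikes split by a 30 ms gap -> two bursts, IBI 30 ms
  two <- detect_bursts(c(reg(25), reg(25, t0 = 0.24 + 0.030)), bp)
  expect_equal(two$n_spikes, c(25L, 25L))
  expect_equal(interburst_intervals(two), 30, tolerance = 1e-9)

  expect_error(detect_bursts(c(2, 1)), "sorted")
  expect_equal(nrow(detect_bursts(numeric(0))), 0)
})

test_that("detector equals the brute-force scanner on random trains", {
  set.seed(101)
  bp <- burst_params()
  for (i in 1:300) {
    times <- random_train(200)
    got <- as.data.frame(detect_bursts(times, bp))
    want <- brute_force_bursts(times)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$t_start_s, want$t_start_s)
      expect_equal(got$t_end_s, want$t_end_s)
      expect_equal(got$n_spikes, want$n_spikes)
    }
  }
})

test_that("bursts are maximal and satisfy the duration bound", {
  set.seed(55)
  bp <- burst_params()
  for (i in 1:50) {
    times <- random_train(200)
    bt <- detect_bursts(times, bp)
    if (nrow(bt) == 0) next
    expect_true(all(bt$duration_ms <= (bt$n_spikes - 1) * bp$max_isi_ms + 1e-9))
    for (j in seq_len(nrow(bt))) {
      before <- times[times < bt$t_start_s[j]]
      after <- times[times > bt$t_end_s[j]]
      if (length(before)) {
        expect_gt(bt$t_start_s[j] - max(before), bp$max_isi_ms / 1000)
      }
      if (length(after)) {
        expect_gt(min(after) - bt$t_end_s[j], bp$max_isi_ms / 1000)
      }
    }
    if (nrow(bt) > 1) {
      expect_true(all(interburst_intervals(bt) > bp$max_isi_ms))
    }
  }
})

test_that("metric table pools bursts and conserves spike counts", {
  expect_equal(nrow(burst_metric_table(detect_bursts(numeric(0)))), 0)

  one <- detect_bursts((seq_len(20) - 1) * 0.010)
  tab <- burst_metric_table(one)
  expect_equal(tab$duration_ms, 190, tolerance = 1e-9)
  expect_equal(tab$n_spikes, 20L)

  set.seed(77)
  for (i in 1:20) {
    times <- random_train(150)
    bt <- detect_bursts(times)
    tab <- burst_metric_table(bt)
    in_burst <- sum(tab$n_spikes)
    outside <- sum(vapply(times, function(t) {
      !any(t >= bt$t_start_s & t <= bt$t_end_s)
    }, TRUE))
    expect_equal(in_burst + outside, length(times))
  }
})

test_that("interburst intervals are end-to-start gaps in ms", {
  bp <- burst_params()
  mk <- function(starts, ends) {
    df <- data.frame(electrode_id = 1L, t_start_s = starts, t_end_s = ends,
                     n_spikes = 20L, duration_ms = (ends - starts) * 1000)
    burstnet:::burst_train(df, bp)
  }
  expect_equal(interburst_intervals(mk(c(0.5, 21), c(1, 21.2))), 20000)
  expect_equal(interburst_intervals(mk(0.5, 1)), numeric(0))
  three <- mk(c(0, 1.025, 21.3), c(1, 1.3, 21.5))
  expect_equal(interburst_intervals(three), c(25, 20000), tolerance = 1e-9)
})

test_that("motif grouping counts singletons, doublets and triplets", {
  bp <- burst_params()
  mk <- function(gaps_ms) {
    starts <- cumsum(c(0, 0.1 + gaps_ms / 1000))
    ends <- starts + 0.1
    df <- data.frame(electrode_id = 1L, t_start_s = starts, t_end_s = ends,
                     n_spikes = 20L, duration_ms = 100)
    burstnet:::burst_train(df, bp)
  }
  m <- label_motifs(mk(c(25, 20000)), bp)
  expect_equal(c(m$n_singletons, m$n_doublets, m$n_triplets), c(1, 1, 0))

  m <- label_motifs(mk(c(22, 24)), bp)
  expect_equal(c(m$n_singletons, m$n_doublets, m$n_triplets), c(0, 0, 1))

  m <- label_motifs(mk(c(20000, 20000)), bp)
  expect_equal(c(m$n_singletons, m$n_doublets, m$n_triplets), c(3, 0, 0))

  ## greedy split of longer chains: 4 -> triplet + singleton, 5 -> triplet + doublet
  m <- label_motifs(mk(c(25, 25, 25)), bp)
  expect_equal(c(m$n_singletons, m$n_doublets, m$n_triplets), c(1, 0, 1))
  m <- label_motifs(mk(c(25, 25, 25, 25)), bp)
  expect_equal(c(m$n_singletons, m$n_doublets, m$n_triplets), c(0, 1, 1))
})

test_that("pipeline recovery: detected bursts equal ground truth exactly", {
  for (seed in c(1, 9)) {
    sim <- generate_spike_trains(small_sim(seed))
    bt <- detect_bursts_all(sim$spikes)
    gt <- sim$ground_truth[order(sim$ground_truth$electrode_id,
                                 sim$ground_truth$t_start_s), ]
    expect_equal(nrow(bt), nrow(gt))
    expect_equal(bt$t_start_s, gt$t_start_s, tolerance = 1e-12)
    expect_equal(bt$t_end_s, gt$t_end_s, tolerance = 1e-12)
    expect_equal(bt$n_spikes, as.integer(gt$n_spikes))
  }
})
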