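mk_train <- function(durations, spikes = rep(25L, length(durations)),
                     electrode = 1L) {
  starts <- seq_along(durations) * 30
  df <- data.frame(electrode_id = rep_len(electrode, length(durations)),
                   t_start_s = starts,
                   t_end_s = starts + durations / 1000,
                   n_spikes = spikes, duration_ms = durations)
  burstnet:::burst_train(df, burst_params())
}

test_that("culture summary computes mean, SEM and active electrodes", {
  cs <- culture_summary(mk_train(c(100, 200)))
  expect_equal(cs$mean_duration_ms, 150)
  expect_equal(cs$sem_duration_ms, 50)   # SD 70.71 / sqrt(2)
  expect_equal(cs$n_bursts, 2)
  expect_equal(cs$n_active_electrodes, 1)

  empty <- culture_summary(mk_train(numeric(0)))
  expect_equal(empty$n_bursts, 0)
  expect_true(is.na(empty$mean_duration_ms))
  expect_equal(empty$n_active_electrodes, 0)

  ## windowing drops bursts starting outside the analysis window
  cs_win <- culture_summary(mk_train(c(100, 200, 300)), window_s = c(0, 70))
  expect_equal(cs_win$n_bursts, 2)
})

test_that("histograms conserve counts on linear and log scales", {
  h <- metric_histogram(c(10, 30), hist_spec("linear", bin_width = 20))
  expect_equal(h$counts, c(1, 1))
  expect_equal(sum(h$counts), 2)

  vals <- c(21, 25, 40, 90, 15000, 22000, 30000)
  hl <- metric_histogram(vals, hist_spec("log10", bins_per_decade = 10))
  expect_equal(sum(hl$counts), length(vals))
  expect_error(metric_histogram(c(-1, 5), hist_spec("log10")), "positive")

  cf <- cumulative_fraction(c(3, 1, 2, 2))
  expect_true(all(diff(cf$cum_fraction) >= 0))
  expect_equal(cf$cum_fraction[nrow(cf)], 1)
  expect_error(cumulative_fraction(numeric(0)), "at least one")
})

test_that("fraction_le counts inclusively", {
  expect_equal(fraction_le(c(100, 150, 250, 300), 200), 0.5)
  expect_equal(fraction_le(c(1, 2), 5), 1)
  expect_equal(fraction_le(c(10, 20), 5), 0)
  expect_equal(fraction_le(c(10, 20), 10), 0.5)   # boundary included
  expect_error(fraction_le(numeric(0), 1), "at least one")
})

test_that("one-way ANOVA matches the closed-form worked case", {
  gc <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  expect_equal(gc$F, 1.5, tolerance = 1e-12)
  expect_equal(gc$df_between, 1L)
  expect_equal(gc$df_within, 4L)
  expect_equal(gc$p, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  same <- one_way_anova(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "2 values")
})

test_that("ANOVA p agrees with a permutation oracle on random groups", {
  set.seed(13)
  for (i in 1:4) {
    groups <- lapply(seq_len(sample(2:3, 1)), function(g) {
      rnorm(sample(5:9, 1), mean = g * runif(1, 0, 0.8))
    })
    names(groups) <- paste0("g", seq_along(groups))
    p_f <- one_way_anova(groups)$p
    p_perm <- perm_anova_p(groups, n_perm = 10000)
    expect_lt(abs(p_f - p_perm), 0.02)
  }
})

test_that("condition comparison flags a real difference and not a null one", {
  mk_summary <- function(label, dur_mean, n = 1200, seed = 1) {
    set.seed(seed)
    culture_summary(mk_train(rgamma(n, shape = 4, scale = dur_mean / 4),
                             spikes = 20L + rnbinom(n, size = 2, mu = 28)),
                    condition_label = label)
  }
  a <- mk_summary("control", 182.5, seed = 2)
  b <- mk_summary("epha4", 211.2, seed = 3)
  rep2 <- compare_conditions(list(a, b))
  cmp <- rep2$duration_ms$omnibus
  expect_lt(cmp$p, 1e-4)
  expect_gt(cmp$means[["epha4"]], cmp$means[["control"]])

  expect_error(compare_conditions(list(a)), "at least 2")

  ## null calibration: identical generating parameters rarely "significant"
  ps <- vapply(1:40, function(s) {
    x <- mk_summary("x", 200, n = 300, seed = 100 + s)
    y <- mk_summary("y", 200, n = 300, seed = 500 + s)
    compare_conditions(list(x, y))$duration_ms$omnibus$p
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("SEM scales as 1/sqrt(n) under bootstrap resampling", {
  set.seed(19)
  durations <- rgamma(400, shape = 3, scale = 60)
  sem_at <- function(n) {
    mean(vapply(1:50, function(i) {
      culture_summary(mk_train(sample(durations, n, replace = TRUE)))$sem_duration_ms
    }, numeric(1)))
  }
  ratio <- sem_at(100) / sem_at(400)
  expect_lt(abs(ratio - 2), 0.3)
})

test_that("pooled log-IBI histogram of a motif-bearing culture is bimodal", {
  sim <- generate_spike_trains(small_sim(23, duration_s = 300, n_electrodes = 20,
                                         doublet = 0.3, triplet = 0.1))
  ibis <- pooled_ibis(detect_bursts_all(sim$spikes))
  h <- metric_histogram(ibis, hist_spec("log10", bins_per_decade = 8))
  cnt <- h$counts
  ## local maxima over the occupied range
  peaks <- which(cnt > c(cnt[-1], 0) & cnt >= c(0, cnt[-length(cnt)]) & cnt > 0)
  peak_pos <- h$mids[peaks]
  expect_true(any(peak_pos > 20 & peak_pos <= 100))
  ## long-interval mode within a factor of 2 of the configured 5 s median
  expect_true(any(peak_pos > 2500 & peak_pos < 10000))
})
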