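## Independent oracles and small fixture builders shared across tests.

## Brute-force burst scanner: walks the train spike by spike, growing a run
## while the next ISI stays at or below the ceiling, and emits every maximal
## run with enough spikes. Deliberately naive and independent of the
## vectorized detector.
brute_force_bursts <- function(times, min_spikes = 20, max_isi_ms = 20) {
  out <- data.frame(t_start_s = numeric(), t_end_s = numeric(),
                    n_spikes = integer())
  if (length(times) == 0) return(out)
  run_start <- 1
  for (i in seq_along(times)) {
    end_of_run <- i == length(times) ||
      (times[i + 1] - times[i]) > max_isi_ms / 1000
    if (end_of_run) {
      n <- i - run_start + 1
      if (n >= min_spikes) {
        out <- rbind(out, data.frame(t_start_s = times[run_start],
                                     t_end_s = times[i],
                                     n_spikes = as.integer(n)))
      }
      run_start <- i + 1
    }
  }
  out
}

## Random spike train alternating tight clusters (whose ISIs straddle the
## 20 ms boundary, and whose sizes straddle the 20-spike minimum) with loose
## inter-cluster gaps, so the oracle-equivalence property sees bursts,
## sub-threshold runs and boundary splits in every few trains.
random_train <- function(max_spikes = 200) {
  times <- numeric(0)
  t <- 0
  while (length(times) < max_spikes) {
    size <- sample(2:40, 1)
    size <- min(size, max_spikes - length(times))
    gaps <- c(runif(1, 0.025, 2), runif(size - 1, 0.0005, 0.0205))
    times <- c(times, t + cumsum(gaps))
    t <- times[length(times)]
    if (runif(1) < 0.1) break
  }
  times
}

## Permutation-test p-value for a one-way layout, using the F statistic.
## Independent of stats::lm/anova: F is recomputed from sums of squares.
perm_anova_p <- function(groups, n_perm = 10000) {
  f_stat <- function(value, grp) {
    gm <- mean(value)
    means <- tapply(value, grp, mean)
    ns <- tabulate(grp)
    ssb <- sum(ns * (means - gm)^2)
    ssw <- sum((value - means[grp])^2)
    dfb <- nlevels(grp) - 1
    dfw <- length(value) - nlevels(grp)
    (ssb / dfb) / (ssw / dfw)
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  f0 <- f_stat(value, grp)
  hits <- 0
  for (i in seq_len(n_perm)) {
    if (f_stat(value[sample.int(length(value))], grp) >= f0) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

## Fraction of times in `a` that have a time in `b` within tol seconds.
coverage_frac <- function(a, b, tol = 1e-3) {
  if (!length(a)) return(NA_real_)
  if (!length(b)) return(0)
  idx <- findInterval(a, b)
  lo <- pmax(idx, 1)
  hi <- pmin(idx + 1, length(b))
  mean(abs(b[lo] - a) <= tol | abs(b[hi] - a) <= tol)
}

## Small, fast simulation parameters for property tests.
small_sim <- function(seed, duration_s = 60, n_electrodes = 6,
                      doublet = 0.2, triplet = 0.1) {
  sim_params(condition_label = "test",
             duration_s = duration_s, n_electrodes = n_electrodes,
             long_ibi_median_s = 5, long_ibi_log_sd = 0.6,
             motif_prob_doublet = doublet, motif_prob_triplet = triplet,
             spikes_per_burst = spikes_per_burst_dist(mean = 45, size = 1.5),
             burst_duration = burst_duration_dist(mean_ms = 180, shape = 2),
             seed = seed)
}
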