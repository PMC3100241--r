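#' Culture-level burst summary
#'
#' Pools per-burst metrics across electrodes and summarizes them: mean and
#' SEM (sample SD / sqrt(n)) of burst duration and spikes per burst, the
#' number of active electrodes (electrodes with at least one detected burst
#' in the window), and the pooled interburst intervals. The individual burst
#' is the unit of analysis.
#'
#' @param bursts a pooled `burst_train` (from [detect_bursts_all()]) or a
#'   metric table from [burst_metric_table()]. IBIs are derived only when a
#'   `burst_train` is supplied.
#' @param condition_label,div condition tag and days in vitro, echoed into
#'   the summary.
#' @param n_electrodes total electrode count (for context; defaults to the
#'   number of distinct electrode ids seen).
#' @param window_s analysis window `(start, end)` in seconds; bursts starting
#'   outside it are dropped. `NULL` (default) keeps everything.
#' @return object of class `culture_summary`; with zero bursts the means and
#'   SEMs are `NA` and `n_bursts` is 0.
#' @export
culture_summary <- function(bursts, condition_label = "culture", div = NA,
                            n_electrodes = NULL, window_s = NULL) {
  is_train <- inherits(bursts, "burst_train")
  df <- as.data.frame(bursts)
  if (!is.null(window_s)) {
    stopifnot(length(window_s) == 2)
    if (!"t_start_s" %in% names(df)) {
      stop_param("windowing requires a burst_train with start times")
    }
    keep <- df$t_start_s >= window_s[1] & df$t_start_s <= window_s[2]
    df <- df[keep, , drop = FALSE]
  }
  ibis <- if (is_train) {
    pooled_ibis(burst_train(df, attr(bursts, "params")))
  } else {
    numeric(0)
  }
  n <- nrow(df)
  m_sem <- function(x) {
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    c(mean(x), stats::sd(x) / sqrt(length(x)))
  }
  dur <- m_sem(df$duration_ms)
  spb <- m_sem(df$n_spikes)
  structure(list(
    condition_label = condition_label, div = div,
    n_bursts = n,
    mean_duration_ms = dur[1], sem_duration_ms = dur[2],
    mean_spikes_per_burst = spb[1], sem_spikes_per_burst = spb[2],
    n_active_electrodes = length(unique(df$electrode_id[!is.na(df$electrode_id)])),
    n_electrodes = n_electrodes,
    ibi_values_ms = ibis,
    durations_ms = df$duration_ms,
    spikes_per_burst = df$n_spikes
  ), class = "culture_summary")
}

#' @export
print.culture_summary <- function(x, ...) {
  cat(sprintf("Culture summary: %s%s\n", x$condition_label,
              if (!is.na(x$div)) sprintf(" (%s DIV)", x$div) else ""))
  cat(sprintf("  %d bursts on %d active electrodes\n",
              x$n_bursts, x$n_active_electrodes))
  if (x$n_bursts > 0) {
    cat(sprintf("  burst duration: %.1f +/- %.1f ms (mean +/- SEM)\n",
                x$mean_duration_ms, x$sem_duration_ms))
    cat(sprintf("  spikes/burst:   %.2f +/- %.2f\n",
                x$mean_spikes_per_burst, x$sem_spikes_per_burst))
    if (length(x$ibi_values_ms)) {
      cat(sprintf("  %d IBIs, median %.0f ms\n",
                  length(x$ibi_values_ms), stats::median(x$ibi_values_ms)))
    }
  }
  invisible(x)
}

#' Histogram specification
#'
#' @param scale `"linear"` or `"log10"`.
#' @param bin_width bin width on a linear scale (ms or spikes).
#' @param bins_per_decade bins per decade on a log10 scale.
#' @param range optional `(low, high)` range; defaults to covering the data.
#' @return object of class `hist_spec`.
#' @export
hist_spec <- function(scale = c("linear", "log10"), bin_width = 25,
                      bins_per_decade = 10, range = NULL) {
  scale <- match.arg(scale)
  check_pos(bin_width, "bin_width")
  check_pos(bins_per_decade, "bins_per_decade")
  structure(list(scale = scale, bin_width = bin_width,
                 bins_per_decade = bins_per_decade, range = range),
            class = "hist_spec")
}

#' Histogram of burst metrics
#'
#' Bins values on a linear or log10 axis. Counts always sum to the number of
#' values.
#'
#' @param values numeric vector.
#' @param spec a [hist_spec()].
#' @return list with `breaks` (bin edges, original units), `counts`,
#'   `mids` (bin midpoints) and `spec`.
#' @export
metric_histogram <- function(values, spec = hist_spec()) {
  stopifnot(inherits(spec, "hist_spec"))
  if (spec$scale == "log10") {
    if (any(values <= 0)) stop_param("log-scale histogram requires positive values")
    x <- log10(values)
    w <- 1 / spec$bins_per_decade
  } else {
    x <- values
    w <- spec$bin_width
  }
  rng <- if (!is.null(spec$range)) {
    if (spec$scale == "log10") log10(spec$range) else spec$range
  } else if (length(x)) {
    range(x)
  } else {
    c(0, w)
  }
  lo <- floor(rng[1] / w) * w
  hi <- ceiling(rng[2] / w) * w
  if (hi <= lo) hi <- lo + w
  breaks <- seq(lo, hi + w / 2, by = w)
  counts <- if (length(x)) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = TRUE,
                        include.lowest = TRUE)
    h$counts
  } else {
    rep(0L, length(breaks) - 1L)
  }
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  if (spec$scale == "log10") {
    breaks <- 10^breaks
    mids <- 10^mids
  }
  list(breaks = breaks, counts = counts, mids = mids, spec = spec)
}

#' Empirical cumulative fraction curve
#'
#' @param values non-empty numeric vector.
#' @return data.frame `(value, cum_fraction)` on the sorted unique values;
#'   the curve is non-decreasing and reaches exactly 1 at the maximum.
#' @export
cumulative_fraction <- function(values) {
  if (!length(values)) stop_param("cumulative_fraction needs at least one value")
  v <- sort(unique(values))
  data.frame(value = v, cum_fraction = stats::ecdf(values)(v))
}

#' Fraction of values at or below a cutoff
#'
#' @param values non-empty numeric vector.
#' @param cutoff the cutoff (inclusive).
#' @return the proportion of values at or below the cutoff.
#' @export
fraction_le <- function(values, cutoff) {
  if (!length(values)) stop_param("fraction_le needs at least one value")
  mean(values <= cutoff)
}

#' One-way ANOVA between groups
#'
#' Fixed-effects one-way analysis of variance on >= 2 groups; F and p come
#' from the standard linear-model decomposition (via [stats::lm()]). When
#' there is neither between- nor within-group variance, F is reported as 0
#' with p = 1.
#'
#' @param groups named list of numeric vectors, each with >= 2 values.
#' @param metric label of the compared metric.
#' @return object of class `group_comparison` with fields `metric`, `labels`,
#'   `means`, `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups, metric = "value") {
  if (!is.list(groups) || length(groups) < 2) {
    stop_param("one_way_anova needs at least 2 groups")
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    stop_param("every group needs at least 2 values")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, 1L)),
                levels = names(groups))
  df_b <- length(groups) - 1L
  df_w <- length(value) - length(groups)
  if (stats::var(value) == 0) {
    f <- 0; p <- 1
  } else {
    tab <- stats::anova(stats::lm(value ~ grp))
    f <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    if (!is.finite(f)) { f <- 0; p <- 1 }
  }
  structure(list(metric = metric, labels = names(groups),
                 means = vapply(groups, mean, numeric(1)),
                 F = f, df_between = df_b, df_within = df_w, p = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s (%s)\n", x$metric,
              paste(sprintf("%s: %.3g", x$labels, x$means), collapse = ", ")))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Compare burst metrics across culture conditions
#'
#' Omnibus and pairwise one-way ANOVAs on the pooled per-burst values
#' (duration and spikes per burst) of two or more culture summaries.
#' P-values are reported raw, without multiple-testing correction.
#'
#' @param summaries list of [culture_summary()] objects (>= 2).
#' @return object of class `condition_report`: per metric, the omnibus
#'   `group_comparison` plus a list of pairwise comparisons.
#' @export
compare_conditions <- function(summaries) {
  if (!is.list(summaries) || length(summaries) < 2) {
    stop_param("compare_conditions needs at least 2 culture summaries")
  }
  stopifnot(all(vapply(summaries, inherits, TRUE, "culture_summary")))
  labels <- vapply(summaries, `[[`, "", "condition_label")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  metrics <- list(duration_ms = "durations_ms",
                  spikes_per_burst = "spikes_per_burst")
  report <- lapply(names(metrics), function(mname) {
    field <- metrics[[mname]]
    groups <- lapply(summaries, `[[`, field)
    names(groups) <- labels
    if (any(vapply(groups, length, 1L) < 2)) {
      stop_param("condition '%s' has fewer than 2 bursts for metric %s",
                 labels[which(vapply(groups, length, 1L) < 2)[1]], mname)
    }
    pairs <- utils::combn(seq_along(groups), 2, simplify = FALSE)
    pairwise <- lapply(pairs, function(ij) {
      one_way_anova(groups[ij], metric = mname)
    })
    names(pairwise) <- vapply(pairs, function(ij) {
      paste(labels[ij], collapse = " vs ")
    }, "")
    list(omnibus = one_way_anova(groups, metric = mname), pairwise = pairwise)
  })
  names(report) <- names(metrics)
  structure(report, class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  for (mname in names(x)) {
    cat(sprintf("== %s ==\n", mname))
    print(x[[mname]]$omnibus)
    for (nm in names(x[[mname]]$pairwise)) {
      pc <- x[[mname]]$pairwise[[nm]]
      cat(sprintf("  %s: F = %.4g, p = %.3g\n", nm, pc$F, pc$p))
    }
  }
  invisible(x)
}
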