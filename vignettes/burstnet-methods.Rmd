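---
title: "Methods: burst detection, synthetic cultures and spine maturity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst detection, synthetic cultures and spine maturity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstnet)
```

## The analysis problem

Dissociated cortical neurons cultured on a multi-electrode array (MEA)
develop spontaneous activity within the first week in vitro: long stretches
of near-silence punctuated by network bursts in which many electrodes fire
together at high rate. Three per-burst quantities summarize this behaviour —
burst duration, spikes per burst, and the interburst interval (IBI) — and
shifts in them track circuit maturation and perturbations such as
over-expression of the receptor tyrosine kinase EphA4 in a subset of
neurons. A parallel anatomical readout classifies dendritic spines on an
8-class morphology scale (classes 6–8 mature) and scores PSD-95
colocalization as a marker of functional excitatory synapses.

`burstnet` implements this analysis as a pipeline of small, separately
testable stages, plus a statistical generator of synthetic recordings so the
whole pipeline can be validated without any recorded data.

## Spike detection

Raw voltage (25 kHz, 60 electrodes on an 8 x 8 grid) is high-pass filtered
at 25 Hz with an order-2 Butterworth applied forward and backward
(`signal::filtfilt`). Zero-phase filtering matters because spike timestamps
feed ISI-based burst segmentation downstream; a causal filter would shift
them by a frequency-dependent lag.

Spikes are threshold crossings at `-k * sigma` with `k = 5`. `sigma` is
estimated per channel — the noise floor varies from electrode to electrode —
as the scaled median absolute deviation `median(|x - median(x)|)/0.6745`
rather than the plain SD: during network bursts a large fraction of samples
are spike waveform, which inflates the plain SD severalfold, whereas the MAD
tracks the noise floor (the tests demonstrate this with 1% contamination at
20 peak SDs: the plain SD doubles, the MAD moves by under 4%). The timestamp
is placed at the extremal sample within the dead-time window (1 ms) after
the crossing, which is stable across spike amplitudes; crossings within the
dead time of an emitted spike are suppressed, so emitted trains respect the
dead-time spacing by construction. Negative polarity is the default since
extracellular somatic spikes are dominantly negative-going. No spike sorting
is attempted: the analysis operates on multi-unit activity per electrode,
and channels with a zero noise estimate (dead electrodes) are reported as
undetectable rather than silently yielding empty trains.

## Burst detection

A burst is a maximal run of consecutive spikes with every ISI at or below
`max_isi_ms` (20 ms) containing at least `min_spikes` (20) spikes. Two
reading choices are deliberate:

- the ISI boundary is **inclusive** (an ISI of exactly 20 ms stays inside
  the burst), and the comparison carries a relative tolerance of 1e-9 so
  float round-off in time arithmetic cannot split a boundary ISI;
- the IBI is the **end-to-start** gap between consecutive bursts on the same
  electrode. Only this convention produces the observed short IBI mode just
  above the 20 ms ISI ceiling; start-to-start gaps would add the burst
  duration and move that mode to 200+ ms.

Burst duration is last spike minus first spike, with no padding, so
`duration_ms <= (n_spikes - 1) * max_isi_ms` is an invariant. Bursts are per
electrode; no cross-electrode network-burst merging is performed. Doublet
and triplet motifs — bursts separated by gaps just over the ISI ceiling —
are grouped greedily left-to-right with a configurable gap maximum
(default 50 ms); chains longer than three are counted as triplets plus a
remainder. The detector is validated against an independent brute-force
maximal-run scanner on randomized trains whose cluster sizes and ISIs
straddle both thresholds.

IBIs are pooled across electrodes before histogramming (the alternative,
per-electrode histograms, is not well determined at the typical 30–60 bursts
per electrode per 10 minutes).

## The synthetic culture generator

The generator is statistical, not biophysical: it reproduces the structure
the analysis assumes, with known ground truth, and makes no claim about
membrane or synaptic dynamics.

- **Event schedule.** Network burst events are separated by log-normal
  silences parameterized by their median (20 s at 7 DIV, 10 s at 14 DIV,
  matching the long IBI mode) and a log-scale SD. Events are shared across
  electrodes with Gaussian onset jitter (10 ms) — bursts in these cultures
  are grid-wide — with an independent per-electrode mode available.
- **Motifs.** With configurable probabilities an event is a doublet or
  triplet; member bursts are separated by gaps uniform on (22, 50) ms,
  i.e. just over the 20 ms ceiling, producing the short IBI mode.
- **Within a burst.** The burst duration `d` is drawn from a gamma
  distribution; the spike count is `n = max(20, ceil(d / 20 ms) + 1) + X`
  with `X` negative binomial. The duration-imposed floor guarantees
  `d <= (n - 1) * 20 ms`, so every generated burst is detectable by
  definition, and it couples spike count positively to duration, which is
  also the physiologically correct direction. The negative-binomial mean is
  calibrated by quadrature so the marginal spike-count mean equals its
  target exactly; drawing `(n, d)` independently and rejecting infeasible
  pairs — the obvious alternative — truncates the gamma tail and biased the
  recovered duration mean by about 6% in development, which is why it was
  abandoned. Spike placement draws `n - 1` exponential ISIs rescaled to span
  `d` exactly, rejecting any draw whose rescaled maximum exceeds the
  ceiling; because that rejection rarely accepts when the mean ISI
  approaches the ceiling, after 50 failed draws a bounded-jitter scheme
  (equal spacing plus zero-sum uniform jitter, scaled to keep every ISI
  strictly inside the ceiling) takes over. Both schemes span the drawn
  duration exactly, so the configured duration distribution is reproduced
  sample for sample.
- **Voltage.** For detector benchmarks, a deterministic biphasic template
  (1.5 ms, negative peak) is added to white Gaussian noise at each spike
  time. The default benchmark SNR places the template peak at 6 noise SDs,
  just above the 5 SD threshold, so detection is exercised nontrivially.
- **Spines.** Per-cell spine counts are Poisson (mean 13, truncated at 1),
  shape classes i.i.d. categorical over the 8 classes, PSD-95 flags i.i.d.
  Bernoulli.

Everything is driven by a single integer seed; identical parameters and seed
give bitwise-identical output, and the generator writes ground-truth burst
sidecars so recovery can be asserted exactly: on noiseless spike trains the
detector returns the true burst set spike for spike.

## Fixture calibration

The four built-in conditions encode the reported group means for this kind
of preparation:

| condition     | duration mean (ms) | spikes/burst | duration shape | long-IBI median |
|---------------|-------------------:|-------------:|---------------:|----------------:|
| control 7 DIV | 182.5              | 47.69        | calibrated to P(d <= 200 ms) = 0.65 | 20 s |
| EphA4 7 DIV   | 211.2              | 48.57        | calibrated to P(d <= 200 ms) = 0.53 | 20 s |
| control 14 DIV| 214.2              | 59.8         | 12 (near-symmetric) | 10 s |
| EphA4 14 DIV  | 248.9              | 73.2         | 4 (right-skewed)    | 10 s |

`calibrate_burst_duration_dist()` solves for the gamma shape whose CDF at
the cutoff matches the target fraction while the scale keeps the mean exact;
residuals are below 1e-6. Two numerical choices are documented here. First,
shapes are restricted to [0.01, 1e6]: as the shape tends to zero the gamma
degenerates into a spike at zero whose CDF at any positive point tends to 1,
a regime meaningless for burst durations; within the supported range, a
constraint such as "99% of mass below the mean" is correctly rejected as
infeasible. Second, when the cutoff sits slightly above the mean the
constraint admits two shape roots; the smaller, right-skewed root is
returned, matching the skewed duration histograms of immature cultures.

Quantities the source values do not pin down were fixed once as calibration
choices: the 14 DIV gamma shapes (from the qualitative histogram
descriptions: control near-normal, EphA4 right-tailed), negative-binomial
sizes (1.5 / 0.8 / 1.0 / 1.0 — geometric-like right tails, more dispersed
under EphA4 at 7 DIV), motif probabilities (doublet/triplet 0.15/0.05,
0.25/0.10, 0.10/0.03, 0.25/0.12 — higher first IBI peak under EphA4),
long-IBI log-SDs (0.8, 1.0, 0.5, 0.8 — broader long-IBI peak under EphA4),
and PSD-95 probabilities (0.50 control, 0.60 EphA4 — a modest increase, as
that contrast is reported as a trend without a test). The spine-class
fixtures set classes 6 and 7 to the reported per-class means (0.16/0.08
control, 0.22/0.12 EphA4) with class 8 taking the remainder of the mature
totals (0.30/0.44) and the immature mass spread over classes 1–5 with a mild
decreasing profile.

## Group statistics

For burst metrics the individual burst, pooled over electrodes, is the unit
of analysis (a 10-minute, 60-electrode culture yields thousands of bursts,
which is what makes the reported SEMs of a few ms plausible); for spine
metrics the cell is the unit, with per-cell proportions computed first.
Comparisons use fixed-effects one-way ANOVA via `stats::lm`; the tests check
F against the closed-form worked case (two groups of three values giving
F(1,4) = 1.5) and p against an independent 10,000-shuffle permutation
oracle. P-values are raw: no multiple-testing correction is applied, and the
report says so rather than hiding it. An electrode is "active" if it carries
at least one detected burst in the analysis window. SEM is the sample SD
divided by the square root of n throughout.

## What passing tests do and do not show

The generator emulates: silences with the right median and spread, grid-wide
synchronized bursts, motif structure, detector-consistent bursts with
configurable duration/spike-count laws, and spine populations with
condition-specific class distributions. It does **not** emulate electrode
crosstalk, slow drifts or artifacts, refractory structure below the ISI
ceiling (exponential ISIs admit sub-millisecond pairs, which the detector's
dead time merges — so voltage-level runs under-count spikes near the
20-spike floor and drop some marginal bursts), non-stationarity within a
recording, culture-to-culture variability (fixtures are single "cultures"),
or any dependence between spine class and PSD-95 state. Recovery of the
fixture means therefore validates the pipeline's arithmetic and the
generator/detector contract, not the biology of any particular culture.

## Problem sizes and numerical choices

The default fixtures are full-scale (600 s, 60 electrodes; 75 cells per
spine condition — 25 cells per experiment over three experiments). Unit and
property tests run on reduced sizes (tens of seconds, a handful of
electrodes) chosen so each property still has power; the detector benchmark
uses 60 s x 8 channels at 25 kHz. Histogram defaults: 25 ms bins for
duration, 10-spike bins for spike counts, 10 bins per decade (log10) for
IBIs — the figure binnings are not stated, so these are package choices.
Voltage is stored as float64 channel-major binary with a JSON metadata
sidecar; times are kept in seconds as doubles internally and reported in ms
where convention expects ms.

## Known limitations

- Bursts are strictly per-electrode; network-burst definitions that merge
  across electrodes are out of scope.
- No alternative burst detectors (surprise-based, log-ISI valley) are
  provided; the fixed-threshold definition is the point of comparison.
- The threshold detector does not adapt over time and performs no artifact
  blanking; recordings with large artifacts need upstream cleaning.
- ANOVA treats bursts (or cells) as independent; electrode- or
  culture-level nesting is not modelled.
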