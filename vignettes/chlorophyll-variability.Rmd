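---
title: "Decomposing chlorophyll variability and finding bloom drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing chlorophyll variability and finding bloom drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorovar)
```

`chlorovar` implements an analysis chain for chlorophyll-*a* dynamics in
shallow, long-residence-time estuaries, where biomass accumulates in place
and blooms can rise and collapse within days. This vignette explains the
models and procedures, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate.

## The multiplicative decomposition

A monthly grab-sample series is arranged into a year × month matrix
$c_{ij}$ (µg·L⁻¹) by `build_monthly_matrix()`; months with several samples
contribute their mean, skipped months stay missing, and non-positive
chlorophyll is rejected because a multiplicative model is undefined at
zero. `fit_decomposition()` then writes

$$c_{ij} = \bar{C}\, y_i\, m_j\, \varepsilon_{ij}$$

with the grand mean $\bar{C}$ over observed cells, annual coefficients
$y_i$ (year mean / grand mean), and monthly coefficients $m_j$ estimated as
the across-year mean of $c_{ij}/(\bar{C} y_i)$ at observed cells. Two
normalisation conventions were open:

* which coefficient set absorbs the leftover scale when data are
  unbalanced, and
* whether residuals or the annual coefficients compensate for
  renormalising $m_j$.

We normalise **both** $y$ and $m$ to unit mean over their observed entries
and let the residuals absorb any imbalance. This makes the three component
sets dimensionless and mutually comparable, keeps the reconstruction
identity $\bar{C} y_i m_j \varepsilon_{ij} = c_{ij}$ exact at every
observed cell (tested to 1e-10 relative), and is exact on noiseless
balanced data. Missing cells are skipped in every mean; imputation was
rejected because a typical multi-year program has only a handful of gaps
and imputing them would leak the seasonal model into the residual
component. Standard deviations are sample (n−1) SDs throughout — the
number of years is small, typically five.

The SDs of $\{y_i\}$, $\{m_j\}$ and $\{\varepsilon_{ij}\}$ partition
variability by timescale (interannual, seasonal, sub-monthly);
`variability_partition()` ranks them, descending, with stable ties. In
systems of this type the residual (event-scale) component typically ranks
first; the package reports raw SDs and ranks rather than percentages,
since a percentage normalisation of dimensionless component SDs has no
single natural definition.

Decomposition is done on the raw scale, not log-transformed: the model is
already multiplicative, and the component coefficients are ratios whose
SDs are the quantities of interest.

## Sonde QC: 15 minutes to daily

`fill_gaps_linear()` interpolates internal gaps on the 15-minute grid;
leading and trailing gaps are never extrapolated. `daily_average()` applies
the omission rule *on the raw record, per variable, per day*: a day is
dropped when its longest run of consecutive missing 15-minute points
strictly exceeds `qc_max_gap` (default 60 min), so a 4-point (60-min) run
is retained and filled while a 5-point (75-min) run omits the day. Boundary
choices:

* a missing run spanning midnight counts toward each day only the portion
  inside that day's 24-hour window;
* partial days at deployment boundaries are kept only when the day's grid
  covers at least 23 hours (92 of 96 slots), avoiding biased partial-day
  means;
* whether the rule applies per variable or to the whole record is not
  fixed by convention; we apply it per variable, so a failed conductivity
  sensor does not discard a valid chlorophyll day.

For gap-free days the daily value is exactly the plain mean of the 96
points (property-tested), so the QC step is transparent where no QC was
needed.

## Bloom detection

`detect_rises()` enumerates every ordered pair of observed days at most
`bloom_window − 1` = 3 calendar days apart and keeps pairs whose rise is at
least `bloom_delta` = 50 µg·L⁻¹ — with a default grand mean near 45 µg·L⁻¹
this is roughly a doubling of the mean. The threshold is inclusive (a rise
of exactly 50 triggers); the boundary had to be fixed somewhere and
"increases of 50" reads naturally as inclusive. Because *all* ordered pairs
within the span are enumerated, the endpoint-to-endpoint and
min-to-max-within-window readings of the criterion coincide — the
(argmin, argmax) pair is itself enumerated — so no configuration switch
distinguishes them. Pairs may bridge omitted days; both endpoints must be
observed.

`merge_events()` clusters triggers by single linkage on end dates with gap
≤ `merge_window` = 14 days. Day 0 of an event is its maximum observed
chlorophyll (ties broken earliest) over the cluster span extended by the
context window, and the analysis window is ±14 days trimmed to the record
("up to 14 days"). Clustering trigger end-dates can still leave two merged
events with peaks within 14 days of each other, which would violate the
separation the merge rule intends, so a consolidation pass re-merges until
all peaks are more than `merge_window` apart; this also makes merging
idempotent. The detector is tested for exact equivalence against a
brute-force pair enumeration on over a hundred random gapped series.

## Driver-model selection

`build_event_frame()` fixes the complete-case rows once per event, so all
candidate models share identical data — a requirement for AICc
comparability. Events whose meteorology does not cover the window (plus the
lag day) completely are flagged not-analyzable rather than fitted on
partial forcing; this is the coverage filter that decides which detected
events can be modelled at all. Zero-variance candidates (rain in a
rain-free window) are dropped with a message.

Candidates are average wind speed, its one-day lag, maximum sustained wind
speed, temperature and rain. Only the one-day lag is screened
(`ccf_screen()`): the lag-1 Pearson cross-correlation (predictor leading)
must reach `1.96/√n`, the approximate white-noise bound, with `n` the
number of lag-1 pairs; the multiplier is configurable. The screen holds its
nominal ~5% level on white noise (tested over 1,000 seeds).

`prune_collinear()` repeatedly resolves the highest-correlated pair at
|r| ≥ 0.7 by keeping the member more correlated with the response, with
deterministic tie-breaks. The 0.7 threshold is an explicit package choice —
collinearity removal needs *some* threshold, and 0.7 is the common rule of
thumb at which coefficient signs start becoming unstable in frames of this
size (n ≈ 29). Note one practical consequence, visible in the synthetic
recovery experiments: average and maximum daily wind are near-collinear
twins (r ≈ 0.97 in the generator, similar in real records), so when wind
forces chlorophyll contemporaneously the pipeline reliably selects *a*
positively-signed wind term but the twin identity is a coin toss. With
lagged forcing the lag-1 term has no twin and is recovered specifically
(> 80% of 200 replicates, and preferred over contemporaneous wind).

`enumerate_models()` fits all $2^p$ additive subsets by OLS and ranks by
AICc with $k$ = slopes + intercept + residual variance; the correction term
depends on $k$, so the convention matters and is fixed package-wide.
`backward_eliminate()` starts from the AICc-best subset — simplification
follows comparison, not the full model — and removes the largest-p term
until all terms satisfy p ≤ α = 0.05, reporting the final model's
per-term coefficients and p-values, adjusted r², overall F-test p (the
interpretation used for the "model p value"), AICc and n. If nothing
survives, the intercept-only model is returned flagged, never silently.
Enumeration, AICc arithmetic and elimination are each verified against
naive normal-equations re-implementations on random frames.

## Sampling-frequency simulation

`partition_blocks()` splits an n-day record into contiguous blocks whose
lengths differ by at most one (171 days → quarters 43/43/43/42, months
3×15 + 9×14); extra days go to the earliest blocks, a deterministic choice
since only the multiset of lengths is dictated by the arithmetic.
`simulate_sampling()` draws one uniform day per block per simulation
(default `n_sims` = 1000), with a counter-derived random substream per
simulation so results are independent of execution order, and reports
per-simulation annual mean/min/max plus their across-simulation averages
next to the raw statistics. By construction every per-simulation min/max is
bounded by the raw record (asserted). `frequency_report()` derives the
policy-relevant numbers: how much of the true maximum reduced sampling
misses (absolute and percent) and how much it overstates the minimum;
`subsampling_summary()` lets already-published summary statistics flow
through the same report.

## The synthetic generator

`synthetic_truth()` fixes the emulated system once: grand mean 45 µg·L⁻¹;
annual factors (1.40, 1.12, 1.00, 0.88, 0.60) — a monotone interannual
decline with SD ≈ 0.30; a seasonal sinusoid of amplitude 0.285 peaking
June–July with SD ≈ 0.21; mean-one lognormal residual noise with σ = 0.35,
placing the residual SD near the upper-0.3s regime typical of event-driven
estuaries; AR(1) wind (φ = 0.6, innovation SD 1.5 m·s⁻¹) around a seasonal
mean of ~6 m·s⁻¹ with maximum sustained wind ≈ 1.7× the average;
Bernoulli(0.15)–Gamma(0.8, 12) rain; a 10–30 °C temperature sinusoid; and
salinity around 30 with slow evaporative rise and sharp rain-driven drops,
clamped to 5–45. Bloom kernels are triangular (2-day rise, 2-day fall),
emulating ephemeral spikes lasting only a few days, with peak amplitude
120 µg·L⁻¹; wind-driven kernels fire where the (optionally one-day-lagged)
average wind exceeds its monthly-climatology 90th percentile, at least 30
days apart. Every planted bloom is written to a ledger (peak date,
amplitude, duration, driver, lag), the ground truth for recovery tests.

What the generator does *not* emulate: nutrient dynamics, grazing,
advection and flushing, sensor drift or fouling, autocorrelated residual
noise, and bloom decline asymmetries. Passing recovery tests therefore
demonstrates the *statistical machinery* — that the decomposition recovers
known factors, the detector finds planted spikes, the model selection
recovers a known forcing — not that the defaults describe any particular
estuary.

Problem sizes used in the shipped tests and acceptance script — 5-year
monthly programs, 30-year decomposition Monte Carlo over 200 seeds, 200
driver-recovery replicates of 29-day windows, 1,000-simulation frequency
comparisons — were chosen so each recovery check has enough replication for
3-standard-error comparisons while a full run stays interactive.

## Numerical notes and limitations

* Timestamps are naive local time; daily aggregation ignores
  daylight-saving arithmetic, appropriate for local-day averaging.
* Missing is `NA` everywhere; zero is a legal measurement and never means
  missing. CSV round-trips preserve both at full precision.
* Validation errors are typed conditions (`chlorovar_parse_error`,
  `chlorovar_validation_error`, `chlorovar_config_error`); malformed input
  never drops rows silently.
* `aicc()` is undefined at `n − k − 1 < 1`; such subsets are skipped, so on
  very short windows large models are simply never considered.
* The per-event OLS assumes independent residuals; daily series within an
  event window are autocorrelated, so reported p-values are
  anti-conservative in the usual way of this analysis family. Mixed or
  autocorrelation-robust models are out of scope.
* Events at record edges get truncated windows ("up to 14 days"), so their
  n can be far below 29; the `n − k − 1` guard, not a hard minimum n,
  decides estimability.
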