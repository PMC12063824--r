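# chlorovar

Timescales and drivers of chlorophyll-*a* variability from estuarine
monitoring data.

Long-residence-time, low-inflow estuaries (e.g. wind-dominated hypersaline
lagoons) accumulate phytoplankton biomass in place, so chlorophyll there can
swing by hundreds of µg·L⁻¹ within days — far faster than the monthly or
quarterly grab-sample programs most agencies run. `chlorovar` packages the
analysis chain needed to quantify that mismatch from two common data sources:
a multi-year monthly monitoring series and high-frequency (15-minute) sonde
deployments. It is aimed at aquatic ecologists and monitoring-program
designers.

## What it computes

**Timescale decomposition.** A monthly chlorophyll series arranged as a
year × month matrix `c_ij` is decomposed multiplicatively:

    c_ij = C̄ · y_i · m_j · ε_ij

with grand mean `C̄`, dimensionless annual coefficients `y_i`, seasonal
(monthly) coefficients `m_j` (both normalised to unit mean) and sub-monthly
residuals `ε_ij`. The sample standard deviations of `{y_i}`, `{m_j}` and
`{ε_ij}` partition variability by timescale; ranking them shows whether
event-scale (sub-monthly) variability dominates the seasonal and interannual
signals.

**Sonde QC.** 15-minute records are converted to daily averages to remove
diel signatures: internal gaps are linearly interpolated, and a day is
omitted when more than one consecutive hour of raw data is missing within
that 24-hour window (a 60-minute run passes, a 75-minute run does not).

**Bloom detection.** A bloom trigger is a chlorophyll rise of at least
δ = 50 µg·L⁻¹ between two observed days at most 3 days apart (a 4-day
inclusive span). Triggers within 14 days are merged into one event; day 0 is
the event's chlorophyll maximum and the analysis window extends up to 14
days either side.

**Driver models.** For each event, additive linear models of daily
chlorophyll on average wind speed, one-day-lagged average wind speed
(admitted only if the lag-1 cross-correlation clears the white-noise bound
1.96/√n), maximum sustained wind speed, temperature and rain are enumerated
over all subsets, ranked by AICc

    AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n − k − 1),   k = terms + 2,

after pruning collinear candidates (pairwise |r| ≥ 0.7, keeping the member
more correlated with chlorophyll), and the AICc-best subset is backward-
eliminated to an all-significant model (α = 0.05).

**Sampling-frequency simulation.** A daily record treated as one "year" is
partitioned into 4 (quarterly) or 12 (monthly) contiguous near-equal blocks;
1,000 seeded simulations draw one random day per block, and the
across-simulation average annual mean/min/max are compared with the raw
record to quantify what reduced sampling misses.

A seed-deterministic synthetic-data generator (`synthetic_truth()`,
`generate_met()`, `generate_daily_chl()`, `generate_15min()`,
`generate_monthly_program()`) emulates all of these structures with a
ground-truth ledger, so every stage is testable against known answers.

## Worked example

```r
library(chlorovar)

sc <- generate_scenario("default", years = 2, seed = 7)   # synthetic estuary
fit <- fit_decomposition(build_monthly_matrix(sc$monthly))
fit
#> <chl_decomposition> grand mean 62.23 ug/L, 2 years
#>   component SDs: annual 0.133, seasonal 0.569, residual 0.310
#>   annual coefficients:
#>  2015  2016
#> 0.906 1.094

events <- detect_blooms(sc$daily)
nrow(events)          # 15 merged events against 16 planted blooms
#> [1] 15

sim <- simulate_bloom_event(seed = 5, lag = 1)   # wind drives chl with 1-day lag
fit_event_drivers(sim$event, sim$daily, sim$met)
#> <driver_model_fit> n = 29, adj r2 = 0.59, model p = 6.58e-07, AICc = 169.4
#>   wind_avg_lag1       9.874  (p = 6.58e-07)
```

The decomposition print shows the grand mean (µg·L⁻¹) and the dimensionless
per-timescale standard deviations; here sub-monthly samples land on bloom
spikes, so the seasonal and residual components carry most of the
variability. The driver fit recovers the planted one-day-lagged wind term
(true coefficient 10) as the only significant model term.

Quantifying what coarse sampling loses, given a record's raw and simulated
summary statistics:

```r
q <- subsampling_summary("quarterly", avg_mean = 69.0, avg_min = 24.9,
                         avg_max = 174.6, raw_mean = 69.7, raw_min = 8.2,
                         raw_max = 305.6)
frequency_report(list(q))[c("max_deficit", "min_excess", "pct_reduction_max")]
#>   max_deficit min_excess pct_reduction_max
#> 1         131       16.7          42.86649
```

Quarterly sampling of this record misses 131 µg·L⁻¹ (43%) of the true
maximum and overstates the minimum by ~17 µg·L⁻¹.

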