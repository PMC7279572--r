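# rollscr

Rolling-window spatially explicit capture–recapture (SCR) density
estimation for camera-trap surveys of low-density, wide-ranging carnivores.

Short ("snap-shot") camera surveys of animals like jaguars typically detect
few individuals, and the resulting SCR density estimates can swing with the
idiosyncrasies of who happened to range where during the survey window.
`rollscr` is built around the diagnostic that exposes this: keep the
cameras running for a year, then estimate density for *every* contiguous
90-day (and 180-day) block, shifted one day at a time — 276 and 186
sessions from a 365-day record. A flat series means robust snap-shots; an
oscillating series means any single short survey should be interpreted with
care. The package provides the estimator, the rolling machinery, a
synthetic-data generator for the whole pipeline, GPS home-range (100%
minimum convex polygon) tools with the circular σ↔area transform, and the
correlation/regression summaries used to attribute variation in the density
series to the detection process and demographic structure.

## The model

Each individual has a latent activity centre $s$; a camera at distance $d$
detects it on a given day with half-normal probability
$p(d) = g_0 \exp(-d^2/2\sigma^2)$. Centres follow a homogeneous Poisson
process with density $D$ (animals/km²), integrated over a habitat mask
(trap bounding box + buffer, discretized at `spacing`). With collapsed
counts $n_{ik}$ over $T$ daily occasions, the full likelihood with
Poisson-distributed detected count $n$ is

$$\log L = \sum_i \log\Big(Da\sum_m \Pr(\omega_i|s_m)\Big) - Da\sum_m p_\cdot(s_m),
\qquad \Pr(\omega_i|s)=\prod_k p_k(s)^{n_{ik}}(1-p_k(s))^{T-n_{ik}},$$

maximized over $(\log D, \operatorname{logit} g_0, \log\sigma)$ with Wald
CIs back-transformed from the link scale. The likelihood and its analytic
gradient are implemented in C++ (RcppArmadillo) and verified in the test
suite against an independent brute-force implementation.

## Worked example

Simulate a year-long 20-station trail survey with seasonally modulated
ranging behaviour, fit one 90-day session, then the full rolling series:

```r
library(rollscr)

sc  <- scenario_jaguar(modulation_amplitude = 0.3, seed = 19)
pop <- simulate_population(sc$scenario, sc$traps)
rec <- simulate_detections(pop, sc$traps, sc$scenario)

fit <- fit_scr(collapse_histories(rec, c(1, 90), "male"), sc$traps,
               build_mask(sc$traps, buffer = 15000, spacing = 1000))
fit
#> SCR fit (half-normal, full likelihood): 7 individuals, 20 detectors, 90 occasions
#>               estimate    lo95    hi95
#> D (/100 km^2)  0.83910 0.34540 2.03800
#> g0 (/day)      0.06579 0.04393 0.09744
#> sigma (km)     4.51700 3.37000 6.05500
#> logLik: -623.7837 ( log(n!) dropped )  converged

ser90  <- batch_fit(rec, sc$traps, L = 90,  buffer = 15000, spacing = 2000)
ser180 <- batch_fit(rec, sc$traps, L = 180, buffer = 15000, spacing = 2000)
ser90
#> Session series: 276 windows of 90 days (step 1 ) over 365 days; male density
#>   fitted: 276/276; D per 100 km^2: mean 1.30, range 0.74-1.81
ser180
#> Session series: 186 windows of 180 days (step 1 ) over 365 days; male density
#>   fitted: 186/186; D per 100 km^2: mean 1.24, range 1.03-1.70
```

True male density here is 2.0/100 km² and constant all year — the sweep of
the 90-day series (0.74–1.81) is temporal-sampling artefact, and the
180-day series is visibly tighter (SD 0.16 vs 0.20 per 100 km²). This
realization drew a sparse population (7 males in the first window), so the
point estimates sit low while every 95% CI covers the truth. Session
precision and what drives the series:

```r
ps <- precision_summary(ser90)
#> mean 95% CI width: 2.46 (range 1.32-3.85) per 100 km^2

association_table(ser90, list(c("sigma", "D"), c("det_male", "g0")))
#>          x  y   n pearson_r  p_value linear_r2 quadratic_r2
#> 1    sigma  D 276    -0.674 5.69e-38    0.4548        0.456
#> 2 det_male g0 276     0.280 2.33e-06    0.0783        0.344
```

The strong negative density–σ association is the signature phenomenon:
with the same animals present, sessions where the detected individuals
ranged wider yield lower density estimates. Comparing σ with telemetry:

```r
tr <- simulate_track(c(3000, 4000), "M1", n_days = 348, fixes_per_day = 4,
                     sigma_move = 2400, seed = 19)
mcp_area(tr)
#> 100% MCP (M1) : 182.9 km^2 from 1392 fixes
round(sigma_from_area(mcp_area(tr)$area_km2), 1)
#> 3.1  # km — the sigma a circular range of that area implies
```

`rolling_mcp()` gives the shifting 90-day MCP series for a track, and
`max_station_distances()` ranks individuals by their widest between-station
movement. File I/O (`read_traps`/`read_captures`/`read_tracks`/
`write_results`) uses plain CSV with documented headers; same-day repeat
photographs of an individual at one station are deduplicated on ingest.

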