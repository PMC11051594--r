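# whistlecee

Multi-scale analysis of group-level dolphin whistle production during
controlled exposure experiments (CEEs) with simulated mid-frequency active
sonar (MFAS), recorded by networks of drifting acoustic buoys.

## The problem

Oceanic dolphins whistle constantly and switch vocal state rapidly — about
once per minute under undisturbed conditions — so a sonar response can hide
inside natural variability, and whether it is detectable at all depends on
the analysis time window.  `whistlecee` measures responses at three nested
scales from per-second whistle-detection counts, for experiments with a
10-min pre-exposure / 10-min exposure (24 pings of 1.6 s every 25 s) /
10-min post-exposure design:

* **10-min**: `periodDiff = |median(exposure) − median(pre)|`, modeled with
  a negative-binomial GLMM,
  `periodDiff ~ ceeType + subSpecies + groupSize + buoyDist`;
* **20-s / 5-s**: per-ping `pingChange = mean(after window) − mean(before
  window)`, modeled as a zero-inflated Gaussian — an exact zero with
  probability π (logit-linear in the baseline median whistle count
  `medWhist`), Gaussian otherwise — with AR(1) correlation `phi^|Δt|`
  between non-zero observations of successive pings at the 5-s scale;
* **changepoints**: binary segmentation on 5-s-smoothed counts detects
  vocal state changes in mean and variance; per-CEE `|pre − exposure|`
  changepoint counts are compared between controls and exposures with a
  pooled t test.

Upstream of the statistics the package handles the field realities: buoy
selection by haversine distance with a 1.6-km exclusion mask at 1-min
resolution, removal of detections overlapping annotated sonar harmonics,
and start-bin per-second counting.  A synthetic-data generator
(`simulate_cee()`, `simulate_study()`) produces whole experiments with
known ground truth — Markov vocal-state switching, Poisson whistle trains,
drifting-buoy geometry, and ping-triggered response bursts that abate
within ~10 s — so every stage is verifiable without field data.

## Worked example

```r
library(whistlecee)

cee <- simulate_cee(sim_config(cee_type = "mfas", seed = 42, cee_id = "demo"))
an  <- analyze_cee(cee)

an$count_series
#> <count_series demo: 1800 s, 4610 whistles, 300 s masked>
an$summary$overall
#>      n     mean       sd median iqr
#> 1 1500 3.073333 3.394452      2   3
an$cpt_mean
#> <cpt_result (mean): 65 changepoint(s) in 1502 analyzed s>
an$first_ping
#> first-ping fold change 3.10 (before 20, after 62)
```

Five minutes of this experiment were masked because the closest buoy
drifted beyond 1.6 km; the summary statistics use the remaining 1500
seconds.  The simulated 4-fold post-ping burst shows up directly in the
first-ping fold change (3.1× more whistles in the 5 s after the first ping
than in the 5 s before).

Study-level statistics from the bundled campaign summary (19 CEEs, 9
controls and 10 sonar exposures):

```r
tab <- load_cee_summary()
changepoint_delta_ttest(tab, "mean")
#> Pooled t test: t(17) = 0.497, p = 0.626
#>   group 1: mean 11.333, sd 14.195, n 9     (controls)
#>   group 2: mean 8.700, sd 8.512, n 10      (sonar exposures)
```

Controls and exposures do not differ in how much their changepoint counts
shift between the pre-exposure and exposure periods — state switching is
that volatile at baseline.  The detectable response lives at the 5-s
scale: `run_power_sim(response_fold = 4)` fits the three models on seeded
synthetic studies and shows the experiment-type effect at the 5-s scale
while the 10-min scale stays null.

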