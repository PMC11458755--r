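# gevitrain

Analysis and simulation of synaptically evoked cortical depolarizations
in wide-field voltage imaging (GEVI/VSFP) movies.

## What this package is for

Wide-field imaging of a genetically encoded voltage indicator turns a
cortical brain slice into an 80 × 80 pixel voltmeter sampled at ~1 kHz
(1.020 ms full-frame interval). Extracellular stimulation in layer 4
evokes compound depolarizations recorded simultaneously at three
regions of interest — ROI-1 at the stimulation site (L4), ROI-2 above
it in L2/3 of the same column, ROI-3 in L2/3 of the adjacent column —
under a paradigm of one conditioning pulse followed by a 10-pulse train
at 20, 40 or 83 Hz (interstimulus intervals 50, 25, 12 ms).

`gevitrain` implements the full quantification pipeline for such
recordings, for experimentalists who have the movies and for
methodologists who want a testbed:

* **Trace extraction** — ΔF/F with polarity inversion (raw GEVI signals
  are negative-going with depolarization), spatial averaging over
  fixed-size ROI apertures (57 px / 37 px), sweep averaging (n = 4),
  exponential photobleach correction, and two branch-specific filter
  chains: 33 Hz Gaussian low-pass (temporal-summation branch, no
  high-pass) or 77 Hz Gaussian low-pass + 0.1 Hz RC high-pass
  (spatial-propagation branch).
* **Metrics** — stimulus-locked per-pulse peak detection;
  **summation efficacy** `P2/P1` (second/first peak amplitude, measured
  from the pre-train baseline, within one trial; > 1 means temporal
  summation of compound EPSPs); **Max Peak** (largest depolarization
  during the train); **propagation efficacy** (amplitude ratios
  ROI 2/1, 3/2, 3/1 within one trial); frame-subtraction voltage maps;
  the stimulus intensity–response curve with polynomial trendline and
  plateau selection.
* **Group statistics** — mean ± SEM summaries, one-way ANOVA, Tukey HSD
  (Tukey–Kramer for unequal n) and the four-level significance-star
  notation.
* **A forward-model simulator** — movies with exponential bleaching,
  shot noise, a non-facilitating fast component confined to the
  stimulation site, facilitating synaptic responses with per-pulse
  weights, trial-to-trial EPSP failures and onset jitter, and known
  ground truth for every derived metric, so each pipeline stage has a
  known-answer test.

Everything is data-frame-first: per-slice metrics arrive as tibbles
that pipe straight into `dplyr`, and result objects have `tidy()` /
`glance()` / `autoplot()` methods.

## Worked example

Simulate one slice at a reduced 40 × 40 px geometry, extract the three
ROI traces through the propagation branch, and compute the metrics:

```r
library(gevitrain)

cfg      <- sim_config(h = 40, w = 40, pixel_size_um = 25, stim_site = c(30, 8))
protocol <- train_paradigm(40)                 # stim 1 + 10-pulse train, 40 Hz
sim      <- simulate_movie(cfg, protocol, seed = 1)

rois   <- default_rois(cfg, 37)
traces <- preprocess_all_rois(sim$sweeps, rois, protocol, "propagation")
traces[["1"]]
#> <gevi_trace> 1153 samples @ 1.020 ms (1176.1 ms)
#>   provenance: dff(invert) -> spatial_avg(px=37) -> sweep_avg(n=4) ->
#>               bleach_correct -> gauss_lp(77) -> rc_hp(0.1)

resp <- lapply(traces, detect_train_peaks, protocol = protocol)
resp[["1"]]
#> <train_response> 10 pulse(s) @ 40 Hz, 10 resolved
#>   P1 = 0.00772, max peak = 0.02428 (baseline sd 0.00019)

propagation_efficacy(resp[["3"]], resp[["2"]])   # recovered ROI 3/2
#> [1] 0.648
sim$truth$table$roi3_over_roi2                   # model truth
#> [1] 0.635
```

The trace provenance lists every stage applied, in order. The recovered
horizontal propagation ratio (0.648) sits within ~2% of the model's
ground truth. P2/P1 comes from the summation branch (57-px apertures,
33 Hz low-pass) the same way via `summation_efficacy()`.

A small two-group cohort, processed end to end:

```r
co  <- simulate_cohort(n_slices = c(AD_F = 4, CTRL_F = 4), frequencies = 40,
                       config = cfg, seed = 2)
eff <- process_cohort(co, "propagation")
summarize_groups(eff[eff$roi == 3, ], roi3_over_roi2, group)
#> # A tibble: 2 × 5
#>   group     n n_invalid  mean     sem
#> 1 AD        4         0 0.491 0.00768
#> 2 CTRL      4         0 0.687 0.0231
```

The AD condition (shorter trans-columnar space constant, 340 vs 600 µm)
shows the weaker trans-columnar propagation the pipeline is built to
resolve: signal reaching the adjacent column is ~50% of the same-column
amplitude in AD versus ~60–70% in CTRL. `one_way_anova()`,
`tukey_hsd()` and `compare_conditions()` take such tables to the
statistical results, and `run_pipeline()` chains all stages from a YAML
or list config (a thin CLI wrapper lives in
`inst/scripts/gevitrain.R`).

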