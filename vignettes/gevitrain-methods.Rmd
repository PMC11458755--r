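---
title: "Quantifying evoked cortical depolarizations in wide-field voltage imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying evoked cortical depolarizations in wide-field voltage imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gevitrain)
library(dplyr)
```

## The measurement problem

Wide-field imaging with a genetically encoded voltage indicator (GEVI,
VSFP class) reports the population membrane potential of a cortical
slice as a fluorescence movie: here an 80 × 80 pixel sensor sampled at a
1.020 ms full-frame interval (~1 kHz). Extracellular stimulation in
layer 4 evokes compound depolarizations that are recorded
simultaneously at three regions of interest: ROI-1 at the stimulation
site (L4), ROI-2 directly above it in L2/3 of the same column, and
ROI-3 in L2/3 of the adjacent column, ~300 µm away from ROI-2. Because
the indicator's green-emission channel dims with depolarization, raw
responses are negative-going; all analysis is done on inverted ΔF/F so
depolarization is positive.

Two statistics summarize each slice:

* **Temporal summation efficacy** — the ratio of the second to the
  first evoked peak (P2/P1) within one trial, plus the maximal
  depolarization reached during a 10-pulse train ("Max Peak").
  P2/P1 > 1 indicates that successive synaptic potentials summate.
* **Spatial propagation efficacy** — the ratio of the evoked amplitude
  at a remote ROI to the amplitude at a reference ROI within the same
  trial (ROI 2/1 vertical, ROI 3/2 horizontal, ROI 3/1 diagonal).

Both are computed per slice at three train frequencies (20, 40, 83 Hz;
interstimulus intervals 50, 25, 12 ms) and then aggregated over
experimental groups (AD vs CTRL × female vs male) with mean ± SEM,
one-way ANOVA and Tukey HSD post-hoc comparisons.

No experimental movies ship with this package; a forward-model
simulator generates movies with known ground truth so that every stage
of the pipeline has a known-answer test.

## Trace extraction

Each ROI trace passes through a fixed stage chain, recorded
step-by-step in the trace's provenance:

1. **ΔF/F with inversion.** Per pixel, `(F − F̄base)/F̄base` against the
   pre-stimulus baseline mean, multiplied by −1.
2. **Spatial averaging** over the ROI aperture — 57 pixels for the
   summation branch, 37 for the propagation branch. Apertures are
   built as the n nearest pixels to the ROI centre, so pixel counts are
   exact.
3. **Sweep averaging** (n = 4 by default), improving SNR by √n.
4. **Photobleach correction.** A single exponential `a·exp(−t/τ) + c`
   is fit by least squares to the samples *outside* a protected window
   (5 ms before the first stimulus to 300 ms — about 7.5 synaptic decay
   constants — after the last pulse) and the entire fitted curve is
   subtracted. Subtracting the whole curve, constant included, leaves a
   zero pre-stimulus baseline; anchoring the curve at either end
   instead leaves a DC offset that the downstream high-pass filter
   turns into an amplitude bias. The (a, τ, c) likelihood surface is
   nearly flat in τ when the observed span is short relative to τ, so
   the fit is seeded by a coarse log-grid profile over τ (a and c
   solved linearly at each τ) and then polished by Levenberg–Marquardt;
   if the polish stalls, the grid optimum is used, and only if both
   fail does the stage fall back to a linear detrend with a warning.
5. **Branch filters.** The summation branch applies a zero-phase
   Gaussian low-pass with a 33 Hz cutoff and *no* high-pass. The
   propagation branch applies a 77 Hz Gaussian low-pass and a causal
   single-pole RC high-pass at 0.1 Hz.

Two conventions deserve a note. The Gaussian "cutoff" is defined as the
half-gain (0.5) frequency; by the Gaussian Fourier pair this fixes the
kernel's time-domain σ at √(ln 2 / 2)/(π f_c). The convention is
recorded in provenance so a −3 dB variant could be swapped in. The RC
high-pass is implemented causally (bilinear transform of the analog
stage, −3 dB at the cutoff) because it mimics AC coupling hardware,
while the low-pass is zero-phase so peak *times* are preserved for peak
detection.

The chain order — ΔF/F, spatial average, sweep average, bleach
correction, filters — differs from the naive "correct every pixel"
order for a practical and a statistical reason: fitting one exponential
per pixel per sweep is computationally indefensible, and because every
averaging step is linear, fitting the bleach model on the averaged ROI
trace estimates the same trend with far less noise. The ΔF/F-then-fit
order (rather than fitting raw intensities) is a documented choice; the
two differ only through the small multiplicative bleach term inside the
response window, which the subtraction removes to first order.

## Peak detection and the two efficacy statistics

For pulse k at time t_k the search window is
[t_k + 2 ms, t_(k+1)) (last pulse: t_k + ISI). The pulse amplitude is
the window maximum minus the pre-train baseline value; ties resolve to
the earliest sample. Measuring from the *baseline*, not from the
preceding trough, is what makes P2/P1 > 1 the signature of summation.
If a window contains no local maximum — fused responses at 83 Hz — the
endpoint-excluded window maximum is reported and the pulse is flagged
unresolved, never silently interpolated; P1 is still read from the
rising phase. Max Peak is the global maximum over the train epoch
extended by three synaptic decay constants.

Ratios carry a validity threshold: a P2/P1 or propagation ratio is only
reported when its denominator exceeds 3× the baseline-window standard
deviation of its trace (a ratio of noise over noise is meaningless; the
threshold choice is ours). Invalid measurements become `NA` markers
that are excluded listwise, and counted, by the group statistics.

Propagation ratios default to P1 of the 10-pulse train — the time point
of the first-response peak used for the frame-subtraction voltage
maps — with a Max-Peak mode available since either reading of "peak
amplitude" is defensible. Similarly, P1 for the summation analysis
defaults to the first pulse of the train rather than the preceding
single conditioning pulse, keeping both peaks within the same optical
trial; the conditioning-pulse response is reported separately.

## The forward model

Each simulated movie is generated as

F(p, t) = B(p) · bleach(t) · (1 − s(p, t)) + shot noise,

where B is the baseline image (with a darker layer-4 band), bleach(t)
decays exponentially (default τ = 8 s, 5% total), and s(p, t) sums two
response components:

* a **fast direct-activation component** ("AP component"): per-pulse
  gain capped at 1 — all-or-none population spiking does not facilitate
  — with a short spatial decay (λ_AP = 60 µm default). Its kernel is a
  Gaussian transient of 6 ms FWHM: single-cell spikes last 1–2 ms, but
  the compound volley seen by a wide-field ROI is temporally dispersed,
  and it is this compound width that determines how much of the
  component survives the 33 Hz analysis filter, as it evidently does in
  real records.
* a **synaptic (EPSP) component**: difference-of-exponentials kernel
  (rise 3 ms, decay 40 ms), per-pulse weights w_k following a
  saturating facilitation schedule `1 + 0.6(1 − 0.55^(k−1))`, Bernoulli
  success per pulse per sweep (p = 0.9) and Gaussian per-sweep onset
  jitter (sd 1 ms).

Spatial decay follows the *path* a signal travels: vertically within
the column, then horizontally through L2/3, so amplitude decays with
the city-block distance. The lateral leg is split at the column
boundary (halfwidth 150 µm): inside the home column, lateral
micro-offsets ride the dense local axo-dendritic arbor and decay with
the local (vertical) constant; only the trans-columnar remainder uses
the horizontal constant. This split matters for group comparisons —
ROI apertures span ±75 µm laterally, and without it a trans-columnar
weakening would leak into the nominally within-column ROI 2/1
measurement. Defaults are λ_local = λ_horiz = 600 µm for CTRL and
λ_horiz = 340 µm for the AD condition, calibrated so the true
ROI 3/2 ratio, exp(−150 µm/λ_local − 150 µm/λ_horiz), sits near 0.6
(CTRL) and 0.5 (AD) — the regime the analysis is designed to resolve —
while the vertical pathway is exactly group-equal. Slice-to-slice
variability is lognormal scatter on the response amplitude (CV 0.2)
and on the space constants (CV 0.08).

The indicator's absolute scale is not constrained by published numbers,
so the defaults — 2% peak ΔF/F at the stimulation site, 60% of it from
the fast component, 20 000 baseline counts with pure shot noise (sd
√F) — are order-of-magnitude choices, exposed in `sim_config()` and
documented as such, not asserted measurements. They give a single-sweep,
single-pixel peak SNR of ~3, low enough that 4-sweep and ROI averaging
visibly matter.

### Ground truth and what "recovery" means

`simulation_truth()` returns the model expectation (no noise, no
jitter, expected synaptic success); `realized_truth()` returns the
noiseless version of the sweep average actually drawn in a trial. The
branch filters are part of the measurement definition — a 33 Hz
low-pass fuses 40 Hz peaks in truth and data alike — so true metrics
are extracted from noiseless traces passed through the *same* filter
chain as the analysis branch. Parameter-recovery tests therefore
measure what the pipeline adds (noise, bleach-fit error, detection
error), not the filter's deterministic and shared effect. With four
sweeps, the Bernoulli sampling of synaptic success moves a trial's
realized amplitudes by ~15% around expectation; comparing against the
realized truth removes that irreducible sampling term.

### What the simulator does not emulate

No conductance-based biophysics, no lateral inhibition or adaptation
(per-pulse weights are fixed, not state-dependent), no slow
oscillations or spontaneous activity, no motion, no hemodynamic or
dual-wavelength artifacts, and spatial decay is separable and
exponential by construction. A passing recovery test shows the pipeline
is correct *under this statistical structure*; it does not certify
behaviour under real-tissue artifacts the model omits.

## Group statistics

Group summaries are mean ± SEM (sd/√n; zero for n = 1 by convention).
The omnibus test is the classical fixed-effects one-way ANOVA; pairwise
comparisons use Tukey's HSD on the studentized-range distribution, in
the Tukey–Kramer form since group sizes (42/41/18/26) are unequal. Both
are delegated to R's `aov()`/`TukeyHSD()` behind the package's
interface, and tests cross-check them against independent oracles: the
F = t² identity on two groups, a 200 000-draw Monte-Carlo studentized-
range oracle on balanced three-group data, and a 500-cohort null
calibration that must reject at ≤ 6% for α = 0.05. Significance stars
use inclusive thresholds (≤ 0.05, 0.01, 0.001, 0.0001 → one to four
asterisks, otherwise "n.s.").

For condition comparisons the default family is per direction: one
ANOVA across the six group × frequency cells of a ratio, with the
within-frequency AD-vs-CTRL Tukey comparison extracted per frequency —
matching how the propagation panels are organised; a per-frequency
family is available as an option.

## Problem sizes and numerical choices

Simulated studies in the tests and the acceptance script run at a
reduced geometry — 40 × 40 pixels at 25 µm/px (the full 80 × 80 at
12.5 µm/px remains the default for interactive use) — with the full
temporal paradigm: 200 ms baseline, conditioning pulse at 200 ms,
10-pulse train from 450 ms, 500 ms tail (~1100–1400 frames). Recovery
studies use 52 slices at 40 Hz; the group-pattern study uses 36 slices
at all three frequencies; the null calibration uses 500 cohorts of
8 + 8 slices at the truth level. Movie rendering is deterministic per
slice via stored seeds, so cohorts are regenerated on demand rather
than held in memory.

Degenerate inputs are contracts, not surprises: empty baseline windows,
non-positive baselines, trains extending past the trace end, empty
ROIs, sub-threshold reference amplitudes and over-strong simulated
responses (fluorescence driven negative) all raise errors or `NA`
markers with explicit messages. Integer camera counts are rounded at
simulation time; fully deterministic studies disable quantization,
because with zero noise the rounding error is identical across sweeps
and neighbouring pixels and never averages out.

## Known limitations

* The amplitude scale, noise level and bleaching parameters are
  modelling choices, so absolute amplitudes (e.g. Max Peak in ΔF/F) are
  only meaningful relative to each other, not as predictions of any
  given indicator.
* Animal-level nesting is ignored: slices are treated as the
  experimental unit. A mixed-effects model of within-animal correlation
  is out of scope.
* The AP/EPSP decomposition is phenomenological. Only its two
  signatures matter downstream: non-facilitating fast transients near
  the electrode, facilitating slow potentials away from it.
* Fused 83 Hz trains make per-pulse amplitudes beyond P1 partly
  conventional; unresolved pulses are flagged so downstream users can
  filter on `n_resolved`.
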