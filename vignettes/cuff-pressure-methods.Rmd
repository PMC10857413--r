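---
title: "Methods: simulating and analysing cuff-pressure discomfort experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing cuff-pressure discomfort experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuffcomfort)
```

## The problem

Rehabilitation robots and other wearable devices press against the body at
their binding parts. Quantifying how uncomfortable a given interface
pressure is — objectively, from physiology, rather than only from
self-report — supports the design of such interfaces. The measurement
paradigm implemented here applies controlled pneumatic-cuff pressures
(10, 20, 30 kPa) to the thigh and records:

* **Electrodermal activity (EDA)**, the skin's electrical conductance,
  driven by sympathetic sweat-gland activity (1 kHz sampling);
* **Tissue oxygen saturation (StO2)** under the cuff via near-infrared
  spectroscopy (NIRS, 5 Hz), which falls when the cuff occludes perfusion;
* a **visual analog scale (VAS)** discomfort rating (0-10) after each
  epoch, normalized per subject against a brief 60 kPa anchor application:
  `VAS_norm = 100 * VAS(P) / VAS(60 kPa)`.

Two within-subject designs are built in: 1-minute epochs with 13 subjects
(EDA only) and 5-minute epochs with 10 subjects (EDA + NIRS), both with
randomized condition order and 5-minute rests.

## Signal model of the simulator

No public per-subject recordings exist for this paradigm, so the package
ships a seeded generator whose outputs exercise every stage of the
analysis.

**EDA.** The trace is `tonic + phasic + noise`:

* tonic: a per-subject baseline level (lognormal across subjects, ~8 uS),
  a slow linear habituation drift (normal, mean −0.0033 uS/s), and a small
  pressure-coupled shift ramped on and off with a 2-s raised cosine at
  epoch edges (avoids step discontinuities and filter ringing);
* phasic: an inhomogeneous Poisson train of skin conductance responses
  (SCRs). Each SCR is a Bateman kernel
  `b(t) = A (e^{-t/4} - e^{-t/0.75})`, normalized to unit peak so `A` is
  the event amplitude — the standard psychophysiology shape; the source
  protocol specifies none, so these conventional constants are a design
  choice. Event rates are `base + gain * P` per minute during epochs
  (defaults 4 and 0.36) and `base` during rests; amplitudes are lognormal
  (sdlog 0.65) with median growing linearly in pressure;
* noise: white Gaussian, default 0.005 uS.

**NIRS.** A latent saturation trajectory relaxes exponentially (default
time constant 45 s) toward a pressure-dependent asymptote and back to
baseline during rests. The asymptotic drop is
`drop_max * [(min(P, P_occ)/P_occ)^gamma + beta * max(P - P_occ, 0)/P_occ]`
with occlusion pressure `P_occ = 20` kPa. We chose a convex exponent
`gamma = 2.3` and a small residual slope `beta = 0.09` above occlusion:
published thigh-cuff decreases rise steeply between 10 and 20 kPa and only
slightly beyond (vessels already occluded), yet the 20 vs 30 kPa contrast
remains statistically detectable — an exactly flat plateau would make that
contrast pure noise, and a linear rule would make the 10 kPa drop half of
the 20 kPa drop, neither of which matches observation. Setting
`gamma = 1, beta = 0` recovers the piecewise-linear hard plateau. Channels
are `oxyHb = THb * S/100` and `deoxyHb = THb - oxyHb`, so total hemoglobin
is conserved exactly before noise and `100*oxy/(oxy+deoxy)` round-trips
the latent trajectory to machine precision.

**VAS.** Raw ratings are `clip(s * P / 6 + e, 0, 10)` with per-subject
sensitivity `s` (lognormal around 1) and rating noise `e` (SD 0.5). The
anchor rating is generated by the same stochastic rule rather than pinned
at 10, so normalization is exercised non-trivially.

**Seeding.** One master seed per cohort; every (subject, signal) pair gets
an independent substream through a documented integer hash
(`substream_seed()`), so cohorts are pure functions of `(design, seed)`.

## Feature extraction

* **Decomposition**: phasic = zero-phase (forward-backward) 2nd-order
  Butterworth high-pass at `fc = 0.05` Hz with odd-reflection padding;
  tonic = raw − phasic. Defining tonic as the exact complement guarantees
  `phasic + tonic = raw` to machine precision on every input. Recordings
  shorter than `10/fc` (200 s) are rejected as too short for settling.
* **Mean SCL** is the epoch mean of the tonic component *referenced to a
  pre-epoch baseline window* (default 10 s). Published mean-SCL values are
  negative, which absolute conductance cannot be, so the measure must be a
  change from baseline.
* **SCR detection**: local maxima of the phasic trace whose rise from the
  preceding trough reaches 0.01 uS, with peaks closer than 1 s merged
  (keeping the larger). These two constants are conventional
  psychophysiology defaults and are tunable. A 0.2-s moving average is
  applied before the extremum scan so broadband measurement noise cannot
  spawn spurious maxima; it attenuates true SCR peaks (rise time ~1.5 s)
  by well under 1%. Per epoch the features are the SCR count and the
  maximum amplitude (0 if no event).
* **StO2 decrease**: saturation is averaged in 30-s blocks from pressure
  onset; the decrease is the pre-onset 30-s baseline mean minus the final
  full block's mean, in percentage points (absolute, not relative — an
  occlusion that removes tens of points of saturation reads naturally in
  points). Whether the reference should be the final or the minimum block
  is ambiguous in the source protocol; the final block is the default and
  `block_stat = "min"` is available. Partial trailing blocks are
  discarded.
* 1 kHz EDA can optionally be block-mean decimated (e.g. to 20-50 Hz)
  before filtering; features agree with full-rate processing to within
  ~1% (tested), and the replicate studies below use 25-50 Hz for speed.

## Inference

One-way repeated-measures ANOVA per feature
(`F = MS_condition / MS_(condition x subject)`), with Greenhouse-Geisser
epsilon and corrected p reported alongside (the source analysis assumed
sphericity, so the uncorrected p is the headline number); post hoc paired
t-tests for the three pressure pairs, uncorrected by default (published
post hoc tables of this kind are typically uncorrected; Holm/Bonferroni
by flag); Pearson correlation of each feature against normalized VAS over
the pooled subject x condition observations (a single r per feature, as
published summaries report; per-subject pooling alternatives are a known
limitation); Shapiro-Wilk normality per condition and Mauchly's
sphericity test. Degenerate inputs (incomplete designs, zero-variance
differences) raise typed errors rather than returning NaN — except the
all-differences-zero case, which is a well-defined "no effect"
(`t = 0, p = 1`; `F = 0, p = 1`).

Rendered tables follow the field's conventions: `mean ± SD` cells,
3-decimal statistics, a `0.000` display floor for p < 0.0005 (stored
values keep full precision), and `*` marking p below alpha.

## Calibration of the generator defaults

The population defaults were calibrated once against the per-condition
summary cells of published thigh-cuff tables (mean SCL, maximum SCR
amplitude, SCR counts for both designs; StO2 decrease for the 5-min
design), by sweeping 30 seeded cohorts per design at a 25 Hz analysis
rate and adjusting the population means until cohort means centred in the
published mean ± 1 SD bands, then frozen. The StO2, SCR-count and
max-amplitude cells all centre well. The Exp-2 mean-SCL cells
(−0.10 to −0.06 ± ~0.04 uS) cannot all be met by this model family: a
kernel train at the published rates and amplitudes necessarily deposits a
sustained tonic elevation during epochs (kernel integral 5.9 s x rate x
mean amplitude ~ 0.2-0.9 uS) that dwarfs those narrow bands. Real skin
conductance evidently contains many more small SCRs and a stronger
habituation than a linearly-coupled Poisson train; we kept the simple
monotone couplings and accept that the simulated mean SCL exceeds the
published cells at 10 and 30 kPa in the 5-min design. This is a
documented, deliberate mismatch — the qualitative orderings (all features
rising with pressure, the StO2 decrease saturating above 20 kPa, StO2
correlating with discomfort more strongly than SCL) are reproduced with
high probability, and those orderings are what the analysis stage is
meant to detect.

## What passing tests do and do not show

The generator emulates epoch structure, pressure-graded SCR activity,
occlusion hemodynamics and anchored self-report, with Gaussian noise. It
does **not** emulate motion artifacts, electrode drift/detachment,
thermoregulatory sweating, emotional SCRs unrelated to pressure, NIRS
heartbeat/respiratory content, or non-stationary habituation beyond a
linear drift. Green tests therefore certify the pipeline's numerics and
its behaviour under the stated model, not performance on arbitrary
real-world recordings.

## Problem sizes and numerical choices

Replicate studies run the 5-min design at 25 Hz EDA (200 replicates for
the qualitative-pattern checks; 1000 reduced null tables for the type-I
calibration), and single-cohort summaries use 50 Hz; both rates were
validated against full-rate processing. Filter settling requires 200 s of
recording; epoch intervals are half-open `[onset, offset)`; ties in the
peak merge keep the earlier-listed larger event; sampled StO2 outside
[0, 100] % or with non-positive total hemoglobin is flagged invalid and
excluded from block means (an all-invalid window is an error).

## Known limitations

* The inter-subject variability model (lognormal/normal with fixed CVs)
  is a pragmatic choice, not identified from data.
* The printed F and r values of the reference experiments cannot be
  reproduced exactly without the unpublished per-subject recordings; the
  package targets their qualitative structure and scale.
* SCR detection is threshold-based on the high-pass phasic trace;
  deconvolution methods (e.g. cvxEDA) would separate overlapping events
  better and are out of scope.
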