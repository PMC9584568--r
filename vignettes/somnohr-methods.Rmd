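---
title: "Heart-rate-based sleep staging: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate-based sleep staging: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnohr)
```

## Overview

`somnohr` implements an automatic sleep-staging pipeline that uses only the
heart-rate signal derived from a single-channel ECG. Sleep stages modulate
autonomic balance: REM sleep shows elevated low-frequency (LF, 0.04–0.15 Hz)
heart-rate-variability power and reduced high-frequency (HF, 0.15–0.40 Hz,
respiratory) power relative to deep NREM sleep, and mean heart rate differs
systematically across stages. The pipeline runs, in order:

1. **Signal quality** — a per-sample SNR index with epoch and recording
   rejection rules;
2. **R-peak processing** — QRS detection, spurious-beat correction, and
   resampling of the RR tachogram onto a uniform grid;
3. **Feature extraction** — per-epoch HR/HRV features and ECG-derived
   respiration on the 30-s AASM epoch grid;
4. **Classification** — a two-stage temporal-convolutional network emitting
   4-level posteriors (Wake / Light / Deep / REM), collapsed hierarchically
   to 3-level (Wake / NREM / REM) and 2-level (Wake / Sleep) outputs;
5. **Evaluation** — epoch-, subject- and cohort-level agreement metrics with
   covariate regressions; and
6. **Alignment** — placing two simultaneously recorded devices on one epoch
   grid.

Every stage is exercised on synthetic cohorts with known ground truth,
generated by the package itself. No external data or pretrained weights are
required or shipped.

## The signal-quality index

The ECG is split into a *signal* and a *background* component by a linear
decomposition. The per-sample quality index is

$$\mathrm{SNR}(i) = 20\,\log_{10}
  \frac{A_\mathrm{signal}(i)}{A_\mathrm{noise}(i)}\ \mathrm{dB},$$

where $A_\mathrm{signal}$ is a maximum filter of the absolute signal
component over a sliding 3-s window and $A_\mathrm{noise}$ is $\sqrt{2}$
times the RMS of the background over a sliding 10-s window, both slid one
sample at a time. An epoch is rejected when **50% or more** of its samples
have SNR **strictly below 5 dB**; a recording is excluded when **10% or
more** of its epochs are rejected. Both percentage boundaries are inclusive.
Retained recordings are scored on *all* epochs, including rejected ones —
rejection only informs the exclusion decision.

Design choices that the operational definition leaves open:

* **Decomposition.** We use an à-trous B3-spline stationary wavelet
  transform (the "starlet"): repeated smoothing with the upsampled kernel
  $(1,4,6,4,1)/16$ produces additive detail layers whose sum reconstructs
  the input exactly. Detail level $j$ spans roughly
  $[f_s/2^{j+1}, f_s/2^{j}]$ Hz; levels intersecting the QRS energy band
  (default 5–32 Hz) form the signal, the residual is the background. The
  transform is linear, making the dB index invariant to input rescaling.
  The decomposition is also a pluggable hook (`qc_config(decompose =)`),
  so the threshold machinery is testable with exactly known components.
* **Window placement.** Whether the 3-s/10-s windows are centered or
  trailing is not operationally fixed; we center them (reflect padding at
  the edges), which keeps the index symmetric around local artifacts.
* **Degenerate values.** SNR is clipped to $[-40, +80]$ dB and the noise
  amplitude floored at machine-epsilon scale, so the index is always
  finite. A perfectly background-free record therefore reads +80 dB.

## R-peak detection and the tachogram

The detector is from the Pan–Tompkins family: zero-phase 5–25 Hz band-pass,
squaring, 150-ms moving-window integration, adaptive signal/noise threshold
tracking, and a 300-ms refractory period. Polarity is resolved by comparing
the energy of positive and negative excursions of the band-passed signal.
Each detection is refined by parabolic interpolation around the local
extremum, giving sub-sample timing. On clean synthetic ECG at 256 Hz the
mean absolute timing error is on the order of 0.01 ms — far inside the
±4 ms precision the staging method requires, since phase jitter in the
tachogram corrupts HF-band HRV estimates.

Spurious-beat handling follows standard tachogram artifact practice: an RR
interval deviating more than 30% from the 11-beat running median (or
outside 300–2000 ms) marks an artifact; premature beats are removed, and
long gaps are bridged by evenly spaced beats flagged `interpolated`. The
operation is idempotent and never produces RR outside 300–2000 ms. The
cleaned series is resampled at 4 Hz by cubic spline (RR values anchored at
the beat terminating each interval) — the rate and scheme fed to the
network are a package choice, as only the 30-s epoch contract is fixed by
the problem.

## Features

Per 30-s epoch: mean HR, SDNN, RMSSD from the epoch's tachogram samples;
LF/HF band powers and their ratio by Welch's method on a 5-min window
centered on the epoch (the shortest conventional window for LF
estimation); respiration as the dominant HF-band frequency (respiratory
sinus arrhythmia), which is also how the generator's ground-truth
respiratory rate is recovered in tests; and an in-bed flag from the modal
body position (out-of-bed iff upright). The classifier consumes both the
raw 4-Hz tachogram segment and the scalar features broadcast along time,
with a mask channel marking context padding, so either input ablation is
runnable. Channel scalings are centered (e.g. RR − 1 s, (HR − 60)/30) to
keep inputs near zero at rest; this materially speeds up optimization.

## The two-stage classifier

**Stage 1** encodes each epoch independently: a 1×1 stem over the 10 input
channels, three inception-residual blocks (parallel kernels 3/5/7 on the
4-Hz grid, concatenated, projected back, residual-added), global mean
pooling, a linear embedding, and an auxiliary 4-class head. **Stage 2**
refines the sequence of epoch embeddings concatenated with the auxiliary
posteriors: a 1×1 stem, six dilated residual blocks (dilations 1, 2, 4, 8,
16, 32 epochs — a receptive field beyond half an hour, letting long-range
sleep architecture inform each epoch), and a two-layer head emitting
per-epoch 4-class logits.

The family and the capacities are fixed; the layer hyperparameters are
not. We expose a closed-form parameter-count formula
(`staging_param_counts()`) — every layer is a biased convolution with
$c_\mathrm{out}(k\,c_\mathrm{in} + 1)$ weights — and solve the widths by
integer search (`calibrate_staging_widths()`) so the default configuration
holds exactly 492,420 (stage 1), 538,796 (stage 2), and 1,031,216 (total)
trainable parameters. The solved defaults are stem 88, branch 101,
embedding 111, stage-2 width 119, head 111. `build_model()` cross-checks
the formula against an enumeration of the instantiated tensors on every
build.

The network, backpropagation, and the Adam optimizer are implemented in
plain matrix R. Convolutions operate on segmented sequences (epochs in
stage 1, subjects in stage 2) and never bleed across segment boundaries;
this is asserted by test. Analytic gradients are verified against central
finite differences.

Training splits subjects 80/20 at the participant level, runs full-batch
Adam, logs the train/test accuracy curve each iteration, and retains the
weights with the smallest held-out loss. The loss is cross-entropy on the
stage-2 head plus 0.3 × cross-entropy on the auxiliary stage-1 head.
Class weighting is exposed (`training$class_weights`, including
`"balanced"`); the default is uniform because the synthetic cohorts are
roughly balanced and uniform weights make the label-permutation control
well defined (a signal-free model converges to base rates). Argmax ties
break toward the earlier class in (W, Light, Deep, R), deterministically.

Collapsing is a probability-space homomorphism: 3-level and 2-level
posteriors are sums of 4-level posteriors within groups
({Light, Deep} → NREM; {Light, Deep, REM} → Sleep; Wake is invariant), and
labels are recomputed as the argmax of the collapsed posteriors.
Consequently Wake one-vs-rest metrics are identical across the three
levels, and collapsing confusion matrices commutes with collapsing label
sequences — both are tested exactly.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed and the
tests run against them.

* **Hypnograms** are first-order Markov chains over {W, N1, N2, N3, R} at
  the 30-s epoch scale. The default transition matrix encodes sticky
  N2/N3/REM runs, transient N1, and occasional awakenings; long-run stage
  frequencies are validated against the analytic stationary distribution.
* **RR dynamics** per stage: baseline mean RR, an LF oscillation at a
  subject-specific frequency in 0.095–0.105 Hz, an HF oscillation at the
  stage respiratory rate (doubling as respiration ground truth), and white
  jitter topping total variance up to SDNN². Sinusoid amplitudes are
  $\sqrt{2 P}$ so band powers equal the configured ms² values. Stage
  boundaries cross-fade linearly over 30 s so the classifier cannot
  exploit unphysiological discontinuities. The `"default"` regime uses
  literature-plausible overnight values (e.g. mean RR 850/1000/1050/900 ms
  for W/N2/N3/REM, REM LF 1200 ms² vs N3 150 ms²); no published
  quantitative stage table is being reproduced, so these live in config,
  not code. The `"easy"` regime widens mean-HR separation and shrinks
  jitter, defining the benign recoverability conditions used in the
  end-to-end training study.
* **ECG waveforms** place one parametric pulse per beat (Ricker by
  default — zero-mean, so its energy sits inside the QRS band; Gaussian
  optional) plus baseline wander and segment-local Gaussian noise. The
  pipeline is morphology-insensitive by design, so no PQRST realism is
  attempted — this is a deliberate non-goal.
* **Cohorts** attach balanced round-robin metadata (age ≤ 40 / 40–60 /
  > 60; AHI none-minimal / mild / severe; sex F/M) and can plant known
  performance effects: predicted labels are built from the reference by
  flipping each epoch to a random *wrong* class with probability
  1 − accuracy, plus a planted extra flip probability per group, so a
  planted −0.05 accuracy effect is exact in expectation.

What the generator does **not** emulate: arrhythmia and ectopy beyond
isolated artifacts, apnea events, movement artifacts with realistic
spectra, inter-subject HRV heterogeneity beyond stage effects, and any
age/AHI/sex physiology (group effects are planted on label quality, not
on the signal). Passing tests therefore demonstrate that the machinery is
correct and that the method recovers structure *when the assumed
stage–HR coupling holds*; they are not evidence about performance on real
polysomnography.

## Evaluation framework

Confusion matrices treat each scored epoch as one observation (rows =
reference, columns = predicted). Metrics: accuracy, Cohen's kappa, and
one-vs-rest sensitivity/specificity/PPV/NPV per class; zero-denominator
cells are `NA`, never zero-filled, and are excluded (with `n` adjusted)
from cohort averages. Subject-level metrics are computed from per-subject
confusion matrices and then averaged to cohort level — the defensible
reading of within-then-across-participant averaging; pooled epoch-level
metrics are reported alongside. Subject-level kappa is the mean of
per-subject kappas (the pooled-counts kappa is available from the pooled
block). Confidence intervals use the normal approximation
mean ± 1.96·SEM, as no particular CI method is prescribed by the problem.

Covariate effects are estimated by *independent* ordinary least-squares
fits — one factor at a time — of each per-subject metric on age group, AHI
group, and sex, dummy-coded against the reference levels age ≤ 40,
AHI ≤ 5 (none/minimal), and female, with significance stars at
0.05/0.01/0.001. The recovery study plants a −0.05 accuracy effect on the
> 60 group across 100 seeded 18-subject cohorts and checks CI coverage;
the type-I study uses 200 effect-free cohorts and checks the 5% nominal
rejection rate.

## Alignment

Two devices are aligned on a common grid starting at the earlier
lights-off time. The shorter recording is extended with W ("awake")
epochs, flagged as padded; interior dropouts (`NA` labels) are W-filled
and flagged too — a documented extension, since only end-padding is
operationally forced. Sub-epoch offsets are snapped to the nearest epoch
boundary with the (< 15 s) residual reported, as fractional offsets have
no prescribed treatment. Lights-off defaults to the recording start when
no diary or position-derived value is supplied.

## Problem sizes and numerical choices

The shipped studies are desk-scale by design:

* End-to-end training: 20 subjects × 60 epochs (easy regime), the
  width-reduced configuration (`width_multiplier = 0.12`, ~24k
  parameters), full-batch Adam. The capacity-calibrated default model is
  built and counted, but trained only at reduced width.
* Regression studies: 18 subjects × 120 epochs × 100 (coverage) and
  200 (type-I) cohorts, run at label level (no waveform synthesis).
* Detector validation: 10 min of clean 256-Hz ECG.

Other numerics: SNR clipped to [−40, 80] dB; Welch PSD with Hann windows,
50% overlap, linear detrending, one-sided density normalization (band
integrals in ms²); tachogram values clamped to [300, 2000] ms; flat-line
ECG yields an empty detection with a warning rather than an error; epochs
outside the tachogram get `NA` features, never fabricated values.

## Known limitations

* The wavelet decomposition is a reasonable stand-in for an unpublished
  proprietary one; absolute SNR values (and hence exclusion counts on any
  given dataset) depend on it, which is why tests pin down the threshold
  semantics rather than dataset-specific exclusion tallies.
* The classifier is trained only on synthetic cohorts at reduced width;
  no claim is made about real-data accuracy, and no trained weights ship.
* Training is full-batch and single-threaded; it is adequate for the
  shipped study sizes, not for overnight-scale corpora.
* WFDB support covers format 16 (including byte-offset `.mat` variants);
  EDF writing is out of scope.
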