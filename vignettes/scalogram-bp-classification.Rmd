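---
title: "Classifying blood pressure from PPG wavelet scalograms"
author: "scalobp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying blood pressure from PPG wavelet scalograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Photoplethysmography (PPG) is a cheap optical measurement of blood-volume
pulsation; arterial blood pressure (ABP) is the invasive reference waveform
in mmHg. Because blood-pressure fluctuations are reflected in PPG pulse
morphology, a single PPG channel can in principle support cuffless
blood-pressure screening. `scalobp` implements the full pipeline for the
image-based variant of that idea: PPG segments are converted to
time-frequency *scalograms* through a continuous wavelet transform (CWT) and
classified as normal versus abnormal blood pressure by a small convolutional
network, with the ABP channel supplying ground-truth labels. The central
scientific question the pipeline supports is which combination of mother
wavelet (six candidates) and segment length (nine candidates, 0.8-4.0 s at
125 Hz) classifies best, explored with `grid_search()`.

## Labels

For a segment, systolic pressure (SBP) is the arithmetic mean of the
synchronous ABP peak values and diastolic pressure (DBP) the mean of the
trough values (`segment_bp()`). Categories follow the 2017 ACC/AHA
hypertension thresholds, written out explicitly since the guideline is
usually cited rather than printed: Stage 2 if SBP >= 140 or DBP >= 90, else
Stage 1 if SBP >= 130 or DBP >= 80, else Elevated if SBP >= 120, else
Normal, with precedence Stage 2 > Stage 1 > Elevated. The binary label pools
Elevated with the two hypertensive stages as "abnormal": reported group
means in comparable ICU cohorts (normal 104.81/71.55, abnormal 132.22/85.09
mmHg) are only consistent with that pooling, and our unit tests verify the
consistency on a mixture with matching proportions.

## Preprocessing

PPG is smoothed with a centred moving average of 5 samples (40 ms at
125 Hz) — wide enough to suppress sensor noise, narrow enough to preserve
the systolic upstroke — then detrended by subtracting a 2 s moving-average
trend. The 2 s window attenuates the 0.1-0.5 Hz respiratory band while
costing < 20% of the pulse band (the moving average's gain is ~sinc(f·T), so
the residual at 1.25 Hz is about 13%). One honest caveat: at 0.25 Hz the
remover cancels ~87% of the wander power, not all of it; a notch or
high-pass filter would do better, but the moving-average subtraction is kept
for its transparency and edge behaviour. Both filters are applied at record
level before segmentation, because the 2 s trend window exceeds the shorter
segment lengths (0.8-2.0 s). The ABP channel is used raw for labelling.

Records are screened automatically (`quality_check()`): `no_signal` when a
channel's SD falls below 1e-6 of its range (or the range is zero),
`missing_peaks` when any inter-beat gap exceeds 2 s, and `artifact` when any
sample deviates from the channel median by more than 8 robust scales. The
robust scale is max(MAD, IQR/1.349) rather than the MAD alone: on a sparse
pulse train most samples sit at baseline, the MAD collapses, and a pure MAD
rule would flag every healthy beat. All thresholds are exposed through
`qc_config()`.

## The six wavelets and the transform

`wavelet_function()` implements the six bases from their closed forms —
frequency B-spline `fbsp1-15-1`, Shannon `shan15-1`, complex Gaussian
`cgau1`, Morlet, Mexican hat, and real Gaussian `gaus1` — with
sinc(x) = sin(pi x)/(pi x) and the first-derivative Gaussians normalised to
unit L2 norm analytically. Note that the conventional `shan15-1`/`fbsp1-15-1`
parameters violate the admissibility sufficiency condition Fc > Fb/2 (their
passband contains 0); `wavelet_spec()` warns and proceeds, since those are
the parameterisations in common use.

The transform is the L2-normalised correlation
W(a,b) = a^(-1/2) * sum_t x(t) psi*((t-b)/a) dt, computed per scale by
frequency-domain convolution with the signal zero-padded by one kernel
support each side. Numerical choices: kernel support is truncated where the
envelope falls below 1e-8 of its peak (Gaussian-enveloped wavelets), and
capped at ±8 effective periods for the slowly decaying sinc-tailed
fbsp/shan; the same sampled kernel feeds `cwt_oracle()`, a literal
double-loop evaluation of the sum, so the two routes must agree to rounding
error (observed ~1e-15, asserted < 1e-6 in tests). The default scale grid is
64 geometric scales spanning pseudo-frequencies 0.5-20 Hz via
f = Fc_eff * fs / a. Fc_eff is the numerically located dominant spectral
frequency for the Gaussian-type wavelets (signed axis — cgau1's energy sits
at negative frequency) and the Fc parameter itself for fbsp/shan, whose flat
rectangular passband has no meaningful spectral peak.

## Rendering

Scalogram images are rendered directly from the coefficient matrix
(magnitude for complex wavelets, real part for real ones, both selectable):
per-image min-max normalisation to [0,1] (constant matrices map to 0.5),
separable bilinear resize to 224 x 224 implemented as two precomputed
interpolation-matrix products (exact, fast, and bit-reproducible), then a
viridis colormap — dark blue for small coefficients through bright yellow
for large ones. Row 1 is the smallest scale (highest pseudo-frequency) at
the image top; time runs left to right. Rendering through a plotting canvas
was deliberately avoided: axes, DPI and interpolation would make pixels
irreproducible. Per-image normalisation means rendering needs no
training-set statistics. The no-CWT baseline (`render_raw_segment()`) tiles
the normalised 1-D segment across the image rows as grayscale.

## The classifier

`build_model()` constructs the fixed stack: 64 3x3 kernels (stride 1, same
padding, ReLU) -> 2x2/2 max pool -> 128 5x5 kernels (same, ReLU) -> 2x2/2
max pool -> flatten (56*56*128 = 401408) -> dense 256 ReLU -> dense 128
ReLU -> 1 sigmoid; 103.0M parameters, almost all in the first dense layer.
It is implemented from scratch in single precision (im2col + BLAS sgemm in
`src/cnn.cpp`) with Adam on mean binary cross-entropy. Training defaults
(`train_config()`): Adam, learning rate 1e-4, batch 32, 30 epochs — stated
as conventional defaults, not tuned values. Pixels are scaled to [0,1];
accuracy uses the 0.5 threshold; ROC/AUC are computed by score sweep and
trapezoid (`roc_curve()`), cross-checked against pROC in tests. The package
pins BLAS to one thread on load: this is the deterministic mode (identical
seeds give bit-identical weights) and is also faster on single-CPU hosts,
where OpenBLAS otherwise oversubscribes threads.

## The synthetic cohort

Real ICU waveform databases cannot ship with a package, so
`generate_dataset()` synthesises paired records at 125 Hz with known
ground truth. The ABP beat is a raised-cosine upstroke over the first 30% of
the beat followed by an exponential decay, so each beat's extrema equal the
SBP/DBP targets exactly before noise; beat periods jitter by up to 2% so
segments are not perfectly periodic. The PPG pulse is a Gaussian systolic
wave plus a dicrotic wave, with pulse width affine in SBP and dicrotic depth
affine in DBP — a *declared fixture* that guarantees the two blood-pressure
regimes are morphologically separable, not a physiological model. Default
"realistic" nuisance settings are wander amplitude 0.1 of the pulse
amplitude at 0.25 Hz (mid respiratory band) and noise SD 0.02; category
proportions default to 1641:1739:2692:334 (normal : elevated : stage 1 :
stage 2), the prevalence reported for comparable ICU cohorts; per-record BP
targets are drawn from category boxes kept >= 2 mmHg clear of the ACC/AHA
thresholds so that waveform-recovered labels (accurate to ~1 mmHg
noiselessly) match the intended category. Consequently, passing end-to-end
tests shows the pipeline is *correct and learnable*, not that 90%-level
accuracy transfers to real PPG, whose morphology-BP coupling is far weaker
and noisier.

## Problem sizes

The end-to-end recovery check (tests and `scripts/acceptance.R`) trains on a
balanced noiseless cohort of 200 segments (cgau1, segment-300, 90/10 split)
for 10 epochs and requires validation accuracy >= 0.85. These sizes are the
package's chosen desk-scale configuration: one forward+backward pass of this
network costs ~16 GFLOP, and 200 x 10 keeps a from-scratch CPU run in the
minutes range while leaving the optimiser enough steps to converge on the
separable fixture. Unit tests use smaller synthetic image sets (16-20
images, <= 8 epochs) sized to demonstrate memorisation and determinism
rather than generalisation.

## Known limitations

* The synthetic PPG-BP coupling is monotone and clean by construction;
  results on it upper-bound nothing about clinical data.
* The segment-level randomised split mirrors the usual practice in this
  literature but allows segments of one subject in both splits; a
  record-level split is available (`split` at the record list level) for
  leakage-aware experiments.
* GoogLeNet-style transfer learning is out of scope (it requires external
  pretrained weights); `grid_search()` accepts only the built-in
  architecture.
* The WFDB binary format is not read; records enter either from the
  generator or from the CSV + JSON sidecar format of `write_record()`.
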