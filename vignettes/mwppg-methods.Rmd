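---
title: "Multi-wavelength PPG fusion for cuffless blood pressure: methods and design notes"
author: "mwppg"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Multi-wavelength PPG fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fingertip photoplethysmography (PPG) measures blood-volume pulsation
optically. Light of different wavelengths penetrates to different tissue
depths — 660 nm stays superficial, 940 nm reaches deeper vascular beds —
so a four-wavelength PPG sensor (660/730/850/940 nm, Channels 1–4) sees
four depth-distinct views of the same pulse. `mwppg` implements a fusion
pipeline that turns such recordings into continuous, cuffless estimates of
systolic and diastolic blood pressure (SBP/DBP), together with the
device-validation statistics used to judge BP monitors (AAMI criterion,
BHS grading, Bland–Altman agreement).

The pipeline is image-based rather than feature-engineered: each 5 s
window of each wavelength is turned into a continuous wavelet transform
(CWT) scalogram, rendered as an RGB image, and the four per-wavelength
images are stacked depth-wise into one 12-channel tensor that a compact
attention CNN + bidirectional LSTM maps to (SBP, DBP).

## Pipeline stages

**Preprocessing.** Each channel is band-pass filtered with a second-order
Butterworth filter, passband 0.5–8 Hz, applied forward and backward
(`signal::filtfilt`), which preserves the timing of pulse landmarks. The
signal mean is removed before filtering; DC lies outside the passband
anyway, and a large sensor offset would otherwise excite edge transients
in the forward–backward pass, which extends the signal with zeros. Each
channel is then z-scored per record (zero mean, unit variance), which
makes all downstream stages invariant to per-channel sensor gain, and cut
into 5 s windows sliding by 1 s — 56 windows per 60 s record — with the
four channels cut simultaneously so window *i* covers identical sample
indices in every channel. Normalising before windowing (rather than per
window) keeps the relative amplitude structure across windows; the
alternative order is available by composing the exported functions
directly.

**Quality screening.** Abnormal segments are rejected by a three-part
rule, each part configurable via `qualityRule()`: a flatline fraction
(default: at most 10 % of near-zero-derivative samples), an amplitude
bound on the record-normalised signal (default |z| ≤ 25, which sits well
above the ≈17 reached by clean narrow systolic pulses after z-scoring,
while still catching artifact spikes), and a periodicity floor (maximum
autocorrelation over lags 0.4–1.5 s, the physiological beat-period range,
at least 0.3). A window is dropped from *all four* channels if *any*
channel violates the rule, preserving alignment. On clean simulated
recordings the default rule retains 100 % of windows.

**Scalograms.** The CWT of a window is computed against the first-order
complex Gaussian wavelet ("cgau1"),
ψ(t) = C₁ d/dt[e^{−t²} e^{−it}] with C₁ chosen for unit L² norm, using
the standard scaled-translate family ψ_{a,b}(t) = |a|^{−1/2} ψ((t−b)/a).
The transform is evaluated by FFT-based linear convolution on the sample
grid; the wavelet support is truncated at |t/a| ≤ 6 where it has decayed
below 10⁻¹⁵, and a dedicated test checks the fast path against a direct
Riemann-sum evaluation of the defining integral to a relative error of
10⁻³ (it agrees to near machine precision). Because the wavelet is
complex-valued the scalogram stores magnitudes, which yields the
non-negative image the rest of the pipeline consumes; the real part alone
would oscillate at the carrier frequency.

Two discretisation conventions are fixed deliberately:

* **Scale grid.** 64 logarithmically spaced scales whose
  pseudo-frequencies span 0.5–8 Hz, matching the filter passband so no
  scalogram row is structurally empty.
* **Center frequency.** The pseudo-frequency of scale *a* is
  f = f_c · f_s / a with f_c = (1+√13)/(4π) ≈ 0.3665 cycles. This is the
  analytic argmax over scale of the L²-normalised wavelet's response to a
  pure tone (maximise √a·|ψ̂(aω)|, giving aω = (1+√13)/2), so a 2 Hz
  sinusoid peaks at the scale row whose pseudo-frequency is nearest 2 Hz.
  A spectral-argmax definition of f_c (≈ 1/π) would displace the response
  peak by about three rows of this grid.

**RGB rendering and fusion.** Scalogram magnitudes are min–max normalised
per window to [0, 1] (making the image invariant to overall window
amplitude), resized by bilinear interpolation with a pixel-center
convention recorded in `resizeBilinear()`, and mapped through a fixed
256-level viridis lookup table — a perceptually uniform map chosen once
for determinism; nothing downstream depends on which map it is. The four
per-wavelength RGB images are stacked depth-wise into an H × W × 12
tensor; block *k* (depth 3k−2…3k) is Channel *k*, and `channelBlock()`
recovers each input image bit-exactly. The default training image side is
32 pixels (configurable; rendering supports any size), which keeps one
full desk-scale experiment in minutes on a single CPU core while leaving
the beat morphology clearly resolved.

## The regressor

The network is, per conv block: 3×3 convolution → batch normalisation →
SELU → channel attention → 2×2 average pooling, repeated three times
(default 8/16/32 channels); then the feature map is read as a sequence
along its time (width) axis with the height collapsed by average pooling;
then a two-layer bidirectional LSTM; then two dense layers emitting
(SBP, DBP) jointly.

Interpretation choices, each made once and configurable:

* **Channel attention** is squeeze-and-excitation: global average pool →
  bottleneck of ratio r (default 8, clipped to keep at least one unit) →
  sigmoid gate, so every weight lies strictly in (0, 1) and gating is
  purely multiplicative.
* **The self-normalising activation** is SELU (λ ≈ 1.0507, α ≈ 1.6733),
  whose defining property is self-normalisation of activations.
* **The CNN→recurrent bridge** treats scalogram columns as time steps —
  after three 2×2 pools a 32-pixel-wide image gives a 4-step sequence —
  with per-step features equal to the channel vector of the
  height-pooled map.
* **The head is joint**: one network predicts both pressures; per-target
  models can be trained by slicing the labels.
* **Variants.** `single` consumes one wavelength's 3-channel image;
  `four_branch` builds four weight-independent conv stacks and splices
  their per-step features before the shared recurrent stage; `fused12`
  consumes the 12-channel tensor directly.

All forward and backward passes are implemented in the package as BLAS
matrix products (shifted-product convolution, batched gates for the
LSTM), and a finite-difference gradient check over every parameter tensor
of every variant is part of the test suite (worst relative error below
10⁻⁴). Targets are standardised per output during optimisation using the
training labels' mean and SD — with raw mmHg targets and MAE loss the
initial gradients would be dominated by the intercept — and predictions
are mapped back to mmHg.

## Training protocol

Adam at learning rate 0.001 with mean absolute error loss; the data are
partitioned 80/20 and 10-fold cross-validation is defined over the 80 %.
The partition is a function of the subject ids and the seed only, so the
four per-wavelength views of one cohort receive identical index sets, and
all three trial variants share the same held-out subjects at a given
seed.

* **Split level.** The default is subject-disjoint (`"record"`): all
  windows of a subject land on one side. Overlapping 5 s windows of one
  record are nearly duplicates, so window-level splitting leaks the test
  set into training; the permissive `"window"` mode is kept for protocol
  comparison only.
* **Cross-validation role.** The fold loop is diagnostic — final metrics
  always come from the untouched 20 %. Because the fold loop multiplies
  the training cost elevenfold without changing the held-out evaluation,
  `trainConfig(run_cv = )` defaults to `FALSE`; enabling it returns one
  metric row per fold.
* **Schedule.** Defaults are 40 epochs at batch size 32, long enough that
  both the fused and the single-wavelength variants approach their
  respective error floors (at short schedules shared optimisation error
  masks the information difference between variants) while a full
  fused-tensor run on the default synthetic study (below) stays under ten
  minutes on one CPU core. Early stopping is not used.

## The synthetic study

`simConfig()` emulates the acquisition protocol: 200 Hz, 60 s per
subject, four channels. Each beat is a two-Gaussian pulse — a systolic
wave of unit amplitude and a dicrotic wave delayed by the notch delay —
the simplest shape with a controllable dicrotic feature; channel *k*
scales amplitude by its gain and offsets the dicrotic/systolic ratio by a
strictly increasing gradient (deeper wavelengths, stronger dicrotic
wave), plus independent per-channel jitter. Baseline wander
(0.08–0.25 Hz, below the passband) and white noise are added. About 41 %
of subjects (matching the study population's 66/162) are drawn from a
hypertensive morphology regime with a higher dicrotic ratio.

Labels are an affine function of heart rate, the across-channel mean
dicrotic ratio, the cross-channel contrast (Channel 4 minus Channel 1
ratio) and the notch delay, plus Gaussian noise (default SD 2 mmHg,
settable to 0), censored into the configured ranges and rounded to whole
mmHg as a cuff would report. Two properties of this link are deliberate:

* the channel-mean ratio is estimated better from four channels than from
  one (the jitter averages out), and the contrast is *invisible* to any
  single channel — so multi-wavelength fusion has a genuine, quantifiable
  information advantage, mirroring the depth-distinct-information
  rationale for multi-wavelength sensing;
* the mapping is affine with known coefficients, which makes parameter
  recovery well-posed: a correctly wired pipeline must beat the
  mean-predictor baseline by a wide margin on a noise-free cohort.

Reproducibility is counter-based: each subject's record is generated from
a seed derived from (cohort seed, subject index), so a subject's data do
not depend on the cohort size.

What the generator does **not** emulate: real pulse morphology classes,
motion artifacts, arrhythmia, sensor saturation, or any physiological
hemodynamic model. Passing the synthetic study shows the pipeline is
wired correctly and that fusion exploits cross-channel information; it
says nothing about accuracy on real patients.

**Problem sizes.** The packaged study uses 60 subjects, 5 s windows
sliding by 3 s (19 per record, 1140 images in total) and 32×32 images
with the default schedule, chosen as the package's desk-scale default;
the dense 56-window cut and larger images are a `stride`/`imgSize`
argument away.

## Evaluation conventions

* **SD is the population form** (divide by n), so RMSE² = ME² + SD² holds
  exactly — the identity that makes published per-channel metric tables
  internally consistent (e.g. √(0.58² + 8.72²) = 8.74).
* **R²** is the standard 1 − SSE/SST with SST about the mean of the
  reference values.
* **AAMI** pass requires |ME| < 5 mmHg and SD < 8 mmHg, both strict.
* **BHS grading** uses inclusive thresholds (≤ 5/10/15 mmHg;
  A = 60/85/95, B = 50/75/90, C = 40/65/85, else D), assigning the best
  row whose three thresholds are all met. Grading is monotone: appending
  a zero error can never lower the grade.
* **Bland–Altman** limits are ME ± 1.96·SD of the differences.

## Degenerate inputs and numerical edges

Constant signals are rejected by `normalizeSignal()` (no variance to
scale); an all-equal scalogram renders as a uniform image at the colormap
origin rather than erroring; batch-norm variance is clamped at zero
before the ε-stabilised inverse square root; the MAE subgradient uses
`sign(0) = 0`; quality screening may reject every window of a record, in
which case the record simply contributes nothing and a warning names it.

## Known limitations

* The network is deliberately small; it is a desk-scale implementation of
  the architecture class, not a tuned clinical model.
* Single-CPU training: no GPU path, no data-parallelism.
* The CWT is computed per window per channel without caching across
  overlapping windows.
* Bland–Altman limits assume approximately normal differences; with the
  bimodal synthetic cohorts the 95 % interpretation is approximate.
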