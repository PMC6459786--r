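---
title: "Classifying artifacts and pathology in intracranial EEG: methods and design"
author: "ieegnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying artifacts and pathology in intracranial EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intracranial EEG (iEEG) recorded during presurgical evaluation of
drug-resistant epilepsy mixes the activity of interest with non-cerebral
contamination: muscle and movement artifacts, machine noise, power-line
interference.  At the same time the recordings contain pathological
transients — interictal spikes, often carrying high-frequency
oscillations (HFOs, ripples at 80–250 Hz and fast ripples at
200–600 Hz) — that share broadband, transient morphology with many
artifacts.  Any automated artifact detector intended to support HFO
analysis must therefore distinguish artifacts from pathology rather than
merely from quiet background, and it must do so per channel, because
contamination is electrode-specific.

`ieegnoise` addresses this as supervised classification of 3-s,
single-channel segments (15,000 samples at the 5 kHz pipeline rate) into
four classes: *physiological iEEG*, *pathological iEEG*, *power-line
noise* (50 or 60 Hz, kept as a class rather than filtered out), and
*non-cerebral artifact*.  A sliding-window detector turns the segment
classifier into channel-by-second probability maps over continuous
recordings.

## Feature construction

Each segment is transformed into a 5 × 15,000 matrix
(`buildFeatureMatrix()`):

* row 1 — the raw trace low-passed at 900 Hz;
* rows 2–5 — *envelograms*: the squared magnitude of the analytic signal
  of the trace bandpass-filtered at 20–100, 80–250, 200–600 and
  500–900 Hz.  These bands cover beta through high-gamma activity,
  ripples, fast ripples and very fast ripples, as well as the broadband
  signature of muscle artifact.

All filters are 3rd-order Butterworth designs applied forward and
backward (`zeroPhaseFilter()`), giving zero net phase shift and an
effective 6th-order magnitude response; zero phase matters because the
envelope rows must stay aligned with the raw row.  "Analytic signal" is
the signal plus *i* times its Hilbert transform; its squared magnitude is
the standard instantaneous-power envelope.  (The magnitude of the Hilbert
transform alone oscillates at the carrier frequency and is not an
envelope.)  Each row is z-scored with the population standard deviation;
a constant row maps to zeros.  Z-scoring removes absolute amplitude,
which varies by orders of magnitude across electrodes and acquisition
systems.

Filtering is delegated to the `signal` package (`butter`/`filtfilt`),
wrapped with odd-reflection padding of about three time constants of the
lowest band edge (capped at the segment length).  Forward–backward IIR
filtering needs padding much longer than the filter order at a 20 Hz
band edge and 5 kHz sampling; three time constants suppresses the edge
transient to below the tolerances used in the tests.

Acquisition-rate data are brought to the 5 kHz pipeline rate by
`antialiasDownsample()`: a zero-phase Bartlett–Hanning-windowed sinc FIR
low-pass at 1 kHz, followed by exact decimation when the ratio is an
integer and linear interpolation on the band-limited signal otherwise
(after a 1 kHz low-pass, interpolation error at the 32 kHz source rate
is far below the 1% passband tolerance).

## The classifier

The classifier (`buildModel()`, `CNNClassifier`) is a one-dimensional
convolutional network that treats the five feature rows as input
channels of a time-axis convolution — the rows are heterogeneous signals,
not a spatial dimension, so a 2-D "image" convolution across rows would
be meaningless.  Each block is convolution → batch normalization → ReLU
→ non-overlapping max pooling; four blocks are stacked and followed by
dropout on the flattened features, one hidden dense layer and a softmax
output.

Default architecture: blocks of 8/16/32/32 filters, kernel length 9,
pooling 6 (15,000 → 2,500 → 416 → 69 → 11 time steps), a 128-unit dense
layer, dropout 0.5, L2 penalty 1e-4 — about 61,000 parameters.  The
defaults were chosen so that the full synthetic training task runs in
minutes on one CPU core while preserving the block pattern; every value
is exposed in `modelConfig()`.  Parameter count stays far below the 5 M
"desk-trainable" ceiling.

The numerical core (convolution and pooling forward/backward) is
C++ (RcppArmadillo, im2col + GEMM) running in single precision; batch
normalization, dense layers, softmax and the optimizer are part of the
same fused C++ step.  Gradients are verified against finite differences
in the test suite.

## Training and early stopping

`trainModel()` minimises cross-entropy plus the L2 penalty with Adam
(base learning rate 1e-3, batch 32 — the optimizer is a free choice and
is exposed in `trainConfig()`).  After every epoch the validation loss is
computed in a forward-only pass: weights are bit-identical before and
after validation.  Training stops when validation loss has failed to
improve by at least `earlyStopMinDelta` for `earlyStopPatience`
consecutive epochs, or at `maxEpochs` (default 25), and the weights of
the best validation epoch are restored — returning a model from after
the decline would contradict the point of stopping.  The min-delta
refinement exists because batch-norm running statistics keep drifting
(and hence validation loss keeps creeping) long after real learning has
stopped.

`splitDataset()` splits stratified per class: validation and test counts
are floored, the remainder goes to train, assignment is a seeded
shuffle.  So 100 segments at 70/30 give exactly 70/30, and at 4/4/92
exactly 4/4/92.

## Transfer learning

A *generalized model* (GM) is trained on three classes — physiological,
pathological, artifact — excluding power-line noise, whose frequency
differs between sites (50 Hz EU, 60 Hz US).  `transferRetrain()` adapts
the GM to a new site and class set: the final softmax layer is replaced
by a fresh normal-initialised layer (mean 0, sd 0.01) sized to the new
class set, and retraining proceeds with the transferred layers' learning
rate set to 10% of the final layer's rate (`transferLrFraction`).  The
idea is that the convolutional feature extractor transfers across
acquisition systems while the decision layer is site-specific.

## Sliding-window detection and probability matrices

`classifyRecord()` slides the classifier along each channel with 3-s
windows at a 1-s stride (2-s overlap), assigning each window's
probability vector to its centre second, so no short event can fall
between windows.  A recording of duration *T* yields a channels ×
floor(*T*) × classes probability array; the first and last seconds have
no centred window and replicate the nearest centred column (the
alternative — leaving them unclassified — complicates every downstream
consumer for no benefit).  A trailing fraction of a second is dropped.
Channels are processed independently; permuting channels permutes matrix
rows and nothing else.

The artifact probability matrix (APM) and pathology probability matrix
(PPM) are binarisations of the same array for one target class at a
strict threshold (cell = 1 iff probability > 0.95).  `extractEvents()`
performs connected-component labelling along time: maximal runs of
supra-threshold seconds become events, runs shorter than a minimum
duration are discarded, and each event records its peak probability.
More elaborate morphological post-processing is intentionally out of
scope.  `renderMatrix()` rasterises a matrix with one pixel per
channel-second, blue background and yellow detections.

## The synthetic generator

Clinical iEEG cannot be redistributed, so the package ships a seeded
generator (`genDataset()` and friends) that emulates the four classes:

* **Background** (all classes): 1/f-amplitude ("pink") noise with a
  per-segment spectral slope (amplitude exponent 0.8–1.4), slow
  amplitude modulation (0.1–0.5 Hz, ±30%) and a white sensor-noise
  floor that is occasionally elevated ("noisy contact").  Absolute
  amplitude is arbitrary; z-scoring removes it.
* **Physiological**: background plus 2–4 oscillations at 8–30 Hz;
  occasionally blunt biphasic sharp transients *without* an HFO (benign
  sharp activity), and brief gamma/low-ripple bursts (60–140 Hz,
  50–300 ms) that are sometimes centred on a transient.
* **Pathological**: 1–5 biphasic spikes (40–120 ms, variable polarity
  and amplitude with a weak tail) each carrying a Gaussian-windowed
  oscillation at 100–240 Hz centred on the spike peak — a spike with a
  riding HFO.  The first spike's ripple amplitude has a higher floor so
  every pathological segment contains at least one detectable event.
* **Line noise**: background plus a 50 or 60 Hz sinusoid with small odd
  harmonics; amplitude varies several-fold across draws.
* **Artifact**: one of three families — a sustained broadband (>100 Hz) noise
  burst of 0.5 s up to the full segment (muscle), a baseline jump larger than ten background
  standard deviations (movement/discontinuity), or a large clipped
  transient (machine saturation).

Event amplitudes are scaled by `artifactSNR` (default 2.5 × the
background standard deviation) with wide per-event jitter.  The default
was calibrated during development so that the classes are clearly
learnable at a few hundred segments per class yet genuinely confusable —
physiological gamma bursts on sharp transients abut weak
spikes-with-HFO, mirroring the physiological/pathological ambiguity that
dominates error patterns on real recordings.  At very high SNR every
class is trivially separable and small-sample experiments saturate; at
very low SNR the weak-event tail becomes invisible to any method.

What the generator deliberately does **not** emulate: spatial
correlation across channels, ictal (seizure) patterns, reference-montage
artifact propagation, electrode drift, and real annotator disagreement.
Consequently, passing the synthetic tests demonstrates that the pipeline
is implemented correctly and that training, transfer and detection
behave as designed — it does not certify clinical performance, which can
only be assessed against expert-annotated recordings.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere (samples in annotation
  tables, seconds in probability matrices).
* Reported recall/PPV/F1 are truncated, not rounded, to two decimals
  (`truncate2()`); full precision is always retained alongside.  Macro
  averages are unweighted means of the unrounded per-class values.
* The network computes in single precision; training losses are
  reproducible to well below 1e-6 for a fixed seed, and evaluation is
  deterministic (dropout off, batch-norm running statistics).
* All randomness flows through explicit seeds; generation and training
  save and restore the caller's RNG state.
* Checkpoints are RDS files storing architecture, weights, batch-norm
  statistics and the class order; loading a checkpoint whose class list
  contradicts its output layer is a version error.

## Problem sizes used in the checks

The test suite trains the default model on 300 train / 100 validation /
100 test segments per class (four classes, epoch cap 25, median of three
seeds) for the classifier-quality property, and compares transfer
learning against from-scratch training at 30 segments per class
(three seeds) starting from a three-class generalized model trained on
150/50 segments per class.  These sizes keep a full run on one CPU core
in the tens of minutes while leaving the properties informative; they
are hundreds of times smaller than a clinical corpus, which is exactly
why the transfer comparison uses a small-sample regime.

## Known limitations

* The acceptance-scale properties are stochastic; they hold for the
  seeded conditions in the tests, with margins, but individual seeds of
  the 30-segment comparison can favour either arm.
* EDF support covers the common equal-rate, 16-bit case; per-channel
  sampling rates are rejected rather than resampled.
* The detector assumes the model's 3-s window and 5 kHz rate; data at
  other rates must go through `antialiasDownsample()` first.
* Training is single-core by design; there is no GPU path.
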