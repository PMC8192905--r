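---
title: "Methods: automated scoring of mouse sleep stages from one EEG channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated scoring of mouse sleep stages from one EEG channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scoring problem

Rodent sleep studies score polysomnographic recordings in consecutive 10-s
epochs, assigning each epoch one of the stages Wake, NREM, pre-REM, REM, or
marking it as artifact. Wake shows low-amplitude broadband EEG, NREM is
dominated by 0.5–4 Hz delta waves, REM by rhythmic 7–8 Hz theta, and pre-REM
— the transitional stage between NREM and REM — by short (< 10 s)
spindle-like high-amplitude bursts over an emerging theta rhythm. Manual
scoring is slow and subject to inter-rater variability; `premscore`
implements an automated scorer: a one-dimensional convolutional network that
maps three consecutive epochs of a single EEG channel to the stage of the
middle epoch.

The two class modes mirror common practice. In the extended 5-class mode all
five labels are scored. In the standard 3-class mode pre-REM epochs are
reinterpreted as NREM and artifact epochs are removed, leaving Wake, NREM,
REM.

## Preprocessing

Signals are low-pass filtered at the native rate with a 4th-order
Butterworth filter (critical frequency 25.6 Hz) applied forward and
backward, so the net phase response is zero and the magnitude response is
the squared single-pass response; the filtered signal is then downsampled to
64 Hz by linear interpolation and cut into 10-s epochs of 640 samples.
Filtering precedes resampling to prevent aliasing; epoching after resampling
avoids the non-integer epoch length that native rates such as 992.06 Hz
would produce. Numerical details that the package fixes explicitly:

* **Zero-phase edge handling.** The signal is padded with an odd reflection
  of length `3 * (order + 1)` before each pass. Start-up transients decay
  within a few filter time constants, so the magnitude contract is stated
  (and tested) on interior samples.
* **Resampling grid.** Output sample `k` (0-based) interpolates the input at
  time `k / fs_out`, anchored at `t = 0`; the output length is
  `floor((n - 1) * fs_out / fs_in) + 1`.
* **Context windows.** The classifier input is the concatenation of epochs
  `k - 1, k, k + 1` (1920 samples at 64 Hz). For the first and last epoch
  the missing neighbour is replaced by a replicate of the edge epoch, so a
  prediction exists for every scored epoch and hypnograms stay aligned; this
  boundary rule is this package's choice, since scorers viewing a
  three-epoch context at the recording edge have no canonical convention.

## Network

The feature extractor applies 8 valid (no-padding) convolutional layers of
96 kernels of length 5, with strides alternating 1 and 2. Each block is
conv → ReLU → batch norm, with dropout on every second block (the stride-2
blocks); the input time series is batch normalized before the first
convolution. The per-layer output lengths on 1920-sample input are 1916,
956, 952, 474, 470, 233, 229, 113, so the flattened feature vector has
113 × 96 = 10 848 entries. The classifier applies dropout, a fully
connected ReLU layer of 80 units with dropout, and a softmax output layer of
3 or 5 units; the predicted stage is the argmax, ties broken towards the
lowest class index.

Reconstruction notes, encoded as tests: with "same" padding the final length
would be 120, and stride-first orderings give 109 — only valid convolutions
with the stride pattern (1, 2, 1, 2, 1, 2, 1, 2) reproduce the flattened
width of 10 848, which fixes the padding convention. The exact dropout
placement among the convolutional blocks and the learnable input
normalization are under-determined by the width bookkeeping alone; the
package places dropout on blocks 2, 4, 6, 8 and uses a learnable
scale-and-shift input batch norm, and documents both as package choices.

Batch norm uses biased batch variance, `eps = 1e-5`, and running statistics
with momentum 0.1 (used verbatim at inference). The feature-extractor
arithmetic runs in single precision by default — the standard choice for
convolutional networks — with a double-precision path retained for
verification; the test suite checks the analytic gradient of the full
double-precision network against central finite differences, and the
agreement of the two precisions on forward passes.

## Training protocol

The loss is the mean negative log-likelihood of the true stage with an L2
penalty `lambda / (2 N_b) * sum(w^2)` over connection weights only (biases
and batch-norm parameters are exempt; the batch-norm exemption is a package
extension of the bias rule). Probabilities are clamped at `1e-12`.
Optimization uses minibatch Adam (`beta1 = 0.9`, `beta2 = 0.999`,
`eps = 1e-8`) after clipping the global gradient norm at `theta = 0.1`.

The learning rate follows a warm-up/cool-down protocol, parameterized per
sample and scaled by the minibatch size `N_b = 256`: linear warm-up from
`1e-7 * N_b` at epoch 1 to `1e-6 * N_b` at epoch 12, then exponential
cool-down `1e-6 * N_b * exp(-0.06 * (i - 12))`. The schedule is applied per
training epoch (the protocol is stated in epochs; a per-step variant would
differ only within the warm-up and is not used). Training runs for at least
12 and at most 50 epochs and stops early when the validation macro F1 has
not strictly improved for 5 consecutive epochs, counted from the best epoch;
the weights of the best epoch are returned. "Improvement" means a strict
increase over the running best — the alternative (resetting the counter on
any non-decrease) is not used.

**Class rebalancing.** Before every training epoch a fresh index multiset is
drawn: for each class, `round(target * N)` indices (rounding half away from
zero) sampled with replacement from that class's windows, keeping the total
at `N`. Two profiles ship with the package: `reb1`
(Wake 30 %, REM 18 %, NREM 24 %, pre-REM 14 %, artifact 14 %) for the
5-class mode and `reb2` (Wake 41 %, REM 25 %, NREM 34 %) for the 3-class
mode. Under `reb1` on a 366 720-window training set the per-class counts are
110 016 / 66 010 / 88 013 / 51 341 / 51 341; the published table prints
110 017 for Wake, a one-unit discrepancy that no standard rounding rule
reproduces together with the other four cells, so the package documents it
and matches the four consistent cells.

**Augmentation.** Four stochastic transforms, each drawn fresh every time a
window enters the network, applied in the order amplitude → sign flip →
window warping → time shift:

* amplitude: `s * (1 + a_a * u)`, `u ~ U[-1, 1)`;
* sign flip: `-s` if `u < a_s`, `u ~ U[0, 1)` (montage/polarity invariance);
* window warping: a temporary window of length `T* = floor(T (1 + a_f u))`
  sharing the original centre is resampled linearly back to `T`, shifting
  frequencies by `T*/T`;
* time shift: the window slides by `dt = floor(T a_t u)` source samples
  while the label stays fixed.

All strengths default to 0 (off). The defining draws are explicit arguments
of the unit operators, so each formula is testable deterministically; the
composite injects RNG draws only at the top. Design choices: samples beyond
the recording bounds (warping, shifting) replicate the edge sample, which
avoids the spectral artifacts of zero padding; the draw interval is the
half-open `U[-1, 1)` for all three bipolar draws (the closed-interval
variant differs with probability zero); and the time shift composes at the
source-index level (the shift moves the window, warping then resamples
around the shifted centre), which reduces exactly to each unit operator when
the other is disabled. Augmentation applies to training windows only, never
at evaluation.

## Evaluation

`confusion()` builds the count matrix (rows = true) and both
normalizations: by actual label frequency (diagonal = recall) and by
predicted label frequency (diagonal = precision). Per-class F1 is the
harmonic mean of precision and recall, defined as 0 when both are 0; macro
F1 averages over classes present in the true labels — absent classes have
undefined recall and are excluded rather than imputed. `markov_matrix()`
counts stage-to-stage transitions (self-transitions included) within each
recording, never across recording boundaries, and row-normalizes. Matrices
are reported in the conventional order Wake, REM, NREM, pre-REM, artifact.

## Synthetic data generator

The original recordings are not redistributable, so the package generates
stage-labeled surrogate data carrying exactly the structure the classifier
must exploit:

* a Markov hypnogram whose default transition matrix encodes the
  physiological cycle (Wake ↔ NREM, REM entered almost exclusively via
  pre-REM, REM exiting mostly to Wake, rare artifacts from any state) and
  whose stationary distribution approximates typical laboratory class
  frequencies (Wake ≈ 55 %, NREM ≈ 37 %, pre-REM ≈ 2 %, REM ≈ 5.5 %,
  artifact ≈ 0.25 %); the entries are synthetic design values, fixed once;
* per-stage signals: pink (1/f) background noise everywhere — a realistic
  EEG spectral floor obtainable without extra dependencies — plus a
  band-limited, slowly amplitude-modulated oscillation (delta for NREM,
  theta for REM), Hann-enveloped 10–15 Hz spindle bursts with a reduced
  delta background and a theta component for pre-REM, and clipped biphasic
  spike transients for artifact epochs;
* the native rate defaults to 992 Hz, an integer stand-in for amplifier
  rates near 1 kHz, so the anti-alias/resampling path is always exercised.

What the generator does **not** emulate: EMG, scorer label noise and
inter-rater disagreement, gradual stage transitions inside epochs,
inter-subject spectral variability, and 1/f slope variation. Passing tests
therefore demonstrate that the implementation learns and scores correctly
on spectrally well-separated data; they do not certify real-data F1 levels,
which depend on exactly the nuisances listed above. As a floor on fixture
quality, the test suite checks that a linear discriminant on log band powers
already separates the three standard stages at ≥ 90 % accuracy — the
convolutional network is given a learnable problem, not an impossible or a
trivial one.

## Reduced-scale experiment sizes

The end-to-end checks train the full architecture at a reduced scale chosen
once: 4 synthetic subjects at 992 Hz — two of 1600 epochs (4.4 h) for
training (3200 windows), one of 600 epochs for validation and one for
testing — minibatches
of 128, no dropout (runs this short do not overfit), a compressed
learning-rate schedule (2-epoch warm-up from `1e-6` to `1e-5` per sample,
cool-down rate 0.3), and at most two training epochs per run. The
compression keeps the shape of the full protocol while matching its step
budget to the smaller problem: the full-scale schedule assumes thousands of
minibatch updates per epoch, whereas these runs make 25, so the per-sample
peak rate is raised tenfold. The 3-class run is compared against a held-out
macro F1 of 0.80; the 5-class rebalanced run's pre-REM F1 is compared
against the first-epoch pre-REM F1 of a no-rebalancing baseline, mirroring
the qualitative observation that rebalancing accelerates minority-class
learning.

## Known limitations

* The EDF writer covers the package's own needs (single channel, rates
  expressible as an integer number of samples over a ≤ 60 s record); the raw
  float32 + JSON dialect is the lossless interchange format.
* Training is CPU-only; at full published scale (≈ 367 k windows, up to 50
  epochs) a run would take days. The package targets method correctness and
  desk-scale experiments, with every size a config value.
* Markov post-processing of predictions, EMG channels, and event-level
  statistics are out of scope.
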