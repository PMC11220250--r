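---
title: "The encoding kernel: additive time decomposition inside EEG CNNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The encoding kernel: additive time decomposition inside EEG CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enkit)
```

## The problem

Convolutional networks classify EEG epochs well, but plain convolutions are
translation-invariant along time: a kernel responds to a waveform the same
way whether it occurs at 100 ms or at 700 ms. Many EEG phenomena are
*time-locked* — the P300 deflection peaks near 300 ms after a rare target,
cognitive-conflict negativity appears at 150–250 ms frontally — so a purely
convolutional feature space discards exactly the information that
distinguishes the classes. The encoding kernel (EnK) is a small trainable
layer, inserted after the first convolution of a standard EEG CNN, that
re-injects absolute-time information by decomposing the signal additively
into three components, in the spirit of classical time-series decomposition
(trend/seasonal/remainder).

## The layer

For a signal tensor `X` with time index `t = 0, ..., k-1`, the layer owns a
per-time-step affine transform with weights `w_t` and biases `b_t`,
broadcast over batch, feature-map and channel axes:

```
Z_t = w_t * X_t + b_t                 (pre-activation)
P_t = sin(Z_t)                        (periodic component)
S_t = Z_t * P_t                       (seasonal component)
A   = X (*) K                         (artifact component)
```

`(*)` is a sliding 2-D cross-correlation over the (channel, time) plane with
an `l x m` kernel `K`, zero-padded so the output keeps the input shape
(stride 1, no kernel flip, `m` odd so the time padding is symmetric; row
padding splits as floor/ceil when `l` is even). The combined output is

```
Y_t = Z_t              for t = 0
Y_t = P_t + S_t + A_t  for t >= 1
```

Because `w_t, b_t` are indexed by absolute time, every feature the layer
produces carries positional information; the sine bounds the periodic term
in `[-1, 1]`, and `|S_t| <= |Z_t|` since `|P_t| <= 1`. The layer is
shape-preserving, so it can be spliced between any two layers of a host
network without disturbing downstream geometry.

Design points that the component definitions leave open, and how this
package resolves them:

* **Shared affine.** The periodic and seasonal components are written with
  the same symbols `w_t, b_t`; the default is one shared affine
  (`shared_affine = TRUE`), with an option to learn separate affines for
  the seasonal term. With the shared affine an EnK layer adds `2k + l*m`
  trainable values; one parameter set per layer, not per feature map.
* **Parameter granularity.** `w_t, b_t` are scalars per time step, broadcast
  across channels and feature maps.
* **The `t = 0` sample.** The two branches of the combination overlap at
  `t = 0`; the affine-only branch wins, so position 0 receives `Z_0` and no
  artifact contribution. (Whether the artifact component should also reach
  position 0 is not decidable from the definitions; this choice is pinned
  and tested.)
* **Artifact term as a sliding window.** Written literally, the artifact sum
  produces a single scalar; it is interpreted here as the column of a
  sliding-window cross-correlation, which is the reading that makes `A_t`
  well-defined at every `t` and reduces to the scalar form for a window
  centered at `t`.
* **Axis convention.** The decomposition operates along the time axis (the
  last tensor axis). The source description is ambiguous between "vertical"
  and "horizontal" convolution; operating along time is the only reading
  under which per-time-step weights encode temporal position, which is the
  layer's stated purpose.
* **Initialization.** Near-pass-through: `w = 1`, `b = 0`, `K` the uniform
  averaging kernel `1/(l*m)`. An untrained EnK then perturbs the host
  network as little as possible. Default kernel `l = 1, m = 7`: time-only
  smoothing, consistent with the artifact term's denoising intent;
  configurable.

All EnK parameters train by backpropagation. The backward pass is exact
(hand-derived; `d/dZ [P + S] = cos(Z)(1 + Z) + sin(Z)` for the shared
affine) and is verified against central finite differences at relative
tolerance `1e-4` in the test suite, together with a scalar triple-loop
oracle of the whole decomposition at absolute tolerance `1e-6`.

## Host architectures

Four baseline classifiers are provided, re-implemented compactly on a small
functional layer framework (conv/batch-norm/ELU/pool/dropout/dense, with an
Rcpp convolution kernel): EEGNet-8,2 (temporal kernel 64, depthwise spatial
filter with depth multiplier 2, separable block, pools 4 and 8),
ShallowConvNet (40 filters, temporal kernel 25, square → 75/15 average pool
→ log), DeepConvNet (four blocks of 25/50/100/200 filters, kernel 10,
max-pool 3) and a recurrent convolutional network. The recurrent model is
specified in its source only loosely ("five recurrent convolution layers");
here it is five weight-shared recurrent convolution layers of three
iterations each (`h_i = relu(conv(x, Wf) + conv(h_{i-1}, Wr))`), with
max-pools after the second and fourth layer — documented as an
interpretation. A `scale` multiplier shrinks filter counts for small-scale
experiments without changing topology. The EnK is inserted immediately
after the first (temporal) convolution; enabling it changes no downstream
layer shape and adds exactly `2k' + l*m` parameters, `k'` being the time
length at that point.

Filter counts not stated by the comparison study (EEGNet's F1/F2, the
recurrent model's kernel sizes) follow the architectures' original
publications or, where those are silent, small canonical defaults.

## Training protocol

`train_config()` encodes the evaluation protocol: stratified 60/20/20
train/validation/test split, Adam at learning rate 0.001, at most 200
epochs, early stopping after a patience of 20 epochs on validation loss,
restoration of the best-validation weights (batch-norm running moments are
restored along with them), batch size in [2, 16] (default 16) and dropout
in [0.15, 0.75] (default 0.25). The split allocates `floor(fraction * n)`
epochs per class per partition and gives the remainder to training. One
master seed derives the split, the weight initialization and the per-epoch
batch orders, so a with/without-EnK pair (`compare_enk()`) differs *only*
in the EnK layer.

Two choices the protocol description leaves open:

* **MSE for classification** is computed between one-hot labels and softmax
  probabilities, averaged over epochs and classes. F1 is the plain positive
  -class F1 for two classes and the support-weighted mean of per-class F1
  for more.
* **Input scaling.** Epochs are standardized per channel (mean/SD estimated
  on the training split only, stored with the fitted model, applied
  consistently at prediction, evaluation and Grad-CAM time). This is the
  standard preprocessing of the host architectures' own training setups.
  It matters doubly for the EnK: with raw tens-of-microvolt inputs the
  pre-activation `Z` reaches magnitudes where `sin(Z)` oscillates over many
  periods and the layer amplifies noise instead of encoding time; after
  standardization the initialization sits in the sine's quasi-linear range.
* Training loss is softmax cross-entropy; MSE and F1 are evaluation
  metrics. Test metrics use the restored best-validation weights.

## The synthetic data

The generator (`synth_spec()`, `synth_preset()`, `synth_generate()`)
emulates the phenomenology of the evaluation datasets so the pipeline is
exercisable without any external download. Every epoch is a sum of
independent components:

* **1/f background**: Gaussian noise spectrally shaped to power ~
  `f^-exponent` (default exponent 1, SD 10 arbitrary units ~ µV);
* **ERP**: a Gaussian-profile deflection (amplitude 8, width 45 ms) at a
  latency jittered across epochs (SD 20 ms), on a target channel subset;
* **oscillation**: a Hann-windowed sinusoidal burst in a canonical band;
* **artifacts**: Poisson-count blink transients (large, slow, frontal) and
  a mains-frequency line sinusoid.

Presets: `p300_like` (positive centro-parietal deflection at 300 ms — the
midpoint of the 250–350 ms range — present only on the target class),
`conflict_like` (frontal negativity at 200 ms), `mi_like` (class-dependent
10 Hz burst amplitude, alpha band), `mrcp_like` (slow negative ramp, four
classes on different channel groups). Amplitudes were fixed once at values
typical of a clean laboratory recording (single-trial ERP of the same order
as the background SD) and define the study conditions for all seeded
experiments; class balance is exact by construction, and generation is
bit-reproducible from the spec (which embeds its seed).

What the generator does **not** emulate: volume conduction and realistic
channel covariance, non-stationary noise, inter-subject variability,
session drift, or the preprocessing idiosyncrasies of the real comparison
datasets. Passing the synthetic experiments therefore demonstrates that the
implementation is correct and that the EnK does not degrade a host network
under controlled conditions — not that the published effect sizes transfer
to real recordings.

## Interpretability

`gradcam()` adapts gradient-weighted class activation mapping to
multichannel time series: the class logit's gradient is taken at a target
layer (the EnK output by default, else the first convolution), each feature
map is weighted by the spatial mean of its gradient, and the rectified
weighted sum is max-normalized to `[0, 1]` (identically-zero maps stay
zero) and linearly resampled along time to the input length for overlay on
the raw signal (`overlay()`). Difference maps (`diff_map()`) subtract
normalized maps and are deliberately not renormalized, so they live in
`[-1, 1]`.

The package quantifies time-locality as the fraction of total heat mass
inside the ERP window, compared with the window's share of the epoch
duration. This is evaluated on the *class-average* test epoch — the
standard time-locked object of ERP analysis — because single-trial maps at
an input-resolution layer are dominated by background activity that
averaging cancels. The window is `latency ± 2(width + jitter)`, the region
in which the jittered deflection can appear.

## Numerical choices and degenerate inputs

* Convolution is cross-correlation with zero "same" padding and stride 1,
  stated bit-exactly so the loop oracle matches; pooling handles strides.
* Batch-norm uses eps `1e-5`, momentum 0.1, biased batch variance.
* The safe log activation clamps at `1e-6`; softmax subtracts the column
  maximum; cross-entropy clamps probabilities at `1e-12`.
* Max-pool ties resolve to the earliest window offset.
* A non-finite training loss aborts with the epoch/batch location rather
  than continuing.
* Degenerate Grad-CAM maps (all-rectified-to-zero) are returned as zero
  rather than renormalized.
* The epoch container stores 64-bit floats so the save/load round trip is
  lossless.

## Problem sizes

The seeded experiments are sized for a single CPU: the headline paired
comparison uses the `p300_like` preset at 400 epochs x 8 channels x 128
samples (1 s at 128 Hz), EEGNet at full width, protocol defaults; the
oracle and gradient checks use tensors up to `(4, 4, 8, 16)`; unit tests
use width-scaled models. The same sizes are used by `scripts/acceptance.R`,
which re-runs the paired experiment, the oracle and gradient checks, and
the heat-mass measurement from scratch at a caller-supplied seed.

## Known limitations

* The recurrent baseline is an interpretation of a loosely specified
  architecture; its numbers are not comparable to any published variant.
* Grad-CAM at input-resolution layers has limited spatial specificity;
  conclusions should rest on averaged maps, as above.
* The layer framework implements exactly what the four architectures need
  (stride-1 convolutions, time pooling); it is not a general-purpose
  deep-learning library.
* Group-level statistics across datasets (repeated-measures designs) are
  out of scope; the package reports paired per-run deltas only.
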