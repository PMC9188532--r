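---
title: "Methods: tree-structured single-muscle segmentation of limb MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-structured single-muscle segmentation of limb MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleseg)
```

`muscleseg` segments individual muscles on 2D MRI slices of the thigh and
lower leg. A binary classifier decides the anatomical district of a slice;
its argmax routes the full-resolution image to one of two residual
encoder–decoder networks that emit per-pixel class probabilities over 13
(thigh) or 7 (leg) classes, background included. This vignette records the
modelling choices, their rationale where the design was genuinely open, and
what the synthetic experiments do and do not demonstrate.

## The synthetic limb phantom

No patient images ship with the package, so every component is exercised on
a parametric phantom (`phantom_config()`, `generate_slice()`). Each slice
holds two elliptical limb cross-sections left and right of the vertical
midline, each with:

* a bright subcutaneous fat ring (intensity 0.90) around a muscle region
  (0.30);
* bone discs — one femur for the thigh, tibia + fibula for the leg — with a
  dark cortical rim (0.10) and bright marrow (0.80);
* `K` angular-sector muscle compartments around the bone (12 thigh, 6 leg),
  labelled 1..K identically on both sides, with per-boundary angular jitter
  so compartment shapes vary across slices.

Only muscles carry foreground labels; fat and bone belong to the background
class, because the segmentation target is the muscle belly avoiding fascia
and bone contours. Fat replacement is emulated by a patchy mixing field: a
Gaussian-smoothed noise field is centred so its mean equals the requested
`severity` in [0, 1], and muscle intensity is linearly mixed toward the fat
intensity by that field. `severity = 0` is a healthy subject; 0.6 and above
emulates severe involvement. A smooth multiplicative bias field and additive
Gaussian noise act on the image only; intensities are clipped to [0, 1]
(the acquisition protocol's intensity statistics are not published, so the
contrast is chosen for plausibility, not matched to a scanner).

The phantom reproduces the *geometric* structure the networks must learn —
multi-class adjacency, bilateral symmetry, severity-dependent contrast loss
— but not anatomy (compartments are sectors, not atlases), not MR physics
(no Dixon/spin-echo signal model) and not 3D continuity. Passing the
scaled-down experiments therefore demonstrates that the pipeline's
mechanics are correct, not that the trained weights transfer to patients.

## Mask cleanup

`clean_mask()` applies, per foreground class in ascending label order, an
area opening followed by an area closing with a 4-pixel threshold, removing
registration speckle. Three readings were open and are fixed as follows:
"threshold 4" is strict (*smaller than* 4 removed; a 4-pixel island
survives); removed islands become background rather than the nearest class,
since the filter targets specks surrounded by background; components use
8-connectivity (holes, the complement, 4-connectivity), the common default
for 2D masks and configurable. The operation is idempotent and can never
introduce a class absent from the input — both are asserted in the tests
against an exhaustive flood-fill oracle.

`downsize_for_classifier()` resizes to 128 × 128 via Catmull-Rom bicubic
interpolation after Gaussian anti-aliasing with per-axis SD
`(scale − 1) / 2`; upsampling is refused rather than silently interpolated.

## Augmentation

Four stochastic, purely geometric transform families (images bicubic,
labels nearest-neighbour) are applied in the fixed order translation →
rotation → piecewise-affine → elastic:

* **per-side translation**: offsets uniform in [−D, D] with D the side's
  shortest distance to any border, so no foreground leaves the canvas;
* **per-side rotation**: angle uniform in [−7, 7] degrees about the side's
  centroid;
* **piecewise affine**: a 4 × 4 control grid, each point displaced normally
  with SD = `scale` × size / 100, `scale` uniform in [0.1, 1] percent;
  the dense field is the bilinear interpolation of the control grid;
* **elastic**: a per-pixel random field smoothed with a Gaussian kernel
  (SD uniform in [5, 10]) and scaled by a strength uniform in [0, 20].

Two bookkeeping choices were open. "A random subset of the sequence" is
read as independent inclusion of each family with probability 0.5
(configurable); and the 5000-pair target contains only transformed copies —
originals are not force-included (an `include_originals` flag exists). The
pool of `target_count` pairs (default 5000) is split disjointly into
⌈0.9 N⌉ training and the remaining validation pairs. Sides are located by
intensity thresholding over the border background level plus hole filling;
slices whose limbs touch raise a side-split error, which the builder logs
and survives by skipping the per-side families for that draw. Out-of-canvas
pixels after warping become 0 in the image and background in the labels,
matching the networks' zero padding.

## Weight maps

The segmentation loss weights every pixel by
`w(x) = w_l(x) + w0 · exp(−(d1 + d2)² / (2σ²))` with `w0 = 10` and σ = 7
(thigh) / 8 (leg), σ representing the maximum distance between neighbouring
muscles. Choices fixed here:

* `w_l` is the inverse class frequency over the training set, normalized so
  the background weight is 1 — the formula mixes `w_l` with the absolute
  constant `w0`, so a scale convention is required; normalization is
  configurable.
* `d1`, `d2` are exact Euclidean distances to the nearest and
  second-nearest *distinct muscle classes* (background excluded), computed
  with per-class exact distance transforms (Felzenszwalb–Huttenlocher);
  tests verify exact agreement with an O(N²) brute-force search.
* The border term is evaluated at every pixel, not only background: inside
  large muscles it is negligible by the Gaussian tail, and the formula as
  written carries no mask. With fewer than two muscle classes the term is
  identically zero (`d2` undefined ⇒ +∞), the only consistent limit.
* Weight maps are computed per training slice *after* augmentation, since
  warping changes border geometry.

## Networks

Both architectures are built from residual blocks following the scheme
Convolution – Batch Normalization – Skip Connection – Activation: the
block's first convolution (kernel `k1`, stride `s1`) acts, after batch
normalization, as the shortcut for the residual map formed by two
subsequent 3 × 3 stride-1 convolutions. All convolutions use zero ("same")
padding so spatial size depends only on stride; weights are initialized
from a Glorot normal distribution.

* **Classifier** (input 128 × 128): five contracting blocks, channels
  32 → 512, spatial 128, 64, 32, 16, 8. Features "collected into a vector"
  from all depth levels are realized as global average pooling per level,
  concatenated (32+64+128+256+512 = 992 features) into a dense two-way
  softmax — pooling is the natural reading compatible with a fixed-length
  vector.
* **Segmenter** (input 432 × 432): six contracting blocks (strides
  1,2,2,2,2,3; spatial 432, 216, 108, 54, 27, 9; channels 32 → 1024) and
  six expanding blocks with transposed convolutions mirroring the
  contracting kernels/strides, halving channels per level
  (1024 → 512 → … → 32 → 32) and concatenating the same-resolution
  contracting features; the last expanding block works at full resolution
  without a skip (its partner feature map is already consumed one level
  below). A final 1 × 1 convolution maps 32 channels to the class count,
  followed by a pixelwise softmax.

Two published details are ambiguous and resolved as follows. The sixth
block's printed receptive fields (188/284/380) are consistent with a
kernel-4, stride-3 downsampling convolution — which also realizes the
stated 1/3 downsampling — whereas the block label's literal kernel 3 would
give 172/268/364; kernel 4 is the default and the literal variant is
available (`block6_kernel = 3`). The activation nonlinearity is unstated;
rectified linear units are used. The receptive-field recursion
`r_i = r_{i−1} + (k_i − 1) j_{i−1}`, `j_i = j_{i−1} s_i` is verified against
an empirical gradient-support oracle on an all-linear copy of the first two
blocks.

## Loss, metrics, optimization

The weighted cross-entropy is a *sum* over the pixels of each image,
averaged over the mini-batch, so the learning-rate scale is independent of
batch size; probabilities are floored at 1e−7 before the logarithm. Dice is
`2TP / (FP + 2TP + FN)` per class; reported "mean Dice" averages over
foreground classes present (classes absent from both maps are skipped —
the background class is excluded, since it would otherwise dominate every
score). Optimization is AMSGrad (β₁ = 0.9, β₂ = 0.999, Keras-style bias
correction) with L2 regularization added to kernel gradients only
(`reg · θ`; biases and normalization parameters are not decayed), dropout
on the input layer (the stated placement; unusual, hence configurable),
and a plateau schedule that halves the learning rate after 4 epochs
without validation-loss improvement. Training aborts with a diagnostic on a
non-finite loss. Hyperband uses η = 3 (the standard default, not stated),
budgets of 20 epochs at batch size 5, and scores configurations by the
validation metric; surviving configurations resume from their checkpoints.
Per-epoch training loss and metric are the running averages accumulated
over the epoch's mini-batches (the convention of mainstream deep-learning
toolkits, and the one behind published training curves); validation is
evaluated in inference mode at epoch end.

## Inference

Slices are min-max normalized to [0, 1] per slice before either network
(the acquisition normalization is unpublished; min-max is the simplest
convention consistent between training and inference). The classifier's
argmax follows the one-hot convention (1,0) = thigh, (0,1) = leg; an exact
tie resolves deterministically to the lowest index (thigh). Arbitrary
input sizes are center-padded/cropped with zeros to the segmenter's
configured size and the label map is mapped back to the input geometry.
Volumes are processed slice-wise along the third NIfTI axis with per-slice
routing and, when ground truth is supplied, per-slice mean and per-class
Dice in the report.

## Problem sizes in the shipped experiments

The test suite runs everything at phantom scale, chosen so the full suite
completes comfortably on a single CPU while still exercising the genuine
training dynamics: phantoms at 64 × 64; the augmentation-bookkeeping
experiment builds the full 5000-pair set from 20 sources; the district
classifier is trained at width 1/8 on 200 slices (100 per district,
severity 0–0.8) for 8 epochs and must reach categorical accuracy 1.0 on 50
held-out slices; the training-behaviour experiment overfits a width-1/2
leg segmenter on 8 slices for 30 epochs (batch 2, lr 0.0075) and must show
mean training Dice above 0.8 with at least 80% increasing epoch-to-epoch
transitions. The leg district is used for that experiment because its
larger compartments make the Dice trajectory informative at 64 × 64, where
thigh sectors shrink to a few dozen pixels. These reproduce the reference
behaviour (perfect district classification; overall monotone Dice growth)
qualitatively at reduced scale; they say nothing about patient-scale Dice.

## Known limitations

* Sector phantoms cannot probe anatomical shape priors or inter-subject
  variability; conclusions are about pipeline correctness.
* The expanding-path internals are an informed reconstruction (mirrored
  transposed convolutions); other decoders consistent with the block
  notation exist.
* Training is single-threaded CPU R/Armadillo; reference-scale
  (432 × 432, full width) training is possible but slow, and no GPU path
  is provided.
* PNG I/O quantizes intensities to 8 bits; NIfTI is the canonical format.
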