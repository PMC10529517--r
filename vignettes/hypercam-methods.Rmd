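---
title: "Weakly supervised fracture localization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised fracture localization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most clinical fracture datasets carry only an image-level label — fracture
or no fracture — because drawing boxes around lesions costs expert time.
`hypercam` trains a binary classifier from such labels alone and then asks
the trained network *where* it looked: gradient-weighted class activation
maps (Grad-CAM) are thresholded into predicted fracture boxes, so
localization comes for free from classification supervision. An optional
coordinate-regression head covers the complementary regime where boxes
*are* available for part of the data.

## Model

### Attention gating (CBAM)

Each backbone tap `F` (a `C x H x W` feature map) is gated twice.

Channel attention pools `F` globally by mean and by max, passes both
`C`-vectors through a shared two-layer bottleneck MLP (hidden width
`ceiling(C/r)`, ReLU in between, no biases, reduction `r = 16` by default),
sums the two outputs and applies a sigmoid:

    M_c(F) = sigma( W1 relu(W0 avg(F)) + W1 relu(W0 max(F)) )

Spatial attention pools the (channel-gated) map across channels by mean
and max, stacks the two `H x W` maps, convolves with a single 7x7 kernel
(padding 3, with bias) and applies a sigmoid. The gates multiply the
feature map sequentially — channel first, then spatial — so every
attention value lies strictly in (0, 1) and gating can only attenuate:
`max |cbam(F)| <= max |F|`. The hidden activation of the MLP is ReLU and
the two pooling branches share their MLP weights; the spatial branch uses
no MLP (the printed form of the spatial formula in some descriptions
includes one, but the accompanying definition of the concatenated
`[avg; max]` input does not, and we follow the latter).

### Hypercolumn fusion

A backbone is a sequence of stages, one per spatial-resolution drop; the
reference desk-scale backbone used throughout the tests has four stages of
(stride-2 3x3 conv, BN, ReLU, 3x3 conv, BN, ReLU) with 16, 32, 64 and 128
channels, so a 64x64 input yields taps at 32, 16, 8 and 4 pixels. Each tap
passes through its own CBAM bank, is resampled bilinearly (half-pixel
centres, no corner alignment) to the *highest-resolution* tap's size, and
the results are concatenated along channels into the hypercolumn — 240
channels in the reference configuration. Stacking at the highest
resolution follows from the fusion idea itself: upsampling the coarse
layers preserves the fine layer's detail, whereas downsampling the fine
layer would discard exactly the spatial precision the method exists to
keep. CBAM is applied before upsampling (the cheaper order; a tap is
gated at its native resolution).

The classification head concatenates global average and global max
pooling of the hypercolumn (a `2 * 240` vector), applies one fully
connected layer and a sigmoid. With `with_coords = TRUE` a parallel
linear head emits four sigmoid outputs interpreted as normalized corners,
canonicalized by min/max so `x_min <= x_max` always holds. The
coordinate head reads the shared pooled vector *plus* each hypercolumn
channel's activation centroid (the activation-weighted mean position, in
normalized coordinates — well-defined because the hypercolumn is
non-negative downstream of ReLU and the attention gates). Sharing only
the pooled vector was the first design tried, but globally pooled
magnitudes are position-invariant by construction: a head reading them
can represent *whether* a fracture pattern is present, not *where*, and
at desk scale the positional leakage through convolution padding is far
too weak to regress corners. The centroids add exactly the missing
first-order location information at the cost of `2 x 240` extra inputs
to one linear layer.

### Grad-CAM and box extraction

The class score for attribution is the pre-sigmoid logit — near-saturated
probabilities would otherwise shrink every gradient. For a chosen layer
(default: the hypercolumn itself, the final fused convolutional map), the
channel weight is the spatial mean of the score's gradient; the weighted
channel sum is rectified (negative evidence should not light up the map;
a flag retains the signed variant), upsampled bilinearly to the input
size, and min–max normalized to integers 0–255. A spatially flat surface
normalizes to all zeros and is flagged degenerate rather than raising an
error, because a confident non-fracture image can legitimately produce a
flat map.

Boxes are the tight bounding rectangles of 8-connected components above
threshold 230 (the "squares above threshold" of the box-prediction rule,
read as rectangles around contiguous hot zones, which is what published
overlay figures show), dropping components smaller than 4 px, ordered by
component peak. The first box is the primary prediction.

## Preprocessing

* **CLAHE stack.** Four CLAHE renditions at clip limits {1, 2, 3, 4}
  (ascending, 8x8 tile grid) are stacked behind the untouched image into a
  five-channel input. The limits are a monotone mild-to-strong ladder; the
  method fixes only that there are four of them plus the original.
* **Otsu bone crop.** Otsu's threshold is computed on the strongest CLAHE
  rendition (the most bone/background-separated channel of the stack); the
  largest 8-connected above-threshold component — a rule that ignores
  text burns and markers common in radiographs — defines the foreground
  box, which is cropped and rescaled to fill the frame. The affine
  transform is returned so ground-truth boxes survive the crop; it
  round-trips exactly up to the final frame clipping.
* **Augmentation.** Rotation uniform in [-30, 30] degrees (exposed corners
  filled with the image minimum so no bright artifact attracts the
  attention maps), horizontal flip and gray-level inversion each with
  probability 0.5, and mix-up with Beta(0.01, 0.01) mixing weights — at
  that alpha nearly every draw is within 0.01 of 0 or 1, so mixed samples
  stay close to one parent while labels interpolate exactly.
* **Pipeline order** is crop, then CLAHE stack, then augmentation; the
  source protocol does not fix the order and each step is exposed
  separately, so any other composition can be assembled.

## Training protocol

Defaults: 120 epochs, batch 32, Lion optimizer (`beta1 = 0.9`,
`beta2 = 0.99`, no weight decay — the optimizer's canonical constants, as
the protocol names the optimizer without hyper-parameters), binary
weighted cross-entropy with `auto` class weights (inverse class frequency
normalized to mean 1, so balanced data gives unit weights), initial
learning rate 1e-4, multiplied by 0.1 on plateau. "Ten iterations without
improvement" is read as ten *epochs* without a new strict minimum of the
validation loss; the first epoch sets the baseline and counts as
non-improving, so a frozen loss drops the rate at epoch `patience + 1`.
Mix-up is applied to a batch with probability 0.5. When the coordinate
head is active, its Smooth L1 loss (delta = 1) is computed only on
box-bearing positives, and only on un-mixed batches — an interpolated
label has no single box to regress.

## The synthetic phantom generator

Real wrist radiographs cannot ship with a package, so every stage is
exercised on synthetic phantoms: a randomly oriented, edge-smoothed
bright capsule ("bone") on a darker background with additive Gaussian
noise (sd 6 gray-levels). With probability `fracture_fraction` a dark
transverse line of 2–5 px interrupts the bone at a random interior point —
a compact, CAM-localizable stand-in for a cortical discontinuity — and
the ground-truth box is that line's mask dilated by 3 px, mirroring expert
boxes that include surrounding cortex. Two styles bracket the regimes of
the public collections the method targets: `mura_like` (low-contrast bone
over part of a near-black frame, no reliable box annotations in the real
counterpart) and `grazped_like` (wider, higher-contrast bone filling the
frame, with boxes). Output is 8-bit, matching the 0–255 heatmap
convention.

What the phantoms do *not* emulate: anatomy (carpal bones, joints,
overlapping structures), scanner artifacts, soft tissue, multi-fracture
images, or the label noise of clinical reads. Passing tests on phantoms
therefore demonstrates that the machinery — attention, fusion, CAM
extraction, training — is correct and that the method can localize a
compact lesion it was never told about; they say nothing about clinical
performance, which in the source protocol requires full-scale backbones,
pretraining and the real datasets.

The generator is calibrated so that a trivial intensity-variance score
(variance of the normalized foreground of a 32x32 downsample) separates
fracture from non-fracture phantoms with AUC > 0.8 in the box-annotated
(`grazped_like`) style — a floor guaranteeing that the learning tasks the
test suite poses are winnable. The low-contrast `mura_like` style is
deliberately harder, as its clinical counterpart is.

## Problem sizes and numerical choices

The test suite and the acceptance script train the reference backbone on
400 phantoms at 64x64 (300/100 train/validation split, 20 epochs) — the
package's study-scale configuration, chosen so a full run executes on one
CPU core in minutes while still reaching validation AUC above 0.9. These
runs use an initial learning rate of 5e-4 rather than the protocol
default of 1e-4: twenty epochs of ten minibatches are only two hundred
Lion steps, and Lion's sign updates move each weight by at most `lr` per
step, so the full-scale rate is an order of magnitude too small for a run
this short. The `train_config()` default remains 1e-4, the full
protocol's value. Under the faster rate the phantom classifier relies
visibly on the fracture itself: its Grad-CAM boxes overlap the true
fracture several times better than a random-box baseline, which is the
property the localization tests assert.
Numerical details: probabilities are clamped to [1e-7, 1 - 1e-7] inside
the cross-entropy; batch-norm uses eps 1e-5 and momentum 0.1 with running
statistics for evaluation; He-style Gaussian initialization throughout;
degenerate metric denominators (no predicted positives, single-class AUC,
both-raters-constant kappa) return 0 / error with an explicit flag rather
than NaN; all randomness is driven by explicit seeds threaded from the
configuration objects, and a fixed seed reproduces datasets bit-identically
and training runs exactly.

## Known limitations

* The hand-rolled network is deliberately desk-scale; the backbone
  contract accepts deeper stacks, but no pretrained weights are shipped.
* Grad-CAM boxes inherit the resolution of the chosen layer; at the
  default hypercolumn resolution (half the input side) very small lesions
  produce coarse boxes.
* The primary-prediction rule scores only the strongest component, so
  multiple fractures in one image are evaluated against the best-matching
  truth box only — the same single-lesion orientation the binary training
  signal induces.
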