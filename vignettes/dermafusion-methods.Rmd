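---
title: "DermaFusion: model, preprocessing and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DermaFusion: model, preprocessing and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

DermaFusion classifies dermoscopy images into the seven HAM10000/ISIC2018
lesion classes — actinic keratosis (Akiec), basal cell carcinoma (Bcc),
benign keratosis (Bkl), dermatofibroma (Df), melanoma (Mel), melanocytic
nevus (Nv) and vascular lesions (Vasc), indexed 0–6 in that order
throughout. This vignette explains the model, the preprocessing pipeline,
the synthetic data the package tests itself on, and the design decisions
taken where the architecture family under-determines a choice.

## The two-stream model

Two convolutional feature extractors see the same 224×224×3 image:

* **DenseNet-121 stream.** A 7×7/2 stem convolution and 3×3/2 max pool,
  then four dense blocks of 6/12/24/16 bottleneck pairs
  (BN–ReLU–1×1 conv, BN–ReLU–3×3 conv) with 0.5-compression transition
  layers. Blocks 1–3 use growth rate 32. Block 4 uses growth rate 16, so
  the block ends at 512 + 16·16 = 768 channels and the stream emits a
  7×7×768 map natively. The published stage table for this architecture
  prints exactly the shapes this trunk produces (56×56×256, 28×28×512,
  14×14×1024, 7×7×768); a standard growth-32 fourth block would end at
  1024 channels instead, which is inconsistent with that table, so the
  reduced-growth final block is the coherent reading.
* **Residual VGG-16 stream.** The five canonical VGG-16 conv blocks
  (2,2,3,3,3 convolutions at 64,128,256,512,512 channels, 2×2 max pool
  after each) with one wrap-around skip connection per block: an identity
  mapping when the channel counts match, a 1×1 projection otherwise,
  merged by elementwise addition followed by ReLU. A final 1×1
  channel-matching convolution brings the 7×7×512 map to 7×7×768. The
  published block-by-block channel listings for this stream are internally
  inconsistent (consecutive rows disagree by factors of 2–3); we keep the
  canonical VGG-16 widths — the stream the design starts from — and use
  the 1×1 channel-matching device (which the architecture already uses in
  its skip paths) only at the output. All widths are arguments of
  `buildResidualVggStream()` / `assembleModel()`.

Both streams end FC-free at 7×7×768, so channel concatenation yields
7×7×1536.

### Fusion head

The concatenated map passes through a **multireceptive-field block**:
parallel 3×3, 5×5 and 7×7 same-padded convolutions capture lesion
structure at several scales, their outputs are concatenated, and a closing
1×1 convolution + ReLU restores 1536 channels. Each branch sits behind a
1×1 channel reduction, the standard Inception-style bottleneck for
multi-kernel blocks. The branch widths are nowhere printed for this
architecture; the only quantitative constraint the source tables give is
the total trainable parameter count, 19.70 M. With the streams fixed
(5.61 M + 15.28 M) we size the default reduction/branch width at 64 so the
full model lands at 21.84 M, within the published figure's sanity band;
a plain, reduction-free block of any conventional width (e.g. 512 per
branch) would add 60 M+ parameters and contradict that figure by a factor
of several. `branchChannels`/`reduceChannels` expose the choice.

**GeM pooling** then reduces 7×7×1536 to a 1536-vector: per channel $k$
with spatial activation set $X_k$,

$$H^{(g)}_k = \Big(\tfrac{1}{|X_k|}\sum_{x \in X_k} x^{p}\Big)^{1/p},$$

the $p$-power mean. $p = 1$ is average pooling and $p \to \infty$ max
pooling (we follow this standard convention; the source text swaps the two
limits in one passage and we treat that as a typo). $p$ is a single scalar
shared across channels, fixed rather than learned; the published exponent
sweep peaks at $p = 4$, the package default. A guard of $\varepsilon =
10^{-6}$ is added to the (post-ReLU, hence nonnegative) activations before
exponentiation to keep gradients finite at exact zeros. A dense
1536→7 layer and softmax complete the classifier.

### Why the engine is in the package

No deep-learning framework is a dependency: the graph engine
(conv/BN/pool/GeM/softmax forward and backward, Adam) is implemented in
Rcpp/RcppArmadillo with float32 tensors and im2col+GEMM convolutions. The
backward pass is validated against central finite differences on a graph
containing every layer type (`test-engine.R`), and training is
deterministic for a fixed seed and thread count.

## Preprocessing

* **Resize**: bilinear, to 224×224, no aspect-ratio padding (the source
  images are 600×450).
* **Hair removal**: ITU-R 601 grayscale → morphological black-hat
  (closing − image) with a 17×17 box structuring element → threshold at
  10/255 → fast-marching inpainting. The element size, threshold and
  inpaint radius are nowhere specified by the source; 17 px captures
  hairs thinner than ~8 px at 224² while a flat region gives an exactly
  zero response. Inpainting fills masked pixels in increasing distance
  from the mask boundary with inverse-square-distance weighted averages of
  known neighbours — the fast-marching order — and never touches unmasked
  pixels. Note an intrinsic property of thresholded black-hat: any *large*
  dark region (a lesion) produces a response ring up to one element-width
  inside its boundary, so hair-detection quality is scored on plain-skin
  hair fields where stroke ground truth is unambiguous; on lesion images
  the measured quantity is instead the inpainting error reduction over
  true hair pixels.
* **Augmentation**: six operations in fixed order — random rotation
  (±180°), horizontal/vertical shift (±10%), zoom (0.9–1.1), shear
  (±10°, our reading of "random transforming" in the standard
  augmentation taxonomy), flips (p = 0.5 each) and resize — composed into
  one centre-anchored affine map with reflection padding and a single
  bilinear resampling. Ranges are unspecified by the source; these
  defaults are the common Keras-style choices and are config-exposed.
* **Split**: stratified 7:2:1 per class, seeded shuffle, largest-remainder
  rounding. The published per-class division deviates slightly from exact
  70/20/10 (its rounding rule is unstated), so `splitDataset()` accepts a
  per-class override table (`isicSplitCounts()`) that reproduces the
  printed counts verbatim — column totals 7020/1998/997.
* **Balancing**: every class except the largest (Nv) is expanded to its
  published target by augmented copies assigned round-robin over the
  class's originals (per-original multiplicity differs by at most one)
  with fresh deterministic seeds; the published targets sum to 34946. The
  published expansion factors are not integer multiples of the six
  operations; round-robin with per-copy random parameter draws is our
  reading.

## Training protocol

Adam (the source names no optimizer) on softmax cross-entropy; batch 16;
initial learning rate 1e-4 decayed ×0.1 on a validation-loss plateau
(patience 3; the source says only "after a period of training"); early
stopping after 5 non-improving epochs; 28-epoch cap; best-validation
weights restored. "No change for five consecutive times" is read as no
improvement of the monitored loss. Because training runs are short, the
batch-norm running statistics are recalibrated at each epoch's end by one
momentum-1 forward pass over a training batch; this makes evaluation-mode
activations (validation metrics, Grad-CAM, the service) faithful to the
trained network and keeps the restored-best-weights invariant exact.
Without a validation set the training loss is monitored and final weights
are kept — the overfitting regime used by the smoke tests.

## Synthetic dermoscopy generator

Real ISIC2018 data is optional everywhere; the generator provides seeded,
byte-identical images with controllable class signal:

* background skin tone drawn from a plausible RGB range with mild value
  noise;
* one elliptical lesion per image (single-label task), with sinusoidal
  boundary perturbation scaled by a per-class irregularity, value-noise
  texture scaled by a per-class amplitude, and a per-class colour centre
  (Mel very dark brown, Nv medium brown, Vasc red-purple, …);
* optional hair: quadratic Bézier strokes, width 1.5–3 px, intensity
  30–80/255, drawn anti-aliased with an exact ground-truth mask.

Class counts can mirror the published imbalance (`isicScaledCounts()`).
The generator emulates colour, border and texture *statistics*, not
photorealistic dermoscopy: no rulers, gel bubbles, ink marks, multi-focal
lesions or calibrated colour. Tests passing on it show the pipeline's
mechanics (signal recovery, bookkeeping, optimization, localization), not
clinical performance; the published headline accuracies require the real
dataset and GPU-scale training and are out of scope by design.

## Evaluation

One-vs-rest precision, recall, F1 and accuracy per class on the percent
scale (macro = unweighted class mean; micro = pooled counts, which for
single-label data collapses to overall accuracy — asserted on every
report); zero-denominator conventions report 0 with a flag. ROC curves by
threshold sweep per class, AUC by trapezoid (equal to the Mann–Whitney
statistic), micro by pooling all sample-class decisions, macro as the mean
of defined per-class AUCs. Grad-CAM weights a convolutional map's channels
by spatially averaged logit gradients, rectifies, upsamples and normalises
to [0, 1]. The default target is the two-stream output map (the
concatenation of the backbone streams): in overfitting experiments on
synthetic data its maps localize the lesion reliably, and it is the
"output feature map" of the two-stream design; the post-fusion layer or
any other convolutional node can be selected with `layer =`.

## Desk-scale problem sizes

The test-suite and the acceptance script exercise the full 224² two-stream
model on an 8-image two-class overfitting problem (batch 4, learning rate
1e-3, cap 200 epochs) — small enough for a single CPU, large enough that
memorization plus Grad-CAM localization on the lesion is a meaningful
end-to-end check. Unit tests use reduced inputs (32²–64²) and a small
stand-in classifier where only bookkeeping, not capacity, is under test.

## Known limitations

* The engine is single-threaded apart from BLAS and tuned for desk-scale
  runs, not production training.
* Per-channel (or learned) GeM exponents are not implemented; `p` is one
  scalar.
* The service's HTTP layer is out of scope; `classifyImage()` returns a
  JSON-serialisable record any front end can wrap.
* Published headline numbers (91.24% accuracy, per-class AUCs, the
  confusion matrix) are reproducible only with the real ISIC2018 download
  and GPU-scale training; the package reproduces the *procedures* and the
  printed-table arithmetic exactly, and validates mechanics on synthetic
  data.
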