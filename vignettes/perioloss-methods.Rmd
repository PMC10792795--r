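---
title: "Measuring periodontal bone loss on molar crops: models and methods"
author: "perioloss authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring periodontal bone loss on molar crops: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perioloss)
```

## The measurement problem

Radiographic periodontal bone loss (PBL) is the standard severity index of
periodontitis. On a molar, it is measured per anatomical side (mesial and
distal) from three landmarks: the cementoenamel junction (CEJ), the most
coronal point of the alveolar crest, and the root apex. With root length
$A = \lVert \mathrm{CEJ} - \mathrm{apex} \rVert$ and bone height
$B = \lVert \mathrm{crest} - \mathrm{apex} \rVert$ (Euclidean pixel lengths),

$$\mathrm{PBL}\,(\%) = \frac{A - B}{A} \times 100,$$

and the periodontal stage follows the classification bands: stage 1 below
15%, stage 2 from 15% to 33% (both boundaries inclusive, because the
neighbouring bands are strict), stage 3/4 above 33%. PBL is a ratio of
lengths, so the computation stays in pixel space; no physical calibration is
needed, and the result is invariant to a common rescaling of image and
coordinates. A predicted crest falling outside the CEJ-apex span would push
the percentage outside $[0, 100]$; such predictions are clamped.

`perioloss` automates this measurement on rectangular molar crops from
panoramic radiographs via a three-component pipeline, and reproduces the
associated rater-evaluation statistics.

## Component 1: the statistical keypoint prior

The six landmarks of a crop form a 12-vector of coordinates normalized by
crop width and height. For each of the 12 coordinate slots, `fitPrior()`
fits every candidate family — normal, log-normal, beta, gamma, uniform,
logistic — by maximum likelihood and ranks them by a histogram
sum-of-squares criterion: the squared difference between the empirical
histogram density (100 equal-width bins over the sample range by default)
and the fitted density at the bin midpoints. The minimizer per slot is
retained, giving 12 one-dimensional probability functions. Sampling all 12
simultaneously (`samplePrior()`) yields a purely statistical keypoint
prediction that knows the anatomy's typical layout but nothing about the
individual image.

Choices worth stating explicitly:

* **Independence.** Coordinates are fitted and sampled independently; no
  covariance or copula structure is modelled.
* **Uniform MLE.** The maximum-likelihood uniform support is the sample
  range; it is computed analytically because a numeric optimizer does not
  find this boundary solution.
* **Family identifiability.** The ranking criterion selects a *density*,
  not really a *family*: a symmetric beta with large shape parameters is
  numerically indistinguishable from a normal on the unit interval, and on
  normally distributed data the winner between the two is decided by
  histogram noise. Family-recovery checks in the test-suite therefore use
  generators that no other candidate can mimic (a uniform with interior
  support); when the family label itself matters, restrict `candidates`.
* **Degeneracy and clamping.** Zero-variance slots are stored as a
  point-mass pseudo-family with fit error 0. Samples are clamped to
  $[0,1]$ rather than rejected, since rejection could loop indefinitely
  under a badly fitted tail.

The prior doubles as data augmentation: `augmentTrainingSet()` pairs every
training crop with `k` prior samples (default `k = 25`, the value used in
the original training recipe). The recipe's own arithmetic is internally
inconsistent — 25 samples per image over its stated training-image count
does not equal its stated total of 10,050 pairs, which corresponds to 402
images — so `k` is a parameter rather than a constant here.

## Component 2: the convolutional refiner

The refiner conditions the statistical prediction on the actual image. Its
input is a 7-channel tensor (`encodeInput()`): the standardized image
resized to a fixed `inputHeight x inputWidth` (aspect distortion is
accepted because keypoints are stored normalized), plus six Gaussian
heatmaps ($\sigma$ = `heatmapSigma` pixels) centred on the prior keypoints.
Heatmaps keep the prior spatially aligned with the image, which is what a
convolutional architecture can exploit; the documented alternative —
concatenating the prior vector after pooling — was rejected because it
prevents the convolutions from seeing image and prior jointly.

The network (`buildRefiner()`) is an entry-flow style stack of
depthwise-separable convolution blocks: each block applies two separable
3x3 convolutions, halves the resolution with 2x2 max pooling, and adds a
1x1 stride-2 convolution shortcut from the block input. After the last
block, *global moment pooling* summarizes each feature map by its mean mass
and its mass-normalized spatial centroid $(\sum F \cdot x / \sum F,\;
\sum F \cdot y / \sum F)$ — a soft-argmax. The same moments of the 7 input
channels are concatenated as an input-level residual, and a 12-unit linear
head emits the refined vector. Plain global average pooling was measured to
discard nearly all location information at this depth (a linear readout of
average-pooled random conv features explains about 20% of keypoint
variance, versus above 99% for input moments), which would contradict the
refiner's purpose; moment pooling is still a global pooling but keeps the
quantity being regressed linearly accessible.

The pooled features are batch-normalized before the head — mean mass and
centroid features live on very different scales, and normalizing them is
what makes the head trainable within a few epochs (the architecture family
this network belongs to normalizes activations throughout); inference uses
running statistics accumulated during training, so predictions stay
deterministic. Dropout (default rate 0.5) applies to every block output
and to the normalized pooled features, never to the output head.

Training (`trainRefiner()`) minimizes the mean squared error between the
12-dimensional output and the true vector with Adam (default learning rate
0.001, batch size 32, global gradient-norm clipping at 5), for at most
five epochs under early stopping (patience 2 epochs of non-improving
validation MSE; the weights of the best validation epoch are restored, so
a late unstable epoch cannot degrade the returned model). Validation examples
are held out at the image level so augmented copies of one image never
straddle the split. Slots belonging to unlabelled sides are masked out of
the loss, so partially labelled molars remain usable. Training is
bit-for-bit reproducible from `config@seed`, which drives initialization,
shuffling and dropout.

## Component 3: geometric staging

`measureMolar()` applies the PBL formula above to each side independently
after denormalizing by the crop dimensions. The crest is *not* projected
onto the root axis — the measurement lines are exactly the segments drawn
between landmarks. Degenerate sides (missing landmarks, or root length
under one pixel) are flagged `valid = FALSE` without affecting the other
side. Stage 3/4 is a single category (`"34"`), exactly as the evaluation
treats it.

## Rater evaluation

`evaluateRater()` scores an answer sheet against a truth sheet per
`(item, side)`. Each item is binarized one-vs-rest over the three stages
(`binarizeStage()`), pooled into per-stage TP/TN/FP/FN counts, and
converted to sensitivity, specificity, precision, F1, and the joint
positive-and-negative success rate $(TP+TN)/\mathrm{total}$. The source
tables call that last quantity "recall"; it is conventionally accuracy, so
the package names it `accuracy_recall` to avoid colliding with
recall-as-sensitivity. Ratios of the form $0/0$ are reported as 0,
matching the printed `0.000` convention for raters who never used a class.

Averages come in three flavours: macro (unweighted mean over stages),
weighted (by true-class support proportion), and micro (metrics of the
pooled counts; micro sensitivity equals plain multiclass accuracy). The
published weighted-average rows of the study this pipeline models are not
reproducible from its per-stage table under support weighting (or any
standard weighting we could identify), so weighted values are reported but
not used as reference checks.

Rater calibration uses the two-way random-effects, absolute-agreement,
single-rater intraclass correlation — ICC(A,1) — computed from the two-way
ANOVA mean squares. The exact ICC form behind the published 0.91 is not
stated there; absolute agreement is the defensible choice for repeated
labelling by one observer, and the implementation is verified against
variance-component simulations with known ground truth.

## The synthetic generator

Clinical radiographs and rater sheets are not redistributable, so
`generateDataset()` renders stylized two-rooted molar crops with exactly
known geometry: a bright crown and two divergent roots composited
additively over a darker background, and an alveolar bone band whose top
edge passes through the two crest keypoints. The crest keypoint is placed
*on* the CEJ-apex segment at bone-height fraction $1 - \mathrm{PBL}/100$,
so the emitted keypoints realize the target percentage exactly and the
stage label is unambiguous. Per-side severities are sampled with
correlation 0.7 (bone loss is correlated across a tooth) inside per-stage
PBL bands that keep a 2-point margin from the 15/33 boundaries, so
rendering noise cannot flip a label. The default stage mix 57.14% / 35.71%
/ 7.14% reproduces the severity imbalance reported for the study's test
items (48/30/6 of 84 under exact allocation). Upper-jaw crops (default
fraction 0.5) are emitted apex-up, so the orientation step has real work.

Noise/exposure realism is limited to additive Gaussian noise (default SD
0.03 intensity units), Gaussian blur (0.8 px) and contrast jitter (±15%
gain). The generator does not emulate superimposed anatomy, restorations,
caries or other obstructive factors, nor panoramic distortion — so passing
synthetic tests demonstrates geometric and statistical correctness of the
pipeline, not clinical performance on real radiographs.

## Desk-scale experiment sizes

The test-suite and the acceptance script exercise the complete pipeline at
sizes chosen to run on a single CPU in minutes, stated here as the
package's own experimental design:

* **End-to-end run** (`runPipeline()` defaults): 400 generated crops (300
  train / 100 held out), 3 blocks with 8/16/32 filters, 32x24 inputs,
  heatmap $\sigma$ = 2 px, `k = 12` prior samples per image, batch 16,
  learning rate 0.005, dropout 0.1, five epochs. The learning rate and
  dropout differ from the original GPU-scale recipe (0.001, 0.5) because
  this run takes roughly a tenth of its optimization steps; with the
  original values the run is undertrained at this scale. At inference the
  prior is sampled five times per test image and the refined predictions
  are averaged — the prior is stochastic by construction, and ensembling
  over its draws is the pipeline's natural inference — while the baseline
  stages the raw prior samples themselves. The pipeline earns its keep by
  beating that baseline on held-out stage accuracy and keypoint error.
* **Learnability check**: when the true vector is made identical to the
  prior encoded in the heatmaps, the network must recover it almost
  exactly (validation MSE below $10^{-3}$); this uses a longer schedule
  (60 epochs, learning rate 0.03) than the five-epoch default, again
  because of the reduced step budget at desk scale.

## Known limitations

* The refiner is a compact CPU-scale network; no attempt is made to
  reproduce the original GPU-scale architecture's capacity or its exact
  validation loss (never published).
* The prior treats coordinates as independent; correlated anatomy (e.g.
  root length linking CEJ and apex) is only captured by the refiner.
* Family labels from `fitPrior()` are not identifiable between
  near-equivalent candidates (see above); the fitted density is.
* The generator's stylization means synthetic performance numbers say
  nothing about real panoramic radiographs; the evaluation module applies
  unchanged to real answer sheets.
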