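---
title: "Attention-based multiple instance learning for multi-magnification slide classification"
author: "attmil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multiple instance learning for multi-magnification slide classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attmil)
```

## The problem

Whole-slide images (WSIs) are gigapixel scans of stained tissue. Clinically
useful labels — tumor present/absent, histological subtype, response to a
drug — exist at the level of the slide, while the informative morphology
occupies a small fraction of its area. Annotating that morphology patch by
patch is the expensive step this package avoids: it treats each slide as a
*bag* of 224×224 patch *instances* and learns from slide-level labels alone.
Under standard multiple-instance (MIL) semantics a bag is positive if and
only if at least one of its instances is positive.

`attmil` implements the full weakly supervised workflow: entropy-based
background removal during tiling, per-magnification attention-MIL bag
classifiers, a mean-pooling ensemble across magnifications (20x, 10x, 5x),
stratified 5-fold cross-validation with best-model selection, and evaluation
with stratified bootstrap confidence intervals. A synthetic-data module
generates both multi-scale slide images with planted lesions and
feature-space MIL bags with known ground truth, so the entire pipeline is
exercisable and testable without any clinical data.

## The model

Each instance (patch) $k$ of a bag is encoded as a feature vector
$h_k \in \mathbb{R}^d$. The attention module scores it through a tanh
projection to 128 dimensions and a learned scoring vector $w$:

$$a_k = \frac{\exp\{w^\top \tanh(V h_k + b_V) + b_w\}}
             {\sum_j \exp\{w^\top \tanh(V h_j + b_V) + b_w\}},$$

giving nonnegative weights that sum to one. The bag feature is the
attention-weighted sum $z = \sum_k a_k h_k$ — a convex combination of the
instance features, so the bag function is invariant to instance order and to
duplicating the bag. A bag-level MLP (one ReLU hidden layer of width 128,
then a two-class softmax) maps $z$ to probabilities $p = (p_-, p_+)$, and
training minimizes the cross-entropy $-\log p_{y}$ of the slide label $y$.
The un-gated tanh attention is implemented as stated; the gated (sigmoid
branch) variant is deliberately not added. Bias terms are included in the
projection, the scoring layer and the MLP, which is standard practice; the
score bias $b_w$ cancels in the softmax and is kept only for completeness.

Gradients are computed analytically (softmax-attention Jacobian, pooling,
ReLU mask, softmax/cross-entropy) and verified against central finite
differences to a relative error below $10^{-4}$ in the test suite.
Optimization is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) with the L2 weight-decay term added to the gradient.

### Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 1e-4 | Adam step size |
| `weight_decay` | 1e-5 | L2 coefficient added to the gradient |
| `iterations` | 500 | optimizer update steps |
| `batch_bags` | 64 | bags per update step |
| `attn_dim` | 128 | attention projection width |
| `hidden` | 128 | bag-MLP hidden width |
| entropy threshold | 5 bits | tiles strictly below are background |
| tile size | 224 px | non-overlapping grid |
| decision threshold | 0.5 | on the ensemble probability |

"Iterations" is interpreted as optimizer update steps, not epochs
(`iteration_unit = "epochs"` switches the reading; both are supported
because the term is genuinely ambiguous). A batch of 64 bags is processed
one bag at a time with gradient accumulation, so a "batch size" of 64 whole
slides never has to be resident at once. Model selection across the five
folds uses validation AUC — the headline metric of this kind of study —
rather than validation loss.

## Tiling and the entropy filter

Images are cut on a 0-based, half-open grid into non-overlapping 224×224
tiles; partial edge tiles are discarded (padding them would create
background-dominated instances). The background statistic is the Shannon
entropy, base 2, of the 256-bin histogram of the 8-bit luminance channel
(0.299 R + 0.587 G + 0.114 B) — the standard image-entropy convention,
bounded in [0, 8] bits so the threshold of 5 is meaningful: a blank region
scores near 0, a texture using many gray levels scores well above 5. Tiles
with entropy *strictly below* 5 are excluded; exactly 5.0 is retained.
Whether entropy should be computed per channel and with how many bins is
not canonical; grayscale with 256 bins is the convention adopted here and
both the statistic and the threshold are explicit function arguments.

Normalization (per-channel mean and variance, one set per magnification) is
fitted on the **training split only** and then applied everywhere.
Fitting it on all slides at once would leak test-set statistics into
training; because the fitting function takes an explicit tile list, that
literal all-slide behavior remains available by passing every tile, but the
pipeline never does.

Augmentation (flips, 90° rotations, additive Gaussian noise,
brightness/contrast jitter, random crop-and-resize) fires each transform
independently with probability 0.5. Magnitudes (noise sd 5/255, jitter
±10%, crop scale 0.8–1.0) are mild defaults — the operation names are
standard but no canonical magnitudes exist — and all are configurable.

## Encoders

The instance encoder is a pluggable contract. `encoder_passthrough()`
accepts precomputed feature matrices; `encoder_custom()` adapts any
user-supplied per-tile embedder (e.g. a pretrained CNN exported from another
framework); `encoder_smallconv()` is the bundled image encoder — three 3×3
convolution + ReLU + 2×2 mean-pool blocks followed by global average
pooling to d = 64. Its weights are seeded random projections and stay
frozen: random convolutional features are a well-established lightweight
baseline, encoding becomes a deterministic one-off featurization (bags are
encoded once, not once per training step), and the MIL head — the part this
package is about — remains the only trained component. Pretrained backbone
weights are deliberately not bundled; the contract is encoder-agnostic.

## Multi-scale ensemble

One model is trained per magnification (20x, 10x, 5x) on bags from the same
slides under a shared slide-level split, so no slide is ever in training at
one scale and in test at another. At inference the three positive-class
probabilities are mean-pooled:
$p_{\text{ens}} = (p_{20x} + p_{10x} + p_{5x})/3$, and the slide is called
positive when $p_{\text{ens}} \ge 0.5$. The mean is a convex combination,
so the ensemble probability always lies within the range of the per-scale
probabilities. No per-scale calibration is applied before averaging. A
missing magnification is a hard error by default; an explicit
`missing_scale = "mean-available"` policy averages what is present and
flags the slide.

## Evaluation

AUC is computed through the Mann–Whitney identity with midrank tie handling
(0.5 per tied pair), verified in the tests against exhaustive pair
enumeration and against an established ROC implementation. Accuracy, FPR
= FP/(FP+TN) and FNR = FN/(FN+TP) come from the thresholded ensemble calls.
Confidence intervals use a stratified nonparametric bootstrap (positives
and negatives resampled separately, so every resample keeps both classes),
B = 2000 replicates by default, percentile interval — the standard choice
for AUC when no distributional assumption is wanted. Intervals are always
reported lo ≤ hi.

## What the synthetic data does and does not emulate

`gen_feature_bags()` emulates encoder output: background instances are
i.i.d. $N(0, \sigma^2)$, and each positive bag plants
`max(1, round(witness_rate * bag_size))` signal instances whose mean is
shifted by `signal_shift` on the first $\lceil d/4 \rceil$ coordinates.
The number of positive bags is exactly `round(pos_fraction * n_bags)`, and
the signal coordinates are fixed, so counts and attention-localization are
test-assertable. `gen_multiscale_feature_bags()` shares the clean signal
across three scales while redrawing the noise independently — the regime
in which averaging per-scale probabilities should help, and the mechanism
behind the ensemble's directional advantage over single scales.

`gen_slide_pyramids()` builds image pyramids: positive slides carry one
contiguous square lesion of high-contrast speckle covering about
`lesion_fraction` of the area; the background is either blank
(near-constant, entropy ≈ 0 bits, removed by the filter) or tissue-like
(smooth low-amplitude field plus fine grain, entropy ≈ 5.4–6.2 bits,
retained). Lower magnifications are 2× and 4× block-mean downsamplings —
how scanners produce pyramid levels, as opposed to subsampling.

None of this imitates real H&E statistics: no stain variation, no scanner
noise, no tissue morphology, and lesions are compact squares rather than
infiltrating regions. Passing tests therefore demonstrate that the
machinery is correct and that the method recovers planted signal under
controlled conditions — not that any particular clinical performance would
be attained.

## Study sizes used by the tests and the acceptance script

Problem sizes were chosen so each property is measured where it is
statistically meaningful at desk scale: signal recovery uses 200 training /
50 test bags (bag size 30, d = 16, witness rate 0.1, shift 2.0) over three
seeds; the ensemble comparison uses 100/100 bags at shift 1.0 — deliberately
moderate so single-scale models are imperfect and averaging has room to
help — over five seeds; null calibration (shift 0) uses 100 training and
200 test bags over five seeds, the larger test set keeping the chance-level
AUC's sampling noise (sd ≈ 0.04) well inside the [0.35, 0.65] sanity band.
The image-mode pipeline demonstration uses 12 slides of 896² base pixels so
the 5x level still contains a whole tile.

## Numerical choices and degenerate inputs

* Cross-entropy clamps the probability at $10^{-12}$ inside the logarithm.
* Softmax subtracts the maximum score before exponentiation.
* A zero-variance channel gets sd clamped to 1 (with a warning) rather than
  dividing by zero.
* Empty bags (every tile filtered) are dropped from training with a
  warning; at prediction they are an error unless the mean-available policy
  is chosen. Bags are validated as non-empty before any forward pass.
* A validation fold containing one class is skipped with a warning and
  recorded; model selection proceeds over the remaining folds.
* Splitting is stratified by label (plain random division can produce
  single-class folds at small cohort sizes); a class with fewer slides than
  the number of folds is a stratification error.
* Parameters are Glorot-initialized under the run seed; a single global
  seed fans out to per-stage seeds by hashing the stage name, so every
  stage is independently reproducible and full pipeline reruns are
  byte-identical.

## Known limitations

* The bundled image encoder is frozen; end-to-end fine-tuning of a deep
  backbone is out of scope (supply embeddings through the passthrough or
  custom encoder instead).
* Binary classification only; no multi-class head.
* The ensemble is an unweighted mean; learned ensemble weights and
  per-scale calibration are not implemented.
* Attention weights are exported as data for localization analysis, but no
  heatmap rendering is provided.
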