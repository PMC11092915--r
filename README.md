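# attmil — attention-based multiple instance learning for multi-magnification slide classification

`attmil` is an R implementation of weakly supervised whole-slide image (WSI)
classification for computational-pathology workflows: tumor detection,
subtype calling, or treatment-response prediction from a single slide-level
label per case, with no patch-level annotation. It is aimed at researchers
who want a fully inspectable, dependency-light reference implementation of
the attention-MIL + multi-magnification-ensemble recipe, complete with a
synthetic ground-truth generator so every component can be validated without
access to clinical cohorts.

## The method

A slide is a **bag** of 224×224 patch **instances**; a bag is positive iff
at least one instance is positive. The pipeline:

1. **Tiling + background removal.** Each magnification (20x, 10x, 5x) is cut
   into non-overlapping 224×224 tiles; tiles whose 256-bin luminance
   histogram has Shannon entropy below 5 bits are discarded as background.
2. **Normalization** by per-channel mean/variance fitted on the training
   split, per magnification.
3. **Encoding.** Each tile becomes a feature vector h_k ∈ R^d via a
   pluggable encoder (precomputed features, the bundled small frozen CNN,
   or any user-supplied embedder).
4. **Attention MIL.** Instance attention
   `a_k = softmax_k( wᵀ tanh(V h_k + b_V) )`, bag feature
   `z = Σ_k a_k h_k`, and a bag-level MLP giving class probabilities; the
   model is trained with cross-entropy under Adam (lr 1e-4, weight decay
   1e-5, 500 update steps, 64 bags per step), with stratified 5-fold
   cross-validation and selection of the fold model with the best
   validation AUC.
5. **Multi-scale ensemble.** One model per magnification; a slide's final
   risk is the arithmetic mean of the three positive-class probabilities,
   thresholded at 0.5.
6. **Evaluation.** AUC (Mann–Whitney, midrank ties), accuracy, FPR, FNR,
   each with stratified bootstrap 95% confidence intervals (B = 2000).

The synthetic-data module generates (a) feature-space MIL bags in which
positive bags contain a known subset of mean-shifted signal instances, and
(b) multi-scale slide images with planted high-contrast lesions on blank or
tissue-textured backgrounds — both with full ground truth (bag labels,
instance masks, lesion rasters).

## Worked example

Feature-bag mode runs the whole pipeline (simulate → split → train →
predict → evaluate) in under a minute:

```r
library(attmil)
cfg <- pipeline_config(
  seed = 11, out_dir = "readme-run", synthetic = NULL,
  feature_bags = list(n_bags = 80L, bag_size = 20L, feature_dim = 16L,
                      witness_rate = 0.15, signal_shift = 2),
  encoder = list(kind = "passthrough", d = 16L),
  train = list(iterations = 200L, batch_bags = 32L),
  bootstrap_B = 1000L)
res <- run_pipeline(cfg)
print(res$report)
head(res$predictions, 4)
```

```
[attmil] simulate  80 feature bags (d = 16) [0.2s]
[attmil] split     64 train / 16 test slides
[attmil] train     3 scales x 5-fold CV; best val AUC 20x=1.000 10x=1.000 5x=1.000 [50.8s]
[attmil] predict   16 test slides [0.1s]
[attmil] evaluate  AUC 1.000 accuracy 0.812 [0.3s]
Slide-level evaluation (8 positive / 8 negative, B = 1000)
  AUC      1.0000  (95% CI 1.0000-1.0000)
  ACCURACY 0.8125  (95% CI 0.6250-0.9375)
  FPR      0.3750  (95% CI 0.0000-0.7500)
  FNR      0.0000  (95% CI 0.0000-0.0000)
  slide_id      p_5x     p_10x     p_20x p_ensemble pred_label label
1 bag_0002 0.8592729 0.7145386 0.8844487  0.8194201          1     1
2 bag_0009 0.5847697 0.5631105 0.5442043  0.5640282          1     0
3 bag_0010 0.5858981 0.5563446 0.5595655  0.5672694          1     0
4 bag_0013 0.5036790 0.2889129 0.4138873  0.4021597          0     0
```

Reading the output: each test slide gets one positive-class probability per
magnification, their mean (`p_ensemble`), and the thresholded call. Here the
ensemble ranks every positive test bag above every negative (AUC 1.0) while
the fixed 0.5 threshold still miscalls three borderline negatives
(accuracy 0.81, FPR 0.375) — the distinction between ranking quality and
thresholded decisions that reporting both metrics is meant to expose. With
`synthetic = list(n_slides = 12, base_size = 896, ...)` instead of
`feature_bags`, the same call generates PNG slide pyramids, tiles and
entropy-filters them, encodes tiles with the bundled CNN, and writes
`slides/`, `tiles_manifest.csv`, per-scale checkpoints, `predictions.csv`,
`metrics.csv` and `run_manifest.json` under `out_dir`.

A thin CLI over the same functions lives at `inst/cli/attmil.R`
(subcommands `simulate`, `tile`, `train`, `predict`, `evaluate`, `run`).

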