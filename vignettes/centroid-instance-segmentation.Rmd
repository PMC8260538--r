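---
title: "Box-free instance segmentation and typing of surgical instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box-free instance segmentation and typing of surgical instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CentroidSeg)
```

## The problem

Endoscopic video of robot-assisted surgery shows a small number of
elongated instruments entering the frame from its borders. Most of each
instrument — the shaft and the wrist — looks the same across instrument
types; what distinguishes a needle driver from a grasper or an
ultrasound probe is chiefly the articulated tip (the *clasper*), a small
part that may even leave the field of view. Bounding-box detectors are a
poor fit: a thin tool lying on the image diagonal has a box covering
most of the frame, typically swallowing the other instruments.

CentroidSeg implements a box-free *mask-then-classify* pipeline for this
setting. Instances are segmented first, pixel-wise, without any box
proposals; each extracted instance is then classified on its own masked
feature map, so the type decision can pool evidence from the whole
instrument while ignoring everything else in the frame.

## The model

A shared convolutional encoder feeds two light decoder heads with long
skip connections from the last three encoder stages (group
normalisation throughout, nearest-neighbour upsampling, each decoder
block an upsampling step followed by two conv–norm–ReLU layers, and a
final block of three conv–norm–ReLU layers):

* the **segmentation head** labels every pixel with an instrument part
  in {background, shaft, wrist, clasper, other};
* the **centroid head** predicts, at every pixel, a 2-vector offset
  pointing to the centroid of the instance occupying that pixel, and a
  sigmoid heatmap with a bump at every instance centroid.

Training minimises

\[
\mathcal{L} \;=\; L_t + L_o + L_c + \gamma\,L_s ,
\]

with \(\gamma = 10\) so that segmentation quality anchors the shared
features. The components are

* \(L_s\): pixel-wise cross-entropy plus a soft DICE term averaged over
  all part classes (`segLoss`);
* \(L_o\): mean L1 distance between predicted and true offsets over
  foreground pixels only — background offsets are unsupervised
  (`offsetLoss`);
* \(L_c\): the penalty-reduced pixel-wise focal loss between the
  predicted heatmap and a target built by placing an unnormalised
  Gaussian (\(\sigma = 20\) at the 512×640 reference resolution) at the
  per-axis median of each instance mask, combining overlaps with the
  maximum (`centroidLoss`, `makeHeatmap`). Exponents \(\alpha = 2\) on
  the prediction and \(\beta = 4\) on the soft target down-weight
  negatives close to a true centre; the sum is normalised by the number
  of instances (floor one);
* \(L_t\): weighted cross-entropy of the per-instance type prediction,
  with weights the mean-normalised inverse type occurrence counts of
  the training split (`typeLoss`, `classWeightsFromCounts`).

At inference, centroids are recovered from the heatmap by local
non-maximum suppression (a pixel survives if it equals the maximum of
its window and exceeds a score threshold), capped at the four
highest-scoring peaks — at most three instruments and one ultrasound
probe are ever visible. Every foreground pixel \(p\) (part argmax
non-background) is assigned to the instance \(i\) minimising
\(\lVert p - \hat{y}_o(p) - s_i \rVert_2\); offsets are stored as
\(p - \text{centroid}\) so this subtraction lands exactly on the
centroid for perfect predictions (`extractCentroids`,
`assignInstances`).

Each surviving instance mask \(m_i\) then gates the segmentation
decoder's final feature map: the classifier consumes \(f_{seg}\cdot
m_i\), hiding background and other instruments, and applies four
conv–norm–ReLU layers, each followed by a stride-2 max pooling, a
global max pooling, and a fully connected layer (`classifyInstance`).
When a *presence prior* is available — on a surgical robot the mounted
instrument types are known — a binary vector over the type vocabulary
is concatenated to the pooled feature and a second fully connected
layer absorbs it.

During training the classifier is *teacher-forced*: it sees
ground-truth instance masks instead of predictions, so early,
inaccurate segmentations cannot poison its features; its input is
additionally perturbed with channel dropout (rate 0.2). Instruments
whose clasper is not visible are excluded from the classification loss,
and frames with no visible clasper at all are discarded from training
entirely; evaluation never filters. Visibility itself is
operationalised as "at least `minPixels` (default 10) rendered clasper
pixels", since the filtering rule needs a concrete criterion.

Training follows a two-phase schedule: the encoder and segmentation
decoder are pretrained alone on \(L_s\), then the joint objective is
optimised end-to-end with AdamW and a step learning-rate schedule.

## Presets and numerical choices

Two presets are provided. The **full** preset mirrors the reference
training setup: a five-stage stride-32 encoder with EfficientNet-B0
stage widths (16/24/40/112/320), 32 `fSeg` channels, batch 24, base
learning rate 1e-3 dropped to 1e-4 after 100 epochs, 20 pretraining
epochs, frames resized to 512×640 and randomly cropped to 384×480, and
heatmap \(\sigma = 20\). It exists as a faithful architecture contract;
training it requires GPU-scale compute and external data.

The **tiny** preset is the package's desk-scale study configuration,
chosen once so that the whole pipeline trains on one CPU core in
minutes and the method's properties remain observable:

* 64×80 scenes; three-stage stride-8 encoder of widths 8/16/32; 12
  `fSeg` channels; classifier widths 12/24/24/24;
* heatmap \(\sigma = 3.5\) — at 64×80 a proportional rescaling of the
  reference \(\sigma\) would be ≈2.5, but bumps that narrow make the
  sparse heatmap regression needlessly brittle at this scale, so the
  tiny preset widens them; correspondingly the study decodes with a
  7-pixel non-maximum-suppression window (≈\(2\sigma\) at this
  resolution; the `inferenceConfig` default stays at the conventional
  3×3) and drops instances below 10 pixels;
* 30 epochs (5 pretraining), batch 4 — group normalisation is
  batch-size independent, so small batches simply buy more optimiser
  steps —, base learning rate 2e-3 dropped tenfold after epoch 24,
  random horizontal flips, no resize/crop;
* offsets are produced as `raw × offsetScale` with
  `offsetScale = diag/8`, so pixel-scale offsets are reachable within
  a short schedule; the L1 loss itself remains in pixels.

Other numerical choices: heatmap predictions are clamped to
\([10^{-6}, 1-10^{-6}]\) before logarithms (the focal loss is undefined
at 0/1); DICE uses smoothing 1 in numerator and denominator and is
computed on soft probabilities over all part classes; centroids are
rounded half-away-from-zero to integer pixels before target placement
(the focal loss needs an exact-1 pixel); the heatmap head bias starts
at \(\mathrm{logit}(0.01)\) so the initial map is near-empty;
nearest-centroid ties break to the smallest (highest-scoring) index;
AdamW decays only convolution and fully-connected weights. The network
itself runs on compiled 3×3 convolution kernels (one GEMM per filter
tap on shifted views) with analytic, finite-difference-verified
gradients.

## What the synthetic generator emulates

`generateScene` draws scenes that reproduce the structural premise of
the endoscopic setting, not its appearance:

* instruments are capsule-shaped shafts entering from a border at an
  arbitrary angle and spanning a large image fraction;
* shaft and wrist rendering is *identical across types*; only the tip
  geometry (one to four prongs, disc, ring, T-bar) identifies the
  class, so a pixel-local semantic classifier cannot solve the typing
  task — the central difficulty the mask-then-classify design
  addresses;
* instances overlap, with later draws occluding earlier ones; an
  occluded instrument keeps one id across its disconnected visible
  fragments (which is why centroids use the median over all pixels,
  ignoring connectivity);
* a fraction of tips (≈15%) is deliberately placed outside the frame,
  producing the hidden-clasper instances the training filter and the
  presence prior are about;
* at most four instruments per scene, mirroring the operating-room
  cap.

What it does **not** emulate: tissue texture, specular highlights,
smoke, blood, motion blur, lighting changes, temporal coherence, or
realistic instrument appearance. Part labels are separable by colour
by construction, so the segmentation task is much easier than on real
video. Passing the desk-scale study therefore demonstrates that the
pipeline's machinery works — targets, losses, grouping, masked
classification, filtering, scoring — not that the model would reach
any particular score on real endoscopic data.

## Evaluation protocol

`frameMIoU` follows the challenge rule: per frame, IoU is averaged
only over labels present in the ground truth, and frames with no
instrument contribute nothing (`dataset mIoU` averages the defined
frames). The study's binary foreground IoU follows the same
present-in-ground-truth rule. `maskMAP` is COCO-style mask mAP: per
class and IoU threshold (0.50 to 0.95 in steps of 0.05), predictions
are matched greedily in score order to the unmatched same-class,
same-frame ground-truth mask of highest IoU, and AP uses all-point
interpolation. Per-instance type accuracy matches every ground-truth
instance to the predicted instance of highest mask IoU (class-blind)
and scores the label; undetected instances count as errors, and
hidden-tip instances are included even though their type is
unidentifiable without the prior — both choices make the reported
accuracy conservative.

## Architecture variants

Three ablation variants are built into `modelConfig` and compared by
`runAblation` under identical data, seeds and budgets:

* `semantic_type`: the instance classifier is removed and a third
  decoder predicts per-pixel type logits — the semantic-segmentation
  baseline. On tip-only-discriminable scenes it must push the type
  decision through purely local evidence, which is exactly what fails
  on shafts;
* `single_decoder`: one decoder (channel widths doubled for comparable
  capacity) feeds all three heads;
* `binary_seg`: the part head collapses to instrument/background; the
  classifier still runs on masked features.

## Known limitations

* The tiny study is a single seeded run per configuration; its
  stochastic metrics move by a few points across seeds.
* The heatmap head is the slowest component to converge at desk scale;
  detection (not masked classification) limits the tiny pipeline's
  type accuracy.
* The full preset's training schedule is untested in this package at
  full scale by construction (no GPU path).
* `maskMAP` enumerates mask pairs densely; it is meant for hundreds,
  not millions, of instances.

## A minimal session

```{r example, eval = FALSE}
scenes <- generateScenes(synthConfig(), 60, seed = 1)
val <- generateScenes(synthConfig(), 20, seed = 2)
fit <- trainModel(modelConfig(preset = "tiny"),
                  trainConfig(preset = "tiny", totalEpochs = 10),
                  scenes, valScenes = val, verbose = TRUE)
res <- predictFrame(fit$model, sceneImage(val[[1]]),
                    inferenceConfig(nmsWindow = 7, minInstancePixels = 10))
res
validateModel(fit$model, val)$report
```
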