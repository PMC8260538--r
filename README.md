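# CentroidSeg

Box-free multi-instance segmentation and typing of surgical instruments,
in R.

Endoscopic frames from robot-assisted surgery contain up to four
elongated instruments that enter the image from its borders. Instrument
types differ almost exclusively at the articulated tip (the *clasper*);
shafts and wrists look alike, and a thin tool on the image diagonal has
a bounding box covering most of the frame. CentroidSeg implements a
*mask-then-classify* pipeline for exactly this regime: instances are
extracted pixel-wise, without box proposals, and each instance is then
classified from its own masked feature map, so the type decision pools
evidence over the whole instrument while ignoring the rest of the
scene.

The model is an encoder with two decoder heads (group normalisation,
long skips from the last three encoder stages). One head segments
instrument parts `{background, shaft, wrist, clasper, other}`; the
other predicts, per pixel **p**, an offset vector pointing to the
centroid of the instance occupying **p**, and a centroid heatmap built
from unnormalised Gaussians at the per-axis median of each instance
mask (maximum-combined, σ = 20 at the 512×640 reference scale).
Training minimises

    L = L_type + L_offset + L_centroid + γ · L_seg,    γ = 10

with cross-entropy + soft DICE for segmentation, masked mean-L1 for
offsets, the penalty-reduced pixel-wise focal loss (α = 2, β = 4) for
the heatmap, and inverse-frequency-weighted cross-entropy for the
per-instance type. At inference, heatmap peaks survive local
non-maximum suppression (capped at the 4 best — at most three
instruments plus an ultrasound probe are visible), every foreground
pixel joins the instance `argmin_i ‖p − offset(p) − s_i‖`, and each
instance mask m_i gates the segmentation features: the shallow
classifier consumes `f_seg · m_i`. A binary *presence prior* (the
instrument types mounted on the robot) can be concatenated to the
pooled classifier feature. Instruments whose clasper is invisible are
filtered from the classification loss during training; frames with no
visible clasper are discarded entirely; evaluation never filters.

Everything runs on CPU: the package ships its own compiled 3×3
convolution kernels (one BLAS GEMM per filter tap on shifted views),
analytic backprop, and an AdamW optimiser. A seeded generator of
synthetic instrument scenes reproduces the structural premise —
elongated border-crossing bodies, identical shafts, class information
only in the tip, overlap and occlusion, tips that may leave the frame —
so the whole pipeline trains and tests at desk scale without external
data. Scoring follows the challenge protocol: mIoU averaged over
labels present in the ground truth, and COCO-style mask mAP over IoU
0.50:0.95.

## A worked example

```r
library(CentroidSeg)

scenes <- generateScenes(synthConfig(), 60, seed = 1)
val    <- generateScenes(synthConfig(), 20, seed = 2)

fit <- trainModel(modelConfig(preset = "tiny"),
                  trainConfig(preset = "tiny", totalEpochs = 10),
                  scenes)

res <- predictFrame(fit$model, sceneImage(val[[1]]),
                    inferenceConfig(nmsWindow = 7, minInstancePixels = 10))
res
#> InstanceResult: 1 instance
#>   id 1 @(52,43): class 7, score 0.032

validateModel(fit$model, val,
              inferenceConfig(nmsWindow = 7, minInstancePixels = 10))$report
#> EvalReport over 20 frames
#>   types mIoU: 0.1013
#>   parts mIoU: 0.7933
#>   mask mAP (0.50:0.95): 0.0073
```

Ten epochs on 60 scenes is only a smoke run; the instance result shows
the output anatomy (score-ordered centroids, per-instance class
distributions), and the report shows the challenge-protocol scores.
The full desk-scale study (200 scenes, 30 epochs, ~10 min on one CPU
core) is what `scripts/acceptance.R` runs; typical held-out scores
there are foreground IoU ≈ 0.98, parts mIoU ≈ 0.9 and per-instance
type accuracy well above chance (1/7), with the exact values printed
by the script.

A command-line interface wrapping the same functions is installed at
`exec/centroidseg` (`synth`, `train`, `predict`, `evaluate`,
`ablate`).

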