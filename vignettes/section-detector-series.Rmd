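---
title: "A lightweight detector series for fetal ultrasound standard sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lightweight detector series for fetal ultrasound standard sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectornet)
```

## The problem

Screening fetal echocardiography hinges on recognising a handful of
standard planes — the abdominal transverse section, the four-chamber view,
the outflow tract and the three-vessel view — inside noisy, low-contrast
ultrasound video. Embedded hardware attached to an ultrasound probe cannot
run a full-size one-stage detector in real time, which motivates a family
of drastically smaller models derived from a single architecture by
pruning, so a deployment can trade accuracy for latency by picking a
variant.

`sectornet` implements that family as a construction kit: the neural
building blocks, a declarative graph of the full 26-layer network, a
registry of the five pruning-derived variants (`emns`, `emnm`, `emnl`,
`emnx`, `emnxx`), exact parameter accounting calibrated against the
published per-variant counts, a synthetic ultrasound scene generator, the
standard detection metric stack, and a small CPU training engine.

## Architecture

The backbone replaces the usual CSP stack with the MobileNetV3-Small
sequence: a stride-2 stem convolution (layer 0) and eleven inverted
residual ("bneck") blocks (layers 1–11), each a 1×1 expansion, a depthwise
3×3 or 5×5 convolution, optional squeeze-and-excitation, and a linear 1×1
projection, with a residual shortcut exactly when the stride is 1 and the
input and output widths agree. Activations are the hard variants
`hswish(x) = x·ReLU6(x+3)/6` and `hsigmoid(x) = ReLU6(x+3)/6`, piecewise
approximations of `swish`/logistic that cost a handful of additions on
edge hardware; the approximation error `|hswish − swish|` never exceeds
0.0872 and vanishes away from the origin.

Layer 12 is the fast spatial pyramid pooling (SPPF) block: three serial
stride-1 max pools with window 5 whose composition reproduces parallel
pooling with windows {5, 9, 13}, concatenated with the unpooled map and
fused by a 1×1 convolution. For a target output grid of `n` positions
from an input of `w`, the pooling parameters follow
`k = s = ceil(w/n)`, `p = floor((k·n − w + 1)/2)` (`sppWindowParams()`).

Layers 13–25 form a two-up/two-down feature-fusion neck whose four concat
layers — 15, 19, 22, 25 — feed the prediction heads at strides 16, 8, 16
and 32. Each head is a 1×1 convolution to `3·(5 + nClasses)` channels:
three anchors per head, each with box offsets, objectness and class
logits. Heads 1 and 3 share a stride but read different fusion depths
(the interpretation of the four prediction sizes as four anchor regimes
rather than four distinct strides is forced by the published layer
ranges: the variant that ends at layer 19 keeps heads 1–2, which places
heads 1 and 2 on the upsampling path).

Variants are derived by `buildVariant()`: keep a layer range, keep a head
subset, and reroute any reference into a removed layer to its nearest
kept ancestor along the chain of first sources (deterministic and
order-independent). Published layer indices are preserved in the derived
graph so per-layer comparisons with the full graph stay direct.

## Width calibration

The published material fixes each variant's total trainable parameters
(0.33, 0.44, 0.81, 0.92 and 1.28 million at four classes) but not the
per-layer channel widths. `calibrateWidths()` treats the free widths —
the neck convolution widths and the expansion of backbone blocks 10–11 —
as unknowns and solves for them exactly. The key observation is that the
five targets decompose into independent subproblems because variants
differ by disjoint layer groups: blocks 10–11 carry the same mass in
`emnl − emns` as in `emnx − emnm`; neck layers 20–21 plus the head-3/
head-1 swap carry `emnm − emns`; layers 23–24 plus head 4 carry
`emnxx − emnx`. Each subproblem is an exhaustive integer search over
multiples of 8. The resolved assignment is shipped as `emnWidths()` and
is, by construction, a fixed point: re-running `countParameters()` on the
rebuilt variants reproduces all five targets to two decimals. Counting
conventions are the reference ones — bias-free convolutions followed by
batch-norm affine pairs, biased squeeze-excitation and head convolutions —
and the same conventions reproduce the well-known 7,235,389-parameter
count of the public small baseline at 80 classes (7.03 M at 4 classes),
which anchors the convention independently of the series.

Two published tables disagree on the `emnm` count (0.44 vs 0.43 M); the
calibration targets the series table (0.44).

The module tally `countLayers()` flattens each block into atomic modules
(convolution, batch norm, activation, pool, upsample, concat, residual
add, one per prediction head). Published layer totals use an unstated
summary convention, so only the strict ordering across variants is
asserted, which this convention preserves.

## Synthetic scenes

Real clinical data cannot ship with the package, so every downstream
stage is exercised on generated scenes that keep the statistical features
the detector relies on: a dark background; a bright, fan-shaped scan
sector; one hypoechoic (dark) structure per image whose shape encodes the
class — a body ellipse plus a separate stomach bubble (abdomen), an
ellipse quartered by bright septa (four-chamber), a single curved vessel
(outflow tract), three collinear circles (three-vessel) — and
multiplicative speckle drawn from a Rayleigh distribution (the standard
first-order model of coherent ultrasound noise; the default scale
`sqrt(2/pi)` gives a unit-mean field). A per-image acquisition-gain
jitter (±15%) emulates scanner gain settings.

Two design constraints make the fixtures meaningful rather than
decorative. First, the hypoechoic area budget is shared across classes
(1.8% of the image), so a histogram of intensities does not separate the
classes — a nearest-centroid histogram classifier stays near chance —
while counting hypoechoic connected components identifies every class
(2/4/1/3). Training on these scenes therefore requires spatial features.
Second, generation is bit-deterministic in the scene seed, so datasets
are reproducible byte-for-byte. If a jittered placement would spill over
the sector boundary, the centre is pulled deterministically toward the
beam axis; explicitly oversized structure parameters still raise an
error.

What the fixtures do *not* emulate: acoustic shadowing, motion blur,
probe-pressure deformation, anatomical variability between patients, or
multiple structures per frame. Passing the pipeline tests therefore shows
the machinery is correct and has the capacity to fit such scenes, not
that the models reach clinical accuracy; the published deployment-scale
precision/recall/mAP require the original clinical data and hardware and
stay out of asserted scope.

## Metrics

Evaluation follows the PASCAL-VOC protocol: greedy confidence-ordered
one-to-one matching at IoU ≥ 0.5, `precision = TP/(TP+FP)`,
`recall = TP/(TP+FN)` (zero denominators give 0 so the report is total),
per-class average precision as the area under the monotone-envelope
precision-recall curve integrated by trapezoid (anchored at precision 1
for recall 0; unreached recall contributes nothing), and mAP@0.5 as the
unweighted mean over classes present in the ground truth. The test suite
holds these equal to brute-force oracles that rebuild the curve by
re-matching from scratch at every distinct confidence. Because the
operating point behind the published precision/recall figures is
unstated, reports carry both a fixed-confidence point (default 0.25) and
the best-F1 point.

## Training engine

No R deep-learning runtime was suitable as a base, and the blocks are the
point of the package, so the engine is authored here: im2col + GEMM
convolutions (grouped, for the depthwise case) in compiled code, batch
normalisation with batch statistics during training and running averages
at inference, and analytic backward passes verified against central
finite differences in the test suite.

The loss composes a `1 − CIoU` box term over matched pairs, binary
cross-entropy objectness over every grid cell with per-head balance
weights (4.0 at stride 8, 1.0 at 16, 0.4 at 32; the second stride-16 head
keeps weight 1.0), and binary cross-entropy class terms, with gains
0.05/1.0/0.5. Each ground truth is assigned to the best shape-matching
anchor across the kept heads, at the grid cell containing its centre.
Anchors come from IoU-distance k-means over the training boxes
(`computeAnchors()`), sorted by area so small anchors serve the
high-resolution head. The CIoU gradient with respect to the decoded box
uses central finite differences (four evaluations of a cheap scalar per
matched pair, step 1e-5) chained with the analytic sigmoid-decode
jacobian; matched pairs are few, so this costs nothing measurable and
avoids a long hand derivation.

Defaults mirror the published regimen — 300 epochs, batch 32, 640×640,
no pretrained weights, checkpoint every epoch with the best validation
mAP@0.5 kept (ties resolved to the later epoch) — with SGD (momentum
0.937, weight decay 5e-4 on convolution weights), linear warmup and
linear decay, and switchable mosaic augmentation (on by default).

### Numerical choices and problem sizes

Float comparisons in the tests use relative 1e-5 / absolute 1e-6 unless
an exact identity is expected. Box encoding clamps the inverse-sigmoid
argument to `[1e-7, 1 − 1e-7]`; `decode(encode(box))` recovers boxes to
1e-4 in normalised units. NMS and matching break score ties toward the
lower index, making every ranking deterministic. The capacity check in
the suite trains the smallest variant for 200 iterations on an 8-image
synthetic subset at 160×160 input — an input size chosen so a full
training run remains a desk-scale computation; the contract (mAP@0.5 ≥
0.9 on the training subset) tests that the implementation can drive the
loss to a solution, and is input-size-agnostic. Determinism is end to
end: fixed seeds reproduce loss trajectories and weight checksums
exactly on the same platform.

## Known limitations

* Batch-norm statistics are computed over whatever batch is presented;
  very small batches make training noisier than a GPU-scale run.
* The engine is written for clarity and testability, not throughput;
  benchmark figures are informational only.
* The mosaic implementation composes four full scenes without random
  cropping, a simplification of the reference augmentation.
* Orientation of the fetal heart is not modelled — the task is plane
  detection, not pose.
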