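# sectornet

Resource-efficient detection of fetal echocardiography standard sections,
implemented as an R construction kit.

Screening fetal echocardiography relies on recognising four standard
ultrasound planes — the abdominal transverse section (`abdomen`), the
four-chamber view (`four_chamber`), the outflow tract (`vot`) and the
three-vessel view (`three_vessels`) — in noisy sector scans. Embedded
devices next to the probe cannot run a full-size one-stage detector in
real time, so this package implements a family of five pruning-derived
lightweight variants (`emns` < `emnm` < `emnl` < `emnx` < `emnxx`,
0.33–1.28 M parameters) of a single MobileNetV3-Small + SPPF detector
with up to four anchor-based prediction heads, against a stock
small-detector baseline of 7.03 M parameters at the same four classes.

The package provides:

* **Block library** — `hswish`/`hsigmoid` hard activations, squeeze-and-
  excitation (`squeezeExcite`), inverted residual bottlenecks
  (`invertedResidual`), fast spatial pyramid pooling (`sppfForward`,
  with `sppWindowParams` giving `k = s = ceil(w/n)`,
  `p = floor((k·n − w + 1)/2)`), and per-scale prediction heads.
* **Declarative architecture** — the full 26-layer graph (`fullGraph`),
  heads at concat layers 15/19/22/25 with strides 16/8/16/32, the variant
  registry (`variantRegistry`), pruning with deterministic rerouting
  (`buildVariant`), exact parameter accounting (`countParameters`,
  verified against brute-force weight enumeration), module tallies
  (`countLayers`), width calibration against the published counts
  (`calibrateWidths`) and YAML round-tripping (`writeModelConfig`).
* **Data tooling** — LabelMe JSON → YOLO txt conversion, deterministic
  7:2:1 splitting with per-class overrides, letterbox resizing, and a
  deterministic synthetic ultrasound scene generator (sector geometry,
  class-specific hypoechoic structures, multiplicative Rayleigh speckle).
* **Metrics** — IoU, VOC-style greedy matching, precision/recall,
  AP/mAP@0.5 with monotone-envelope trapezoid integration, all checked
  against brute-force oracles.
* **Engine** — an im2col+GEMM CPU autograd core (Rcpp/RcppArmadillo),
  CIoU+BCE detection loss, IoU k-means anchors, NMS, training with the
  published regimen defaults (300 epochs, batch 32, no pretraining),
  detection and latency benchmarking, plus a CLI
  (`inst/cli/sectornet`) with `synth`/`convert`/`split`/`train`/`eval`/
  `detect`/`bench`/`summary` subcommands.

## Worked example

```r
library(sectornet)

# the model series and its calibration surface
parameterTable(4)
#>   model        layers heads modules parameters millions
#>    emns    0-9, 12-19   1,2     143     329998     0.33
#>    emnm    0-9, 12-22   2,3     150     440038     0.44
#>    emnl          0-19   1,2     173     812462     0.81
#>    emnx          0-22   2,3     180     922502     0.92
#>   emnxx          0-25 2,3,4     188    1282521     1.28
yolov5sParameterCount(4) / 1e6
#> [1] 7.030417
```

The table reproduces the published per-variant counts (millions, two
decimals), and the same counting conventions give the baseline detector
7.03 M parameters at four classes. A small end-to-end run on synthetic
scans:

```r
dir <- tempfile()
generateDataset(10, ratios = c(7, 2, 1), seed = 3, outDir = dir)

cfg <- trainConfig(epochs = 40, batchSize = 8, inputSize = 160,
                   mosaic = FALSE, seed = 7, evalEvery = 10)
res <- trainModel("emns", dir, cfg)
res$checkpoint$epoch   # best validation epoch
evalDataset(res$checkpoint, dir, part = "test")
#> Evaluation report (IoU 0.50, conf 0.10)
#>  class          name n precision recall precisionF1 recallF1    ap
#>  ... one row per section class, mAP@0.5 printed last
```

Single-image inference returns normalised boxes with confidences:

```r
scan <- generateScan(sceneSpec(classId = 1, seed = 42))
detectObjects(scan$image, res$checkpoint, confThr = 0.25)
```

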