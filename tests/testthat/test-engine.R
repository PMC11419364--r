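# The training/inference engine: anchor k-means, the loss contract, box
# encode/decode, NMS behaviour, determinism of the loop, benchmarking.

test_that("anchor k-means covers the box shapes", {
  strides <- c(`1` = 16L, `2` = 8L)
  # degenerate clustering: all boxes identical
  same <- data.frame(w = rep(0.2, 20), h = rep(0.3, 20))
  a <- computeAnchors(same, strides, inputSize = 320)
  expect_named(a, c("1", "2"))
  for (h in names(a)) {
    expect_equal(dim(a[[h]]), c(3L, 2L))
    expect_equal(unname(a[[h]]),
                 matrix(rep(c(64, 96), each = 3), 3, 2), tolerance = 1e-9)
  }
  expect_error(computeAnchors(same[1:3, ], strides), "at least")
  # varied boxes: small anchors land on the low-stride head
  set.seed(12)
  boxes <- data.frame(w = runif(60, 0.05, 0.6), h = runif(60, 0.05, 0.6))
  a2 <- computeAnchors(boxes, strides, inputSize = 320)
  area <- vapply(a2, function(m) mean(m[, 1] * m[, 2]), numeric(1))
  expect_lt(area[["2"]], area[["1"]])   # stride 8 head gets the small ones
  expect_gte(meanBestAnchorIoU(boxes, a2, 320), 0.5)
})

test_that("box encoding and decoding are mutually inverse", {
  anchor <- c(50, 80)
  for (seed in 1:25) {
    set.seed(seed)
    grid <- sample(c(10L, 20L, 40L), 1)
    box <- c(runif(1, 0.1, 0.9), runif(1, 0.1, 0.9),
             runif(1, 0.02, 0.25), runif(1, 0.02, 0.25))
    gx <- min(floor(box[1] * grid), grid - 1)
    gy <- min(floor(box[2] * grid), grid - 1)
    raw <- encodeBox(box, gx, gy, grid, anchor, 320)
    back <- decodeBox(raw, gx, gy, grid, anchor, 320)
    expect_lt(max(abs(back - box)), 1e-4)
  }
})

test_that("the detection loss is non-negative and vanishes on perfection", {
  g <- buildVariant("emns", 4)
  S <- 64L
  anch <- list(`1` = matrix(c(20, 20, 28, 22, 24, 30), 3, 2, byrow = TRUE),
               `2` = matrix(c(8, 8, 12, 10, 10, 14), 3, 2, byrow = TRUE))
  truths <- list(data.frame(class = 1L, cx = 0.52, cy = 0.48,
                            w = 0.28, h = 0.30))
  shapes <- forwardShapes(g, S)
  set.seed(3)
  raw <- lapply(names(shapes), function(h) {
    array(rnorm(shapes[[h]][1]^2 * 27, sd = 0.5),
          c(shapes[[h]], 27, 1))
  })
  names(raw) <- names(shapes)
  ls1 <- detectionLoss(raw, truths, anch, g@strides, S, 4)
  expect_gte(ls1$box, 0); expect_gte(ls1$obj, 0); expect_gte(ls1$cls, 0)
  expect_equal(ls1$total, ls1$box + ls1$obj + ls1$cls, tolerance = 1e-12)
  for (h in names(raw)) expect_equal(dim(ls1$dheads[[h]]), dim(raw[[h]]))
  # plant the exact encoding of the truth: the box term collapses to ~0
  tgt <- sectornet:::build_targets(truths, anch, g@strides, S)
  raw0 <- lapply(raw, function(a) array(0, dim(a)))
  h <- tgt$head[1]; a0 <- (tgt$anchor[1] - 1) * 9
  grid <- S / g@strides[[h]]
  enc <- encodeBox(c(0.52, 0.48, 0.28, 0.30), tgt$gx[1], tgt$gy[1], grid,
                   anch[[h]][tgt$anchor[1], ], S)
  raw0[[h]][tgt$gy[1] + 1, tgt$gx[1] + 1, a0 + 1:4, 1] <- enc
  ls0 <- detectionLoss(raw0, truths, anch, g@strides, S, 4)
  expect_lt(ls0$box, 1e-6)
  # assignment conservation: every truth lands on exactly one kept head
  many <- list(data.frame(class = 0:3, cx = c(0.2, 0.4, 0.6, 0.8),
                          cy = 0.5, w = c(0.1, 0.2, 0.3, 0.4),
                          h = c(0.1, 0.2, 0.3, 0.4)))
  tg <- sectornet:::build_targets(many, anch, g@strides, S)
  expect_equal(nrow(tg), 4L)
  expect_true(all(tg$head %in% names(headLayers(g))))
  expect_true(all(tg$gx >= 0 & tg$gy >= 0))
})

test_that("the complete-IoU penalty behaves like an IoU refinement", {
  b <- c(0.5, 0.5, 0.2, 0.3)
  expect_equal(ciou(b, b), 1)
  shifted <- c(0.6, 0.5, 0.2, 0.3)
  expect_lt(ciou(shifted, b), iou(shifted, b))
  expect_gt(ciou(shifted, b), -1)
})

test_that("NMS keeps the confident survivor and respects separation", {
  far <- data.frame(class = c(0L, 0L, 1L), cx = c(0.2, 0.8, 0.2),
                    cy = 0.5, w = 0.1, h = 0.1, conf = c(0.9, 0.7, 0.5))
  expect_setequal(nms(far, 0.45), 1:3)
  near <- data.frame(class = 0L, cx = c(0.50, 0.505), cy = 0.5,
                     w = 0.2, h = 0.2, conf = c(0.8, 0.6))
  expect_equal(nms(near, 0.45), 1L)
  # equal scores: the lower index wins
  tie <- near; tie$conf <- c(0.7, 0.7)
  expect_equal(nms(tie, 0.45), 1L)
  # different classes are never suppressed against each other
  cross <- near; cross$class <- c(0L, 1L)
  expect_setequal(nms(cross, 0.45), 1:2)
})

test_that("the training configuration mirrors the published regimen", {
  cfg <- trainConfig()
  expect_equal(cfg$epochs, 300L)
  expect_equal(cfg$batchSize, 32L)
  expect_equal(cfg$inputSize, 640L)
  expect_false(cfg$pretrained)
  expect_true(cfg$mosaic)
  expect_error(trainConfig(pretrained = TRUE), "pretrained")
  expect_error(trainConfig(inputSize = 100), "multiple of 32")
})

test_that("seed-fixed short runs reproduce trajectories and weights", {
  dir <- local_synth_dataset(2, seed = 11, imageSize = 96)
  cfg <- trainConfig(epochs = 2L, batchSize = 4L, inputSize = 96L,
                     mosaic = FALSE, seed = 5L, evalEvery = 2L,
                     warmupIters = 2L)
  r1 <- trainModel("emns", dir, cfg, valPart = "train")
  r2 <- trainModel("emns", dir, cfg, valPart = "train")
  expect_identical(r1$log[, c("box", "obj", "cls")],
                   r2$log[, c("box", "obj", "cls")])
  expect_equal(sectornet:::networkChecksum(r1$checkpoint$net),
               sectornet:::networkChecksum(r2$checkpoint$net))
  expect_equal(r1$checkpoint$epoch, 2L)
  expect_true(is.finite(r1$checkpoint$map))
  # detection on a frame returns boxes inside the image bounds
  img <- generateScan(sceneSpec(0, imageSize = 96, seed = 77))$image
  d <- detectObjects(img, r1$checkpoint, confThr = 0.0001)
  if (nrow(d)) {
    expect_true(all(d$cx - d$w / 2 >= -1e-9 & d$cx + d$w / 2 <= 1 + 1e-9))
    expect_true(all(d$cy - d$h / 2 >= -1e-9 & d$cy + d$h / 2 <= 1 + 1e-9))
  }
  # an impossible confidence threshold yields nothing
  expect_equal(nrow(detectObjects(img, r1$checkpoint, confThr = 1)), 0L)
})

test_that("the latency benchmark reports what it measured", {
  g <- buildVariant("emns", 4)
  ck <- list(net = initNetwork(g, 1), inputSize = 64L,
             anchors = sectornet:::default_anchors()[c("1", "2")])
  b <- benchmarkModel(ck, nFrames = 10L, warmup = 1L)
  expect_length(b$ms, 10L)
  expect_gte(b$mean, min(b$ms))
  expect_error(benchmarkModel(ck, nFrames = 5L), ">= 10")
})

test_that("the summary table reports the series in size order", {
  tab <- parameterTable(4)
  expect_equal(tab$model, c("emns", "emnm", "emnl", "emnx", "emnxx"))
  expect_true(all(diff(tab$parameters) > 0))
  expect_equal(tab$millions, c(0.33, 0.44, 0.81, 0.92, 1.28))
})
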