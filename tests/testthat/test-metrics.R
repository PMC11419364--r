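# IoU, the VOC-style matcher, precision/recall, average precision and its
# invariances, checked against independent brute-force oracles.

test_that("IoU follows the area arithmetic", {
  b <- c(0.5, 0.5, 0.2, 0.2)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(b, c(0.9, 0.9, 0.1, 0.1)), 0)
  # corner boxes (0,0)-(2,2) and (1,1)-(3,3): intersection 1, union 7
  expect_equal(iou(c(1, 1, 2, 2), c(2, 2, 2, 2)), 1 / 7)
  expect_equal(iou(c(0.5, 0.5, 0, 0.2), b), 0)  # degenerate box
})

test_that("greedy matching penalises duplicates and misses", {
  truths <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  perfect <- cbind(truths, conf = 0.9)
  m <- matchDetections(perfect, truths)
  expect_equal(m$counts, list(tp = 1L, fp = 0L, fn = 0L))
  # two detections on one truth: 1 TP + 1 FP
  dup <- rbind(cbind(truths, conf = 0.9), cbind(truths, conf = 0.8))
  m2 <- matchDetections(dup, truths)
  expect_equal(m2$counts, list(tp = 1L, fp = 1L, fn = 0L))
  expect_equal(m2$tpFlag, c(TRUE, FALSE))
  # a shifted detection with IoU 0.4 < 0.5 scores FP + FN
  off <- data.frame(class = 0L, cx = 0.5 + 0.2 * 3 / 7, cy = 0.5,
                    w = 0.2, h = 0.2, conf = 0.9)
  expect_lt(iou(as.numeric(off[1, 2:5]), as.numeric(truths[1, 2:5])), 0.5)
  m3 <- matchDetections(off, truths)
  expect_equal(m3$counts, list(tp = 0L, fp = 1L, fn = 1L))
  # same-class constraint: a correct box of the wrong class is an FP
  wrong <- cbind(truths, conf = 0.9); wrong$class <- 1L
  expect_equal(matchDetections(wrong, truths)$counts$tp, 0L)
})

test_that("precision and recall reproduce the defining ratios", {
  expect_equal(precision(list(tp = 5, fp = 0, fn = 0)), 1)
  expect_equal(precision(list(tp = 8, fp = 2, fn = 0)), 0.8)
  expect_equal(precision(list(tp = 0, fp = 0, fn = 0)), 0)
  expect_equal(recall(list(tp = 5, fp = 0, fn = 0)), 1)
  expect_equal(recall(list(tp = 6, fp = 0, fn = 2)), 0.75)
  expect_equal(recall(list(tp = 0, fp = 0, fn = 0)), 0)
})

test_that("average precision handles the canonical hand cases", {
  truths <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  # TP at conf 0.9 plus FP at 0.8: full recall reached at precision 1
  dets <- data.frame(class = 0L, cx = c(0.5, 0.1), cy = c(0.5, 0.1),
                     w = 0.2, h = 0.2, conf = c(0.9, 0.8))
  expect_equal(averagePrecision(dets, truths, 0.5), 1)
  # all detections correct at any confidence
  t3 <- data.frame(class = 0L, cx = c(0.2, 0.5, 0.8), cy = 0.5,
                   w = 0.1, h = 0.1)
  d3 <- cbind(t3, conf = c(0.3, 0.9, 0.6))
  expect_equal(averagePrecision(d3, t3, 0.5), 1)
  # FP first: precision climbs late, AP < 1
  d4 <- rbind(data.frame(class = 0L, cx = 0.05, cy = 0.05, w = 0.05,
                         h = 0.05, conf = 0.95), cbind(t3, conf = 0.5))
  expect_lt(averagePrecision(d4, t3, 0.5), 1)
})

test_that("AP and NMS equal brute-force oracles on random instances", {
  for (seed in 1:200) {
    inst <- random_metric_instance(seed)
    for (cl in unique(inst$truths$class)) {
      d <- inst$dets[inst$dets$class == cl, , drop = FALSE]
      t <- inst$truths[inst$truths$class == cl, , drop = FALSE]
      expect_equal(averagePrecision(d, t, 0.5),
                   oracle_average_precision(d, t, 0.5), tolerance = 1e-12)
    }
    if (nrow(inst$dets) > 0 && nrow(inst$dets) <= 8) {
      expect_equal(nms(inst$dets, 0.45), oracle_nms(inst$dets, 0.45))
    }
  }
})

test_that("AP is invariant to monotone confidence rescaling", {
  for (seed in c(7, 19, 51)) {
    inst <- random_metric_instance(seed)
    d <- inst$dets[inst$dets$class == 0, , drop = FALSE]
    t <- inst$truths[inst$truths$class == 0, , drop = FALSE]
    if (nrow(t) == 0) next
    ap0 <- averagePrecision(d, t, 0.5)
    d2 <- d; d2$conf <- plogis(5 * d2$conf - 1)   # strictly increasing
    expect_equal(averagePrecision(d2, t, 0.5), ap0, tolerance = 1e-12)
    # appending a lowest-confidence FP never increases AP
    if (nrow(d)) {
      d3 <- rbind(d, data.frame(class = 0L, cx = 0.01, cy = 0.01,
                                w = 0.01, h = 0.01,
                                conf = min(d$conf) / 2))
      expect_lte(averagePrecision(d3, t, 0.5), ap0 + 1e-12)
    }
  }
})

test_that("mAP averages per-class AP and flags truth-free classes", {
  t1 <- data.frame(class = c(0L, 1L), cx = c(0.3, 0.7), cy = 0.5,
                   w = 0.2, h = 0.2)
  d1 <- cbind(t1, conf = c(0.9, 0.8))
  rep <- suppressWarnings(mapAt(d1, t1))
  expect_equal(rep$map, 1)
  expect_equal(nrow(rep$perClass), 2L)
  expect_true(all(rep$perClass$ap == 1))
  w <- capture_warnings(mapAt(d1, t1))
  expect_match(w, "no ground truth", all = TRUE)
  expect_length(w, 2L)   # classes 2 and 3 are absent
  # per-class-identical inputs: mAP equals the single-class AP
  t2 <- t1; t2$class <- 0L
  d2 <- d1; d2$class <- 0L
  ap_single <- averagePrecision(d2, t2, 0.5)
  t_dup <- rbind(t2, within(t2, class <- 1L))
  d_dup <- rbind(d2, within(d2, class <- 1L))
  rep2 <- suppressWarnings(mapAt(d_dup, t_dup))
  expect_equal(rep2$map, ap_single)
  # report values stay inside [0, 1]
  num <- unlist(rep2$perClass[, c("precision", "recall", "ap")])
  expect_true(all(num >= 0 & num <= 1))
})
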