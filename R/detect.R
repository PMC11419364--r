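# Inference: grid decoding, non-maximum suppression, end-to-end detection
# on an image, and the informational latency benchmark.

#' Non-maximum suppression
#'
#' Greedy descending-score suppression: detections are visited in
#' decreasing confidence (ties: lower row index wins) and kept unless they
#' overlap an already-kept detection of the same class with IoU greater
#' than `iouThr`.
#'
#' @param dets detection data.frame (`class`, `cx`, `cy`, `w`, `h`,
#'   `conf`).
#' @param iouThr suppression IoU threshold.
#' @return integer indices (into `dets`) of the kept rows, in decreasing
#'   confidence order.
#' @export
nms <- function(dets, iouThr = 0.45) {
  n <- nrow(dets)
  if (n == 0) return(integer())
  ord <- order(-dets$conf, seq_len(n))
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (dets$class[j] == dets$class[i] &&
          iou(as.numeric(dets[i, c("cx", "cy", "w", "h")]),
              as.numeric(dets[j, c("cx", "cy", "w", "h")])) > iouThr) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# decode all cells of all heads into candidate detections (normalised to
# the network input square); one candidate per (cell, anchor) with the
# best class
decode_predictions <- function(rawHeads, anchors, strides, inputSize,
                               nClasses, confThr = 0.25, n = 1L) {
  rows <- list()
  for (h in names(rawHeads)) {
    raw <- rawHeads[[h]]
    g <- dim(raw)[1]
    natt <- 5L + nClasses
    gx <- matrix(rep(0:(g - 1), each = g), g, g)   # column index
    gy <- matrix(rep(0:(g - 1), times = g), g, g)  # row index
    for (a in 1:3) {
      a0 <- (a - 1L) * natt
      sx <- sigmoid(raw[, , a0 + 1L, n])
      sy <- sigmoid(raw[, , a0 + 2L, n])
      sw <- sigmoid(raw[, , a0 + 3L, n])
      sh <- sigmoid(raw[, , a0 + 4L, n])
      obj <- sigmoid(raw[, , a0 + 5L, n])
      clp <- sigmoid(raw[, , a0 + 5L + seq_len(nClasses), n, drop = FALSE])
      dim(clp) <- c(g * g, nClasses)
      best_cl <- max.col(clp, ties.method = "first")
      best_p <- clp[cbind(seq_len(g * g), best_cl)]
      conf <- as.vector(obj) * best_p
      keep <- which(conf >= confThr)
      if (!length(keep)) next
      anc <- anchors[[h]][a, ]
      rows[[length(rows) + 1L]] <- data.frame(
        class = best_cl[keep] - 1L,
        cx = ((2 * as.vector(sx) - 0.5 + as.vector(gx)) / g)[keep],
        cy = ((2 * as.vector(sy) - 0.5 + as.vector(gy)) / g)[keep],
        w = ((2 * as.vector(sw))^2 * anc[1] / inputSize)[keep],
        h = ((2 * as.vector(sh))^2 * anc[2] / inputSize)[keep],
        conf = conf[keep])
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(class = integer(), cx = numeric(), cy = numeric(),
               w = numeric(), h = numeric(), conf = numeric())
}

clip_boxes <- function(boxes) {
  if (!nrow(boxes)) return(boxes)
  x1 <- pmax(boxes$cx - boxes$w / 2, 0); x2 <- pmin(boxes$cx + boxes$w / 2, 1)
  y1 <- pmax(boxes$cy - boxes$h / 2, 0); y2 <- pmin(boxes$cy + boxes$h / 2, 1)
  boxes$cx <- (x1 + x2) / 2; boxes$cy <- (y1 + y2) / 2
  boxes$w <- pmax(x2 - x1, 0); boxes$h <- pmax(y2 - y1, 0)
  boxes[boxes$w > 0 & boxes$h > 0, , drop = FALSE]
}

#' Detect sections in one image
#'
#' Letterboxes the image to the checkpoint's input size, runs the
#' network, decodes every head grid (sigmoid offsets, anchor-scaled
#' sizes), filters by confidence, applies class-wise NMS and maps the
#' surviving boxes back to the original image frame (clipped to the image
#' bounds).
#'
#' @param image `(H, W)` matrix or `(H, W, 3)` array in `[0, 1]`, or a
#'   file path.
#' @param checkpoint checkpoint from [trainModel()] (or a list with
#'   `net`, `anchors`, `inputSize`).
#' @param confThr confidence threshold (default 0.25).
#' @param iouThr NMS IoU threshold (default 0.45).
#' @return detection data.frame (`class`, `cx`, `cy`, `w`, `h`, `conf`)
#'   normalised to the original image.
#' @export
detectObjects <- function(image, checkpoint, confThr = 0.25, iouThr = 0.45) {
  if (is.character(image)) image <- readImageArray(image)
  net <- checkpoint$net
  lb <- letterbox(image, checkpoint$inputSize)
  x <- gray_to_input(lb$image)
  fwd <- networkForward(net, x, train = FALSE)
  dets <- decode_predictions(fwd$heads, checkpoint$anchors,
                             net$graph@strides, checkpoint$inputSize,
                             net$graph@nClasses, confThr)
  if (nrow(dets)) {
    dets <- dets[nms(dets, iouThr), , drop = FALSE]
    dets <- cbind(boxesFromLetterbox(dets[, c("class", "cx", "cy", "w", "h")],
                                     lb$transform),
                  conf = dets$conf)
    dets <- clip_boxes(dets)
    rownames(dets) <- NULL
  }
  dets
}

# grayscale (H, W) or colour (H, W, 3) -> network input (H, W, 3, 1)
gray_to_input <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) {
    array(rep(img, 3), c(d[1], d[2], 3, 1))
  } else {
    array(img, c(d[1], d[2], 3, 1))
  }
}

#' Benchmark single-frame inference latency
#'
#' Times `nFrames` forward passes on random inputs after `warmup`
#' excluded passes. Purely informational: wall-clock figures depend on the
#' host and are never asserted against published hardware numbers.
#'
#' @param checkpoint checkpoint (or list with `net`, `inputSize`).
#' @param nFrames number of timed frames (>= 10).
#' @param warmup warm-up passes excluded from the statistics.
#' @return list with `ms` (per-frame times), `mean`, `median`, `n`.
#' @export
benchmarkModel <- function(checkpoint, nFrames = 10L, warmup = 2L) {
  if (nFrames < 10) stop("`nFrames` must be >= 10")
  s <- checkpoint$inputSize
  x <- array(stats::runif(s * s * 3), c(s, s, 3, 1))
  for (i in seq_len(warmup)) networkForward(checkpoint$net, x, train = FALSE)
  ms <- vapply(seq_len(nFrames), function(i) {
    t0 <- proc.time()[["elapsed"]]
    networkForward(checkpoint$net, x, train = FALSE)
    (proc.time()[["elapsed"]] - t0) * 1000
  }, numeric(1))
  list(ms = ms, mean = mean(ms), median = median(ms), n = nFrames)
}
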