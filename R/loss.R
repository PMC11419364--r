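# Detection loss: complete-IoU box term, binary cross-entropy objectness
# and class terms, with per-head objectness balancing. Targets are
# assigned to the best shape-matching anchor (one head cell per truth).
#
# Raw head channel layout per anchor: (x, y, w, h, obj, cls...). Decoding
# follows the reference convention: centre = (2*sigmoid(t) - 0.5 + cell)
# / grid, size = (2*sigmoid(t))^2 * anchor.

#' Complete IoU of two centre-format boxes
#'
#' IoU minus the normalised centre distance and an aspect-ratio
#' consistency penalty; equals 1 only for identical boxes.
#'
#' @param boxA,boxB numeric `c(cx, cy, w, h)`.
#' @return CIoU in `(-1, 1]`.
#' @export
ciou <- function(boxA, boxB) {
  i <- iou(boxA, boxB)
  ax1 <- boxA[1] - boxA[3] / 2; ax2 <- boxA[1] + boxA[3] / 2
  ay1 <- boxA[2] - boxA[4] / 2; ay2 <- boxA[2] + boxA[4] / 2
  bx1 <- boxB[1] - boxB[3] / 2; bx2 <- boxB[1] + boxB[3] / 2
  by1 <- boxB[2] - boxB[4] / 2; by2 <- boxB[2] + boxB[4] / 2
  cw <- max(ax2, bx2) - min(ax1, bx1)
  ch <- max(ay2, by2) - min(ay1, by1)
  c2 <- cw^2 + ch^2 + 1e-12
  rho2 <- (boxA[1] - boxB[1])^2 + (boxA[2] - boxB[2])^2
  v <- 4 / pi^2 * (atan(boxB[3] / boxB[4]) - atan(boxA[3] / boxA[4]))^2
  alpha <- v / (1 - i + v + 1e-12)
  i - rho2 / c2 - alpha * v
}

# assign each truth to its best shape-matching anchor over the kept heads
# -> one (head, anchor, cell) per truth
build_targets <- function(truthsByImage, anchors, strides, inputSize) {
  heads <- names(anchors)
  rows <- list()
  for (n in seq_along(truthsByImage)) {
    tr <- truthsByImage[[n]]
    if (is.null(tr) || nrow(tr) == 0) next
    for (i in seq_len(nrow(tr))) {
      w_px <- tr$w[i] * inputSize; h_px <- tr$h[i] * inputSize
      best <- c(NA, NA); best_iou <- -1
      for (h in heads) {
        a <- anchors[[h]]
        for (j in seq_len(nrow(a))) {
          s <- wh_iou(w_px, h_px, a[j, 1], a[j, 2])
          if (s > best_iou) { best_iou <- s; best <- c(h, j) }
        }
      }
      grid <- inputSize / strides[[best[1]]]
      gx <- min(floor(tr$cx[i] * grid), grid - 1)
      gy <- min(floor(tr$cy[i] * grid), grid - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        image = n, head = best[1], anchor = as.integer(best[2]),
        gx = gx, gy = gy, class = tr$class[i],
        cx = tr$cx[i], cy = tr$cy[i], w = tr$w[i], h = tr$h[i])
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# decode one anchor's raw values at one cell into a normalised box
decode_box <- function(t4, gx, gy, grid, anchor, inputSize) {
  sx <- sigmoid(t4)
  c((2 * sx[1] - 0.5 + gx) / grid,
    (2 * sx[2] - 0.5 + gy) / grid,
    (2 * sx[3])^2 * anchor[1] / inputSize,
    (2 * sx[4])^2 * anchor[2] / inputSize)
}

#' Encode a ground-truth box into raw grid targets
#'
#' Inverse of the decoding transform at the assigned cell and anchor;
#' `decode(encode(box))` recovers the box to numerical precision provided
#' the box size is within 4x the anchor.
#'
#' @param box numeric `c(cx, cy, w, h)` normalised to the input square.
#' @param gx,gy integer cell coordinates (0-based).
#' @param grid grid size (cells per side).
#' @param anchor numeric `c(w, h)` anchor in pixels.
#' @param inputSize network input size in pixels.
#' @return numeric length-4 raw values `(tx, ty, tw, th)`.
#' @export
encodeBox <- function(box, gx, gy, grid, anchor, inputSize) {
  clamp <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)
  tx <- logit(clamp((box[1] * grid - gx + 0.5) / 2))
  ty <- logit(clamp((box[2] * grid - gy + 0.5) / 2))
  tw <- logit(clamp(sqrt(box[3] * inputSize / anchor[1]) / 2))
  th <- logit(clamp(sqrt(box[4] * inputSize / anchor[2]) / 2))
  c(tx, ty, tw, th)
}

#' @rdname encodeBox
#' @param raw numeric length-4 raw values.
#' @export
decodeBox <- function(raw, gx, gy, grid, anchor, inputSize) {
  decode_box(raw, gx, gy, grid, anchor, inputSize)
}

bce_with_logits <- function(x, t) {
  # numerically stable elementwise BCE
  pmax(x, 0) - x * t + log1p(exp(-abs(x)))
}

#' Detection loss over a batch of raw head outputs
#'
#' Composition: box term `1 - CIoU` of decoded matched pairs, objectness
#' binary cross-entropy over every grid cell (per-head balance weights),
#' class binary cross-entropy at matched cells; total is the gain-weighted
#' sum scaled by the batch size. Also returns the gradient with respect to
#' every raw head output, for the backward pass.
#'
#' @param rawHeads named list of raw head arrays `(Hg, Wg, na*(5+nc), N)`.
#' @param truthsByImage list (length N) of ground-truth data.frames
#'   normalised to the input square.
#' @param anchors named per-head anchor matrices (pixels).
#' @param strides named per-head strides.
#' @param inputSize network input size.
#' @param nClasses number of classes.
#' @param gains loss gains `c(box, obj, cls)`.
#' @param balance per-head objectness weights (named by head id).
#' @return list with `total`, `box`, `obj`, `cls` (scalars) and `dheads`
#'   (named list of gradient arrays).
#' @export
detectionLoss <- function(rawHeads, truthsByImage, anchors, strides,
                          inputSize, nClasses = 4L,
                          gains = c(box = 0.05, obj = 1.0, cls = 0.5),
                          balance = NULL) {
  heads <- names(rawHeads)
  if (is.null(balance)) {
    # reference balance by stride (4 at stride 8, 1 at 16, 0.4 at 32);
    # a duplicated stride-16 head keeps the appended weight 1
    balance <- setNames(vapply(heads, function(h) {
      c(`8` = 4.0, `16` = 1.0, `32` = 0.4)[[as.character(strides[[h]])]]
    }, numeric(1)), heads)
  }
  na <- 3L; natt <- 5L + nClasses
  targets <- build_targets(truthsByImage, anchors, strides, inputSize)
  N <- dim(rawHeads[[1]])[4]
  lbox <- 0; lobj <- 0; lcls <- 0
  nbox <- 0
  dheads <- lapply(rawHeads, function(a) array(0, dim(a)))
  for (h in heads) {
    raw <- rawHeads[[h]]
    d <- dim(raw)
    grid <- d[1]
    tobj <- array(0, c(d[1], d[2], na, d[4]))
    th_t <- if (!is.null(targets)) targets[targets$head == h, , drop = FALSE]
            else NULL
    if (!is.null(th_t) && nrow(th_t)) {
      for (r in seq_len(nrow(th_t))) {
        tt <- th_t[r, ]
        a0 <- (tt$anchor - 1L) * natt
        ri <- tt$gy + 1L; ci <- tt$gx + 1L; n <- tt$image
        t4 <- raw[ri, ci, a0 + 1:4, n]
        anc <- anchors[[h]][tt$anchor, ]
        pb <- decode_box(t4, tt$gx, tt$gy, grid, anc, inputSize)
        tb <- c(tt$cx, tt$cy, tt$w, tt$h)
        ci_val <- ciou(pb, tb)
        lbox <- lbox + (1 - ci_val)
        nbox <- nbox + 1
        # CIoU gradient w.r.t. the decoded box by central differences,
        # chained with the analytic decode jacobian (diagonal)
        eps <- 1e-5
        dci <- vapply(1:4, function(q) {
          p1 <- pb; p2 <- pb
          p1[q] <- p1[q] + eps; p2[q] <- p2[q] - eps
          (ciou(p1, tb) - ciou(p2, tb)) / (2 * eps)
        }, numeric(1))
        sx <- sigmoid(t4)
        jac <- c(2 * sx[1] * (1 - sx[1]) / grid,
                 2 * sx[2] * (1 - sx[2]) / grid,
                 8 * sx[3] * (2 * sx[3]) * (1 - sx[3]) / 2 * anc[1] / inputSize,
                 8 * sx[4] * (2 * sx[4]) * (1 - sx[4]) / 2 * anc[2] / inputSize)
        dheads[[h]][ri, ci, a0 + 1:4, n] <-
          dheads[[h]][ri, ci, a0 + 1:4, n] - gains[["box"]] * dci * jac
        # class BCE at the matched cell
        cl <- raw[ri, ci, a0 + 5L + seq_len(nClasses), n]
        tcl <- as.numeric(seq_len(nClasses) - 1L == tt$class)
        lcls <- lcls + sum(bce_with_logits(cl, tcl))
        dheads[[h]][ri, ci, a0 + 5L + seq_len(nClasses), n] <-
          dheads[[h]][ri, ci, a0 + 5L + seq_len(nClasses), n] +
          gains[["cls"]] * (sigmoid(cl) - tcl)
        tobj[ri, ci, tt$anchor, n] <- 1
      }
    }
    oi <- rep(seq(5L, by = natt, length.out = na), each = 1)
    obj_raw <- raw[, , oi, , drop = FALSE]
    nel <- length(obj_raw)
    lobj <- lobj + balance[[h]] * sum(bce_with_logits(obj_raw, tobj)) / nel
    dheads[[h]][, , oi, ] <- dheads[[h]][, , oi, ] +
      c(gains[["obj"]] * balance[[h]] * (sigmoid(obj_raw) - tobj) / nel)
  }
  nbox <- max(nbox, 1)
  # normalise box/cls by the number of targets; gradients above are summed,
  # so rescale them identically
  for (h in heads) {
    d <- dim(rawHeads[[h]]); natt_i <- natt
    box_cls_idx <- setdiff(seq_len(d[3]),
                           rep(seq(5L, by = natt_i, length.out = na)))
    dheads[[h]][, , box_cls_idx, ] <- dheads[[h]][, , box_cls_idx, ] / nbox
  }
  box_l <- gains[["box"]] * lbox / nbox
  cls_l <- gains[["cls"]] * lcls / nbox
  obj_l <- gains[["obj"]] * lobj
  list(total = (box_l + cls_l + obj_l) * N, box = box_l, obj = obj_l,
       cls = cls_l, dheads = lapply(dheads, function(a) a * N),
       nTargets = nbox)
}
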