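# Detection evaluation: IoU, greedy confidence-ordered matching
# (PASCAL-VOC protocol), precision, recall, average precision with the
# monotone-envelope/trapezoid integration, and the per-class report.
#
# Detections are rows of a data.frame with columns class, cx, cy, w, h,
# conf (plus an optional `image` column when evaluating a whole set);
# ground truths share the box columns.

#' Intersection over union of two boxes
#'
#' Boxes are centre-format numeric vectors `c(cx, cy, w, h)` in a common
#' coordinate frame. Degenerate zero-area boxes yield 0 by convention.
#'
#' @param boxA,boxB numeric length-4 vectors.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(1, 1, 2, 2), c(2, 2, 2, 2))  # 1/7
#' @export
iou <- function(boxA, boxB) {
  if (boxA[3] <= 0 || boxA[4] <= 0 || boxB[3] <= 0 || boxB[4] <= 0) return(0)
  ax1 <- boxA[1] - boxA[3] / 2; ax2 <- boxA[1] + boxA[3] / 2
  ay1 <- boxA[2] - boxA[4] / 2; ay2 <- boxA[2] + boxA[4] / 2
  bx1 <- boxB[1] - boxB[3] / 2; bx2 <- boxB[1] + boxB[3] / 2
  by1 <- boxB[2] - boxB[4] / 2; by2 <- boxB[2] + boxB[4] / 2
  iw <- min(ax2, bx2) - max(ax1, bx1)
  ih <- min(ay2, by2) - max(ay1, by1)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter)
}

# IoU matrix between detection rows and truth rows
iou_matrix <- function(dets, truths) {
  m <- matrix(0, nrow(dets), nrow(truths))
  for (i in seq_len(nrow(dets))) {
    a <- as.numeric(dets[i, c("cx", "cy", "w", "h")])
    for (j in seq_len(nrow(truths))) {
      m[i, j] <- iou(a, as.numeric(truths[j, c("cx", "cy", "w", "h")]))
    }
  }
  m
}

#' Match detections to ground truths (greedy, confidence-ordered)
#'
#' Detections are processed in decreasing confidence (ties: lower row
#' index first). Each detection claims the highest-IoU unmatched truth of
#' the same class (within the same image, when an `image` column is
#' present) provided IoU >= `iouThr`; otherwise it is a false positive.
#' Unmatched truths are false negatives. Each truth is claimed at most
#' once, so duplicate detections are penalised.
#'
#' @param dets detection data.frame (`class`, `cx`, `cy`, `w`, `h`, `conf`).
#' @param truths ground-truth data.frame (`class`, `cx`, `cy`, `w`, `h`).
#' @param iouThr IoU threshold (default 0.5).
#' @return list with `counts` (list `tp`, `fp`, `fn`) and `tpFlag`
#'   (logical per detection, in the original row order).
#' @export
matchDetections <- function(dets, truths, iouThr = 0.5) {
  nD <- nrow(dets); nT <- nrow(truths)
  tpFlag <- logical(nD)
  if (nD > 0) {
    ord <- order(-dets$conf, seq_len(nD))
    img_d <- if ("image" %in% names(dets)) dets$image else rep(1L, nD)
    img_t <- if ("image" %in% names(truths)) truths$image else rep(1L, max(nT, 1L))
    used <- logical(nT)
    for (i in ord) {
      cand <- which(!used & truths$class == dets$class[i] &
                      img_t == img_d[i])
      if (!length(cand)) next
      ious <- vapply(cand, function(j) {
        iou(as.numeric(dets[i, c("cx", "cy", "w", "h")]),
            as.numeric(truths[j, c("cx", "cy", "w", "h")]))
      }, numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iouThr) {
        used[cand[best]] <- TRUE
        tpFlag[i] <- TRUE
      }
    }
  }
  tp <- sum(tpFlag)
  list(counts = list(tp = tp, fp = nD - tp, fn = nT - tp), tpFlag = tpFlag)
}

#' Precision and recall from confusion counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, with the
#' zero-denominator convention fixed to 0 so the report is total.
#'
#' @param counts list or data.frame with `tp`, `fp`, `fn`.
#' @return numeric in `[0, 1]`.
#' @examples
#' precision(list(tp = 8, fp = 2, fn = 0))  # 0.8
#' recall(list(tp = 6, fp = 0, fn = 2))     # 0.75
#' @export
precision <- function(counts) {
  d <- counts$tp + counts$fp
  if (d == 0) 0 else counts$tp / d
}

#' @rdname precision
#' @export
recall <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0) 0 else counts$tp / d
}

# PR points of one class: cumulative precision/recall along the
# confidence-ordered detection list
pr_points <- function(dets, truths, iouThr) {
  nT <- nrow(truths)
  if (nrow(dets) == 0 || nT == 0) {
    return(list(rec = numeric(), prec = numeric()))
  }
  ord <- order(-dets$conf, seq_len(nrow(dets)))
  m <- matchDetections(dets, truths, iouThr)
  tp_sorted <- m$tpFlag[ord]
  cum_tp <- cumsum(tp_sorted)
  cum_fp <- cumsum(!tp_sorted)
  list(rec = cum_tp / nT, prec = cum_tp / (cum_tp + cum_fp))
}

# envelope + trapezoid over the PR points, with (0, 1) prepended; recall
# never reached contributes nothing
integrate_pr <- function(rec, prec) {
  if (!length(rec)) return(0)
  r <- c(0, rec); p <- c(1, prec)
  p <- rev(cummax(rev(p)))
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Average precision of one class
#'
#' Sweeps the confidence over all detection scores, builds the
#' precision-recall curve by greedy matching, applies the monotone
#' precision envelope and integrates by trapezoid over recall. The curve
#' is anchored at (recall 0, precision 1); recall that is never reached
#' contributes no area.
#'
#' @param dets detections of one class (may span images via an `image`
#'   column).
#' @param truths ground truths of the same class.
#' @param iouThr IoU threshold.
#' @return AP in `[0, 1]`.
#' @export
averagePrecision <- function(dets, truths, iouThr = 0.5) {
  pts <- pr_points(dets, truths, iouThr)
  integrate_pr(pts$rec, pts$prec)
}

#' Per-class evaluation report with mAP
#'
#' Computes per-class precision/recall at two operating points (all
#' detections above `confThr`, and the best-F1 confidence) plus AP, and
#' the unweighted mean AP over the classes present in the ground truth.
#' Classes with zero ground-truth boxes are excluded from the mean with a
#' warning.
#'
#' @param dets detection data.frame across the evaluation set.
#' @param truths ground-truth data.frame.
#' @param iouThr IoU threshold (0.5 for the standard report).
#' @param confThr fixed-confidence operating point for precision/recall.
#' @param classes integer ids to report on (default: the four-class map).
#' @return an `EvalReport` (list with `perClass` data.frame, `map`,
#'   `iouThr`, `confThr`).
#' @export
mapAt <- function(dets, truths, iouThr = 0.5, confThr = 0.25,
                  classes = unname(classMap())) {
  rows <- list(); aps <- numeric()
  for (cl in classes) {
    d <- dets[dets$class == cl, , drop = FALSE]
    t <- truths[truths$class == cl, , drop = FALSE]
    if (nrow(t) == 0) {
      warning(sprintf("class %d has no ground truth; excluded from mAP", cl))
      next
    }
    ap <- averagePrecision(d, t, iouThr)
    mfix <- matchDetections(d[d$conf >= confThr, , drop = FALSE], t, iouThr)
    # best-F1 operating point over the detection scores
    pts <- pr_points(d, t, iouThr)
    f1 <- if (length(pts$rec)) {
      2 * pts$rec * pts$prec / pmax(pts$rec + pts$prec, 1e-12)
    } else 0
    bi <- if (length(pts$rec)) which.max(f1) else NA
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, name = className(cl), n = nrow(t),
      precision = precision(mfix$counts), recall = recall(mfix$counts),
      precisionF1 = if (is.na(bi[1])) 0 else pts$prec[bi],
      recallF1 = if (is.na(bi[1])) 0 else pts$rec[bi],
      ap = ap)
    aps <- c(aps, ap)
  }
  perClass <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = integer(), name = character(), n = integer(),
               precision = numeric(), recall = numeric(),
               precisionF1 = numeric(), recallF1 = numeric(), ap = numeric())
  structure(list(perClass = perClass,
                 map = if (length(aps)) mean(aps) else 0,
                 iouThr = iouThr, confThr = confThr),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("Evaluation report (IoU %.2f, conf %.2f)\n", x$iouThr,
              x$confThr))
  if (nrow(x$perClass)) {
    df <- x$perClass
    df[, c("precision", "recall", "precisionF1", "recallF1", "ap")] <-
      round(df[, c("precision", "recall", "precisionF1", "recallF1", "ap")], 3)
    print(df, row.names = FALSE)
  }
  cat(sprintf("mAP@%.1f = %.3f\n", x$iouThr, x$map))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' @param report an `EvalReport` from [mapAt()].
#' @param path CSV output path.
#' @return `path` invisibly.
#' @export
writeEvalReport <- function(report, path) {
  df <- report$perClass
  df$map <- report$map
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
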