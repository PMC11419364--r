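# Anchor priors: k-means over box widths/heights with an IoU-style
# distance, the adaptive-anchor step run before training.

wh_iou <- function(w1, h1, w2, h2) {
  inter <- pmin(w1, w2) * pmin(h1, h2)
  inter / (w1 * h1 + w2 * h2 - inter)
}

#' Compute per-head anchors from training boxes
#'
#' Runs Lloyd k-means with distance `1 - IoU` on the absolute
#' (width, height) of the training boxes at the network input scale, with
#' `k = anchorsPerHead * length(strides)` clusters. Clusters are sorted
#' by area ascending and chunked to the heads in ascending stride order,
#' so small anchors land on high-resolution heads (stride ties resolved
#' by head id).
#'
#' @param boxes ground-truth data.frame with normalised `w`, `h`.
#' @param strides named integer, head id -> stride (as in a
#'   [ModelGraph-class]).
#' @param inputSize network input size in pixels.
#' @param anchorsPerHead anchors per head (3).
#' @param maxIter Lloyd iteration cap.
#' @return named list: head id -> `anchorsPerHead x 2` matrix of
#'   (width, height) in pixels.
#' @export
computeAnchors <- function(boxes, strides, inputSize = 640L,
                           anchorsPerHead = 3L, maxIter = 100L) {
  k <- anchorsPerHead * length(strides)
  if (nrow(boxes) < k) {
    stop(sprintf(paste0("need at least %d boxes for %d anchor clusters; ",
                        "consider the default anchors"), k, k))
  }
  wh <- cbind(boxes$w, boxes$h) * inputSize
  # deterministic init: spread seeds over the area-sorted boxes
  ord <- order(wh[, 1] * wh[, 2], seq_len(nrow(wh)))
  centres <- wh[ord[round(seq(1, nrow(wh), length.out = k))], , drop = FALSE]
  assign_prev <- rep(0L, nrow(wh))
  for (it in seq_len(maxIter)) {
    sim <- sapply(seq_len(k), function(j) {
      wh_iou(wh[, 1], wh[, 2], centres[j, 1], centres[j, 2])
    })
    asg <- max.col(sim, ties.method = "first")
    if (identical(asg, assign_prev)) break
    assign_prev <- asg
    for (j in seq_len(k)) {
      if (any(asg == j)) {
        centres[j, ] <- colMeans(wh[asg == j, , drop = FALSE])
      }
    }
  }
  ord_c <- order(centres[, 1] * centres[, 2])
  centres <- centres[ord_c, , drop = FALSE]
  head_order <- names(sort(strides))  # ascending stride, id breaks ties
  out <- list()
  for (i in seq_along(head_order)) {
    out[[head_order[i]]] <-
      centres[(i - 1) * anchorsPerHead + seq_len(anchorsPerHead), ,
              drop = FALSE]
  }
  out[names(strides)]
}

#' Mean best-anchor IoU of a box set
#'
#' For each box, the best shape IoU against any anchor of any head;
#' averaged over boxes. A value above 0.5 indicates the anchor set covers
#' the box shapes well.
#'
#' @param boxes ground-truth data.frame with normalised `w`, `h`.
#' @param anchors named list of per-head anchor matrices (pixels).
#' @param inputSize network input size.
#' @return numeric scalar.
#' @export
meanBestAnchorIoU <- function(boxes, anchors, inputSize = 640L) {
  all_a <- do.call(rbind, anchors)
  mean(vapply(seq_len(nrow(boxes)), function(i) {
    max(wh_iou(boxes$w[i] * inputSize, boxes$h[i] * inputSize,
               all_a[, 1], all_a[, 2]))
  }, numeric(1)))
}
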