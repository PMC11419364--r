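# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately share no code with the
# implementation paths they check.

# average precision by re-matching from scratch at every distinct
# confidence threshold, then envelope + trapezoid on the resulting curve
oracle_average_precision <- function(dets, truths, iouThr) {
  if (nrow(dets) == 0 || nrow(truths) == 0) return(0)
  thrs <- sort(unique(dets$conf), decreasing = TRUE)
  rec <- prec <- numeric(length(thrs))
  for (k in seq_along(thrs)) {
    sub <- dets[dets$conf >= thrs[k], , drop = FALSE]
    m <- matchDetections(sub, truths, iouThr)
    rec[k] <- m$counts$tp / nrow(truths)
    prec[k] <- if (nrow(sub)) m$counts$tp / nrow(sub) else 0
  }
  r <- c(0, rec); p <- c(1, prec)
  p <- rev(cummax(rev(p)))
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

# literal-definition NMS: repeatedly take the highest-confidence
# unsuppressed box (lower index on ties), keep it, suppress same-class
# overlaps
oracle_nms <- function(dets, iouThr) {
  n <- nrow(dets)
  state <- rep("open", n)
  kept <- integer()
  repeat {
    open <- which(state == "open")
    if (!length(open)) break
    i <- open[order(-dets$conf[open], open)][1]
    state[i] <- "kept"
    kept <- c(kept, i)
    for (j in which(state == "open")) {
      if (dets$class[j] == dets$class[i] &&
          iou(unlist(dets[i, c("cx", "cy", "w", "h")]),
              unlist(dets[j, c("cx", "cy", "w", "h")])) > iouThr) {
        state[j] <- "suppressed"
      }
    }
  }
  kept
}

# random small detection/truth instances for the metric oracles
random_metric_instance <- function(seed, maxBoxes = 10) {
  set.seed(seed)
  nt <- sample(1:4, 1)
  truths <- data.frame(class = sample(0:3, nt, replace = TRUE),
                       cx = runif(nt, 0.2, 0.8), cy = runif(nt, 0.2, 0.8),
                       w = runif(nt, 0.05, 0.3), h = runif(nt, 0.05, 0.3))
  nd <- sample(0:maxBoxes, 1)
  if (nd > 0) {
    base <- truths[sample(nt, nd, replace = TRUE), ]
    dets <- data.frame(class = ifelse(runif(nd) < 0.8, base$class,
                                      sample(0:3, nd, replace = TRUE)),
                       cx = pmin(pmax(base$cx + rnorm(nd, 0, 0.08), 0.05), 0.95),
                       cy = pmin(pmax(base$cy + rnorm(nd, 0, 0.08), 0.05), 0.95),
                       w = pmax(base$w * runif(nd, 0.6, 1.4), 0.02),
                       h = pmax(base$h * runif(nd, 0.6, 1.4), 0.02),
                       conf = round(runif(nd), 3))
  } else {
    dets <- data.frame(class = integer(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric(), conf = numeric())
  }
  list(dets = dets, truths = truths)
}

# shape-aware class oracle: number of hypoechoic connected components of
# a generated scan (smooth, threshold, open, count)
oracle_component_count <- function(scan, S) {
  sm <- t(as.array(EBImage::gblur(EBImage::Image(t(scan$image)),
                                  sigma = S / 80)))
  dark <- sm < 0.30 & scan$sector
  lab <- EBImage::bwlabel(EBImage::opening(EBImage::Image(t(dark)),
                                           EBImage::makeBrush(5, "disc")))
  sizes <- table(as.vector(lab))
  sizes <- sizes[names(sizes) != "0"]
  sum(sizes > 3e-4 * S^2)
}

# expected component count per class id (abdomen, four_chamber, vot,
# three_vessels)
expected_components <- c(`0` = 2L, `1` = 4L, `2` = 1L, `3` = 3L)

# numeric gradient of a scalar function of an array
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# one tiny cached synthetic dataset shared by the data-hungry tests
local_synth_dataset <- local({
  cache <- new.env()
  function(nPerClass = 2, seed = 11, imageSize = 640) {
    key <- paste(nPerClass, seed, imageSize, sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("sectornet_fix_", key))
      if (!dir.exists(dir)) {
        generateDataset(nPerClass, ratios = c(1, 0, 0), seed = seed,
                        outDir = dir, imageSize = imageSize)
      }
      cache[[key]] <- dir
    }
    cache[[key]]
  }
})
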