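# Training driver: configuration, the SGD loop with warmup and linear
# decay, per-epoch logging, checkpoint selection by validation mAP.

#' Training configuration
#'
#' Defaults follow the published regimen: 300 epochs, batch size 32,
#' 640x640 input, no pretrained weights. The optimiser is stochastic
#' gradient descent with momentum, linear warmup and linear decay; mosaic
#' augmentation is on by default and switchable.
#'
#' @param epochs training epochs.
#' @param batchSize images per gradient step.
#' @param inputSize square network input (multiple of 32).
#' @param pretrained must be `FALSE`; no pretrained weights are used.
#' @param seed RNG seed controlling initialisation, shuffling and mosaic.
#' @param lr0 initial learning rate (after warmup).
#' @param lrf final learning-rate fraction of `lr0`.
#' @param momentum SGD momentum.
#' @param weightDecay L2 penalty on convolution weights.
#' @param warmupIters linear warmup iterations.
#' @param mosaic enable mosaic augmentation.
#' @param evalEvery validate (and checkpoint) every this many epochs.
#' @param nClasses number of classes.
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(epochs = 300L, batchSize = 32L, inputSize = 640L,
                        pretrained = FALSE, seed = 0L, lr0 = 0.01,
                        lrf = 0.1, momentum = 0.937, weightDecay = 5e-4,
                        warmupIters = 20L, mosaic = TRUE, evalEvery = 1L,
                        nClasses = 4L) {
  if (inputSize %% 32 != 0) stop("`inputSize` must be a multiple of 32")
  if (isTRUE(pretrained)) {
    stop("pretrained weights are not used by this model family")
  }
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 inputSize = as.integer(inputSize), pretrained = FALSE,
                 seed = as.integer(seed), lr0 = lr0, lrf = lrf,
                 momentum = momentum, weightDecay = weightDecay,
                 warmupIters = as.integer(warmupIters),
                 mosaic = isTRUE(mosaic), evalEvery = as.integer(evalEvery),
                 nClasses = as.integer(nClasses)),
            class = "TrainConfig")
}

# load one split of a YOLO-layout dataset into memory
load_yolo_split <- function(dir, part, nClasses = 4L) {
  imgdir <- file.path(dir, "images", part)
  if (!dir.exists(imgdir)) return(list())
  files <- sort(list.files(imgdir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE))
  lapply(files, function(f) {
    id <- sub("\\.[^.]+$", "", f)
    list(id = id, image = readImageArray(file.path(imgdir, f)),
         boxes = readYoloLabels(file.path(dir, "labels", part,
                                          paste0(id, ".txt")), nClasses))
  })
}

# letterbox an item to the network input and carry its boxes along
prep_item <- function(item, inputSize) {
  lb <- letterbox(item$image, inputSize)
  list(id = item$id, image = lb$image,
       boxes = if (nrow(item$boxes)) boxesToLetterbox(item$boxes,
                                                      lb$transform)
               else item$boxes)
}

# four-image mosaic: each tile letterboxed to half size into one quadrant
make_mosaic <- function(items, inputSize) {
  s2 <- inputSize %/% 2L
  canvas <- matrix(114 / 255, inputSize, inputSize)
  boxes <- list()
  offs <- list(c(0L, 0L), c(0L, s2), c(s2, 0L), c(s2, s2))
  for (q in 1:4) {
    it <- items[[q]]
    sc <- min(s2 / dim(it$image)[1], s2 / dim(it$image)[2])
    nh <- max(1L, round(dim(it$image)[1] * sc))
    nw <- max(1L, round(dim(it$image)[2] * sc))
    tile <- resize_gray(if (length(dim(it$image)) == 3L) it$image[, , 1]
                        else it$image, nh, nw)
    py <- offs[[q]][1] + (s2 - nh) %/% 2L
    px <- offs[[q]][2] + (s2 - nw) %/% 2L
    canvas[py + seq_len(nh), px + seq_len(nw)] <- tile
    if (nrow(it$boxes)) {
      b <- it$boxes
      b$cx <- (b$cx * dim(it$image)[2] * sc + px) / inputSize
      b$cy <- (b$cy * dim(it$image)[1] * sc + py) / inputSize
      b$w <- b$w * dim(it$image)[2] * sc / inputSize
      b$h <- b$h * dim(it$image)[1] * sc / inputSize
      boxes[[length(boxes) + 1L]] <- b
    }
  }
  list(image = canvas,
       boxes = if (length(boxes)) do.call(rbind, boxes) else empty_boxes())
}

sgd_step <- function(net, grads, state, lr, momentum, weightDecay) {
  for (p in networkParamPaths(net)) {
    g <- tree_get(grads, p)
    if (is.null(g)) next
    w <- tree_get(net, p)
    key <- paste(p, collapse = "/")
    leaf <- p[length(p)]
    if (weightDecay > 0 && leaf %in% c("w", "w1", "w2")) g <- g + weightDecay * w
    v <- state$vel[[key]]
    if (is.null(v)) v <- 0
    v <- momentum * v - lr * g
    state$vel[[key]] <- v
    net <- tree_set(net, p, w + v)
  }
  list(net = net, state = state)
}

# gradients arrive under grads$layers/<id>/... possibly missing bn nesting
# names; align them with the parameter tree paths
align_grads <- function(grads) grads

#' Train a model variant on a YOLO-layout dataset
#'
#' Runs the SGD loop with the letterbox (and optional mosaic) input
#' pipeline, computes dataset-specific anchors by IoU k-means before the
#' first epoch, logs per-epoch loss components and validation
#' precision/recall/mAP, checkpoints at every evaluation and returns the
#' best checkpoint (highest validation mAP@0.5; ties resolved towards the
#' later epoch).
#'
#' @param variant variant name (see [variantRegistry()]) or a
#'   [ModelGraph-class].
#' @param datasetDir dataset directory in YOLO layout.
#' @param cfg a [trainConfig()].
#' @param valPart split used for validation (`"val"`; falls back to the
#'   training split when empty).
#' @return list with `checkpoint` (`net`, `variant`, `epoch`, `map`,
#'   `anchors`, `inputSize`) and `log` (per-epoch data.frame).
#' @export
trainModel <- function(variant, datasetDir, cfg = trainConfig(),
                       valPart = "val") {
  graph <- if (is.character(variant)) buildVariant(variant, cfg$nClasses)
           else variant
  vname <- if (is.character(variant)) variant else graph@name
  train_items <- load_yolo_split(datasetDir, "train", cfg$nClasses)
  if (!length(train_items)) stop("empty training split in ", datasetDir)
  val_items <- load_yolo_split(datasetDir, valPart, cfg$nClasses)
  if (!length(val_items)) val_items <- train_items

  prepped <- lapply(train_items, prep_item, inputSize = cfg$inputSize)
  val_prepped <- lapply(val_items, prep_item, inputSize = cfg$inputSize)

  all_boxes <- do.call(rbind, lapply(prepped, `[[`, "boxes"))
  anchors <- tryCatch(
    computeAnchors(all_boxes, graph@strides, cfg$inputSize),
    error = function(e) {
      sc <- cfg$inputSize / 640
      lapply(default_anchors()[names(graph@heads)], function(a) a * sc)
    })

  net <- initNetwork(graph, cfg$seed)
  state <- new.env()
  state$vel <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)

  n <- length(prepped)
  iters_per_epoch <- ceiling(n / cfg$batchSize)
  total_iters <- cfg$epochs * iters_per_epoch
  it <- 0L
  best <- NULL
  log <- list()
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(n)
    eb <- eo <- ec <- 0; nb <- 0
    for (b in seq_len(iters_per_epoch)) {
      sel <- ord[((b - 1) * cfg$batchSize + 1):min(b * cfg$batchSize, n)]
      batch <- prepped[sel]
      if (cfg$mosaic && n >= 4) {
        batch <- lapply(batch, function(it0) {
          make_mosaic(train_items[sample(n, 4)], cfg$inputSize)
        })
      }
      B <- length(batch)
      x <- array(0, c(cfg$inputSize, cfg$inputSize, 3, B))
      for (i in seq_len(B)) x[, , , i] <- gray_to_input(batch[[i]]$image)
      truths <- lapply(batch, `[[`, "boxes")
      fwd <- networkForward(net, x, train = TRUE)
      net <- fwd$net
      ls <- detectionLoss(fwd$heads, truths, anchors, net$graph@strides,
                          cfg$inputSize, cfg$nClasses)
      grads <- networkBackward(net, x, fwd, ls$dheads)
      it <- it + 1L
      warm <- min(1, it / max(cfg$warmupIters, 1))
      decay <- 1 - (1 - cfg$lrf) * (it / total_iters)
      lr <- cfg$lr0 * warm * decay
      up <- sgd_step(net, grads, state, lr, cfg$momentum, cfg$weightDecay)
      net <- up$net
      state <- up$state
      eb <- eb + ls$box; eo <- eo + ls$obj; ec <- ec + ls$cls; nb <- nb + 1
    }
    row <- data.frame(epoch = epoch, box = eb / nb, obj = eo / nb,
                      cls = ec / nb, precision = NA, recall = NA, map = NA)
    if (epoch %% cfg$evalEvery == 0 || epoch == cfg$epochs) {
      ck <- list(net = net, variant = vname, epoch = epoch,
                 anchors = anchors, inputSize = cfg$inputSize)
      rep <- evalItems(ck, val_prepped, confThr = 0.1)
      ck$map <- rep$map
      row$map <- rep$map
      row$precision <- mean(rep$perClass$precision)
      row$recall <- mean(rep$perClass$recall)
      if (is.null(best) || ck$map >= best$map) best <- ck
    }
    log[[epoch]] <- row
  }
  list(checkpoint = best, log = do.call(rbind, log))
}

# evaluate a checkpoint on prepared (letterboxed) items
evalItems <- function(checkpoint, items, confThr = 0.1, iouThr = 0.45,
                      matchIou = 0.5) {
  dets <- list(); truths <- list()
  for (i in seq_along(items)) {
    d <- detectObjects(items[[i]]$image, checkpoint, confThr = confThr,
                       iouThr = iouThr)
    if (nrow(d)) { d$image <- i; dets[[length(dets) + 1L]] <- d }
    tb <- items[[i]]$boxes
    if (nrow(tb)) { tb$image <- i; truths[[length(truths) + 1L]] <- tb }
  }
  dets <- if (length(dets)) do.call(rbind, dets) else
    cbind(empty_boxes(), conf = numeric(), image = integer())
  truths <- if (length(truths)) do.call(rbind, truths) else
    cbind(empty_boxes(), image = integer())
  suppressWarnings(mapAt(dets, truths, iouThr = matchIou))
}

#' Evaluate a checkpoint on one split of a dataset
#'
#' Runs detection over every image of the split and computes the
#' per-class precision/recall/AP report with mAP@0.5.
#'
#' @param checkpoint checkpoint from [trainModel()].
#' @param datasetDir dataset directory in YOLO layout.
#' @param part split name (`"test"`, `"val"`, `"train"`).
#' @param confThr detection confidence threshold used for the report's
#'   fixed operating point.
#' @return an `EvalReport`.
#' @export
evalDataset <- function(checkpoint, datasetDir, part = "test",
                        confThr = 0.1) {
  items <- load_yolo_split(datasetDir, part,
                           checkpoint$net$graph@nClasses)
  if (!length(items)) stop("no images in split '", part, "'")
  prepped <- lapply(items, prep_item, inputSize = checkpoint$inputSize)
  evalItems(checkpoint, prepped, confThr = confThr)
}
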