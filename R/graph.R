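# The reference detector topology and its pruning-derived variants.
#
# Layer numbering follows the published convention: 0 = stem convolution,
# 1-11 = the eleven MobileNetV3-Small inverted-residual (bneck) blocks,
# 12 = SPPF, 13-25 = the feature-fusion neck whose concat layers 15, 19,
# 22 and 25 feed the four prediction heads (strides 16, 8, 16, 32).

# MobileNetV3-Small bneck schedule: kernel, expansion, out, SE, activation,
# stride. Blocks 10-11 take their expansion width from the calibrated
# width assignment instead of the stock 576.
mnv3_small_schedule <- function(widths) {
  list(
    list(kernel = 3L, exp = 16L,  cout = 16L, se = TRUE,  act = "relu",   stride = 2L),
    list(kernel = 3L, exp = 72L,  cout = 24L, se = FALSE, act = "relu",   stride = 2L),
    list(kernel = 3L, exp = 88L,  cout = 24L, se = FALSE, act = "relu",   stride = 1L),
    list(kernel = 5L, exp = 96L,  cout = 40L, se = TRUE,  act = "hswish", stride = 2L),
    list(kernel = 5L, exp = 240L, cout = 40L, se = TRUE,  act = "hswish", stride = 1L),
    list(kernel = 5L, exp = 240L, cout = 40L, se = TRUE,  act = "hswish", stride = 1L),
    list(kernel = 5L, exp = 120L, cout = 48L, se = TRUE,  act = "hswish", stride = 1L),
    list(kernel = 5L, exp = 144L, cout = 48L, se = TRUE,  act = "hswish", stride = 1L),
    list(kernel = 5L, exp = 288L, cout = 96L, se = TRUE,  act = "hswish", stride = 2L),
    list(kernel = 5L, exp = widths$bneck10_exp, cout = 96L, se = TRUE,
         act = "hswish", stride = 1L),
    list(kernel = 5L, exp = widths$bneck11_exp, cout = 96L, se = TRUE,
         act = "hswish", stride = 1L)
  )
}

#' Calibrated channel widths of the reference graph
#'
#' The free widths of the architecture (neck convolution widths, the
#' expansion of backbone blocks 10-11, the SPPF reduction width) are not
#' derivable from the published figures; they are fixed once by
#' [calibrateWidths()] against the published per-variant parameter counts
#' and shipped here as the canonical assignment.
#'
#' @return named list of integer channel widths.
#' @export
emnWidths <- function() {
  list(bneck10_exp = 504L, bneck11_exp = 504L, sppf_hidden = 48L,
       c13 = 24L, c16 = 136L, c18 = 56L, c20 = 96L, c21 = 312L,
       c23 = 80L, c24 = 336L)
}

# default anchors before dataset-specific k-means, scaled per stride from
# the standard single-stage defaults
default_anchors <- function() {
  list(`1` = matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
       `2` = matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
       `3` = matrix(c(45, 91, 93, 67, 88, 178), ncol = 2, byrow = TRUE),
       `4` = matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))
}

#' Build the full reference model graph
#'
#' Returns the unpruned topology with all 26 layers and all four
#' prediction heads. Heads read the concat layers 15, 19, 22 and 25 with
#' strides 16, 8, 16 and 32 relative to the input image.
#'
#' @param nClasses number of object classes (>= 1; the fetal-section task
#'   uses 4).
#' @param widths channel-width assignment, defaulting to the calibrated
#'   canonical widths ([emnWidths()]).
#' @return a [ModelGraph-class].
#' @examples
#' g <- fullGraph(4)
#' headLayers(g)
#' @export
fullGraph <- function(nClasses = 4L, widths = emnWidths()) {
  nClasses <- as.integer(nClasses)
  if (nClasses < 1L) stop("`nClasses` must be >= 1")
  sched <- mnv3_small_schedule(widths)
  layers <- list(layer_spec(0, "conv", -1, cout = 16L, k = 3L, stride = 2L,
                            act = "hswish"))
  for (i in seq_along(sched)) {
    s <- sched[[i]]
    layers[[length(layers) + 1L]] <-
      layer_spec(i, "bneck", -1, kernel = s$kernel, exp = as.integer(s$exp),
                 cout = s$cout, se = s$se, act = s$act, stride = s$stride)
  }
  w <- widths
  add <- function(.index, .kind, .from, ...) {
    layers[[length(layers) + 1L]] <<- layer_spec(.index, .kind, .from, ...)
  }
  add(12, "sppf", -1, hidden = as.integer(w$sppf_hidden), cout = 96L, k = 5L)
  add(13, "conv", -1, cout = as.integer(w$c13), k = 1L, stride = 1L, act = "hswish")
  add(14, "upsample", -1)
  add(15, "concat", c(14, 8))
  add(16, "conv", -1, cout = as.integer(w$c16), k = 1L, stride = 1L, act = "hswish")
  add(17, "upsample", -1)
  add(18, "conv", -1, cout = as.integer(w$c18), k = 1L, stride = 1L, act = "hswish")
  add(19, "concat", c(18, 3))
  add(20, "conv", -1, cout = as.integer(w$c20), k = 3L, stride = 2L, act = "hswish")
  add(21, "conv", -1, cout = as.integer(w$c21), k = 1L, stride = 1L, act = "hswish")
  add(22, "concat", c(21, 16))
  add(23, "conv", -1, cout = as.integer(w$c23), k = 3L, stride = 2L, act = "hswish")
  add(24, "conv", -1, cout = as.integer(w$c24), k = 1L, stride = 1L, act = "hswish")
  add(25, "concat", c(24, 13))
  g <- new("ModelGraph", name = "emn_full", layers = layers,
           heads = c(`1` = 15L, `2` = 19L, `3` = 22L, `4` = 25L),
           strides = c(`1` = 16L, `2` = 8L, `3` = 16L, `4` = 32L),
           nClasses = nClasses, anchors = default_anchors())
  validObject(g)
  g
}

#' The five published model variants
#'
#' Kept layer ranges and prediction heads for each pruning-derived model,
#' exactly as tabulated for the series: emnxx keeps layers 0-25 with heads
#' 2-4; emnx 0-22 with heads 2-3; emnl 0-19 with heads 1-2; emnm drops
#' backbone blocks 10-11 (0-9, 12-22, heads 2-3); emns is the smallest
#' (0-9, 12-19, heads 1-2).
#'
#' @return named list of [VariantSpec-class].
#' @export
variantRegistry <- function() {
  v <- function(name, kept, heads)
    new("VariantSpec", name = name, keptLayers = as.integer(kept),
        keptHeads = as.integer(heads))
  list(
    emnxx = v("emnxx", 0:25, c(2, 3, 4)),
    emnx  = v("emnx", 0:22, c(2, 3)),
    emnl  = v("emnl", 0:19, c(1, 2)),
    emnm  = v("emnm", c(0:9, 12:22), c(2, 3)),
    emns  = v("emns", c(0:9, 12:19), c(1, 2))
  )
}

#' Derive a pruned model variant from the full graph
#'
#' Keeps only the variant's layers and heads. A `from` reference into a
#' removed layer is rerouted to its nearest kept ancestor along the chain
#' of first sources (deterministic and order-independent). The published
#' layer indices are preserved so that per-layer comparisons against the
#' full graph remain direct.
#'
#' @param name variant name (`emns`, `emnm`, `emnl`, `emnx`, `emnxx`).
#' @param nClasses number of object classes.
#' @param widths channel-width assignment (see [emnWidths()]).
#' @return a [ModelGraph-class].
#' @examples
#' buildVariant("emns", 4)
#' @export
buildVariant <- function(name, nClasses = 4L, widths = emnWidths()) {
  reg <- variantRegistry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown variant '%s'; valid names: %s", name,
                 paste(names(reg), collapse = ", ")))
  }
  spec <- reg[[name]]
  pruneGraph(fullGraph(nClasses, widths), spec@keptLayers, spec@keptHeads,
             name = paste0("emn_", name))
}

#' Prune a model graph to a subset of layers and heads
#'
#' @param graph a [ModelGraph-class].
#' @param keptLayers integer layer indices to keep (must include layer 0).
#' @param keptHeads integer head ids to keep.
#' @param name name for the derived graph.
#' @return a [ModelGraph-class].
#' @export
pruneGraph <- function(graph, keptLayers, keptHeads, name = "pruned") {
  keptLayers <- sort(unique(as.integer(keptLayers)))
  if (!0L %in% keptLayers) stop("layer 0 (the stem) cannot be pruned")
  idx <- layerIndices(graph)
  if (!all(keptLayers %in% idx)) stop("keptLayers outside the graph")
  by_index <- setNames(graph@layers, idx)
  # resolve -1 to absolute indices first
  prev <- -1L
  layers <- lapply(graph@layers, function(l) {
    l@from[l@from == -1L] <- prev
    prev <<- l@index
    l
  })
  names(layers) <- idx
  ancestor <- function(j) {
    while (j != -1L && !(j %in% keptLayers)) {
      j <- layers[[as.character(j)]]@from[1]
    }
    j
  }
  out <- lapply(layers[as.character(keptLayers)], function(l) {
    l@from <- vapply(l@from, ancestor, integer(1))
    l
  })
  keptHeads <- as.character(sort(as.integer(keptHeads)))
  if (!all(keptHeads %in% names(graph@heads))) stop("unknown head id")
  heads <- graph@heads[keptHeads]
  if (!all(heads %in% keptLayers)) {
    stop("a kept head reads a pruned layer")
  }
  g <- new("ModelGraph", name = name, layers = unname(out), heads = heads,
           strides = graph@strides[keptHeads], nClasses = graph@nClasses,
           anchors = graph@anchors[keptHeads])
  validObject(g)
  g
}

# Channel/stride propagation: for each layer, its input channels, output
# channels and cumulative stride. Used by parameter counting, shape
# inference and the network builder.
graphInfo <- function(graph) {
  idx <- layerIndices(graph)
  info <- list()
  prev <- NULL
  for (l in graph@layers) {
    from <- l@from
    from[from == -1L] <- if (is.null(prev)) -1L else prev
    if (l@index == idx[1]) {
      src_c <- 3L; src_s <- 1
    } else {
      src_c <- vapply(from, function(j) info[[as.character(j)]]$cout, numeric(1))
      src_s <- vapply(from, function(j) info[[as.character(j)]]$stride, numeric(1))
    }
    e <- switch(l@kind,
      conv = list(cin = src_c[1], cout = l@hyper$cout,
                  stride = src_s[1] * l@hyper$stride),
      bneck = list(cin = src_c[1], cout = l@hyper$cout,
                   stride = src_s[1] * l@hyper$stride),
      sppf = list(cin = src_c[1], cout = l@hyper$cout, stride = src_s[1]),
      upsample = list(cin = src_c[1], cout = src_c[1], stride = src_s[1] / 2),
      concat = {
        if (length(unique(src_s)) != 1L) {
          stop(sprintf("concat layer %d mixes strides %s", l@index,
                       paste(src_s, collapse = ", ")))
        }
        list(cin = sum(src_c), cout = sum(src_c), stride = src_s[1])
      })
    e$from <- from
    info[[as.character(l@index)]] <- e
    prev <- l@index
  }
  info
}

#' Per-head output grid shapes
#'
#' @param graph a [ModelGraph-class].
#' @param inputSize square input size in pixels, divisible by 32.
#' @return named list: head id -> `c(rows, cols)` of the prediction grid.
#' @examples
#' forwardShapes(buildVariant("emnl", 4), 640)
#' @export
forwardShapes <- function(graph, inputSize = 640L) {
  if (inputSize %% 32 != 0 || inputSize <= 0) {
    stop("`inputSize` must be a positive multiple of 32")
  }
  lapply(setNames(nm = names(graph@heads)), function(h) {
    g <- inputSize / graph@strides[[h]]
    c(g, g)
  })
}
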