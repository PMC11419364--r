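#' Declarative layer specification
#'
#' A `LayerSpec` is one node of the computational graph: an index, a kind
#' (`conv`, `bneck`, `sppf`, `upsample`, `concat`), the indices of its
#' source layers (`-1` meaning "previous layer" is resolved at build time),
#' and kind-specific hyper-parameters.
#'
#' @slot index integer layer index (0-based, matching the published layer
#'   numbering).
#' @slot kind character, one of `conv`, `bneck`, `sppf`, `upsample`, `concat`.
#' @slot from integer vector of source layer indices (0-based; all `< index`).
#' @slot hyper named list of hyper-parameters.
#' @export
setClass("LayerSpec",
  representation(index = "integer", kind = "character",
                 from = "integer", hyper = "list"))

setValidity("LayerSpec", function(object) {
  kinds <- c("conv", "bneck", "sppf", "upsample", "concat")
  if (!object@kind %in% kinds) {
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  }
  if (length(object@from) < 1L) return("every layer needs at least one source")
  if (any(object@from >= object@index)) {
    return("all `from` indices must be smaller than the layer index")
  }
  if (object@kind == "concat" && length(object@from) < 2L) {
    return("concat layers need at least two sources")
  }
  TRUE
})

#' Declarative model graph
#'
#' The whole detector as data: an ordered list of [LayerSpec-class] nodes,
#' a mapping from prediction-head id to the concat layer it reads, the
#' number of object classes, and per-head anchor boxes. Every model variant
#' is derived from one full graph by pruning (see [buildVariant()]).
#'
#' @slot name character model name.
#' @slot layers list of [LayerSpec-class], ordered by index.
#' @slot heads named integer: head id ("1".."4") -> layer index it reads.
#' @slot strides named integer: head id -> stride w.r.t. the input image.
#' @slot nClasses integer number of object classes.
#' @slot anchors list: head id -> 3x2 matrix of (width, height) anchor
#'   pixels at the reference input size.
#' @export
setClass("ModelGraph",
  representation(name = "character", layers = "list", heads = "integer",
                 strides = "integer", nClasses = "integer", anchors = "list"))

setValidity("ModelGraph", function(object) {
  idx <- vapply(object@layers, function(l) l@index, integer(1))
  if (is.unsorted(idx, strictly = TRUE)) return("layer indices must increase")
  known <- c(-1L, idx)
  for (l in object@layers) {
    if (!all(l@from %in% known[known < l@index | known == -1L])) {
      return(sprintf("layer %d references an unknown source", l@index))
    }
  }
  if (length(object@heads)) {
    if (!all(object@heads %in% idx)) {
      return("every head must point at an existing layer")
    }
    kind_of <- setNames(vapply(object@layers, function(l) l@kind,
                               character(1)), idx)
    if (!all(kind_of[as.character(object@heads)] == "concat")) {
      return("heads must read concat layers")
    }
  }
  if (object@nClasses < 1L) return("nClasses must be >= 1")
  TRUE
})

#' @describeIn ModelGraph-class number of layers in the graph.
#' @param x,object a `ModelGraph`.
#' @export
nLayers <- function(x) length(x@layers)

#' @describeIn ModelGraph-class named integer of head id -> layer index.
#' @export
headLayers <- function(x) x@heads

#' @describeIn ModelGraph-class integer layer indices present in the graph.
#' @export
layerIndices <- function(x) vapply(x@layers, function(l) l@index, integer(1))

#' @describeIn ModelGraph-class number of object classes.
#' @export
nClasses <- function(x) x@nClasses

setMethod("show", "ModelGraph", function(object) {
  cat(sprintf("ModelGraph '%s': %d layers, %d head(s), %d classes\n",
              object@name, length(object@layers), length(object@heads),
              object@nClasses))
  cat(sprintf("  heads: %s\n", paste(sprintf("%s@L%d(stride %d)",
      names(object@heads), object@heads,
      object@strides[names(object@heads)]), collapse = ", ")))
  cat(sprintf("  trainable parameters: %s\n",
              format(countParameters(object), big.mark = ",")))
  invisible(NULL)
})

#' Variant specification: one row of the published pruning table
#'
#' @slot name one of `emns`, `emnm`, `emnl`, `emnx`, `emnxx`.
#' @slot keptLayers integer indices of the full graph retained.
#' @slot keptHeads integer head ids retained.
#' @export
setClass("VariantSpec",
  representation(name = "character", keptLayers = "integer",
                 keptHeads = "integer"))

setMethod("show", "VariantSpec", function(object) {
  r <- range(object@keptLayers)
  cat(sprintf("VariantSpec '%s': layers {%s}, heads {%s}\n", object@name,
              compress_ranges(object@keptLayers),
              paste(object@keptHeads, collapse = ",")))
  invisible(NULL)
})

compress_ranges <- function(v) {
  v <- sort(unique(v))
  brk <- c(0L, which(diff(v) != 1L), length(v))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    seg <- v[(brk[i] + 1L):brk[i + 1L]]
    if (length(seg) == 1L) as.character(seg)
    else sprintf("%d-%d", seg[1], seg[length(seg)])
  }, character(1)), collapse = ", ")
}

# dotted formals so hyper names like `k` cannot partially match `kind`
layer_spec <- function(.index, .kind, .from, ...) {
  new("LayerSpec", index = as.integer(.index), kind = .kind,
      from = as.integer(.from), hyper = list(...))
}
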