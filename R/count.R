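# Exact trainable-parameter accounting.
#
# Counting conventions (identical to the reference single-stage detector
# implementations): every convolution is bias-free and followed by a batch
# norm whose two affine terms per channel are counted; squeeze-excitation
# and prediction-head convolutions carry biases and no batch norm.

roundup8 <- function(x) as.integer(8 * ceiling(x / 8))

# squeeze-excitation bottleneck width: quarter of the gated channels,
# rounded up to a multiple of 8
se_width <- function(c) roundup8(c / 4)

count_conv <- function(cin, cout, k, groups = 1) k * k * (cin / groups) * cout + 2 * cout

count_se <- function(c) {
  r <- se_width(c)
  c * r + r + r * c + c
}

count_bneck <- function(cin, h) {
  p <- 0
  if (h$exp != cin) p <- p + count_conv(cin, h$exp, 1)
  p <- p + count_conv(h$exp, h$exp, h$kernel, groups = h$exp)
  if (isTRUE(h$se)) p <- p + count_se(h$exp)
  p + count_conv(h$exp, h$cout, 1)
}

count_sppf <- function(cin, h) {
  count_conv(cin, h$hidden, 1) + count_conv(4 * h$hidden, h$cout, 1)
}

count_head <- function(cin, nClasses, nAnchors = 3) {
  cout <- nAnchors * (5 + nClasses)
  cin * cout + cout
}

layer_param_count <- function(kind, cin, hyper) {
  switch(kind,
    conv = count_conv(cin, hyper$cout, hyper$k),
    bneck = count_bneck(cin, hyper),
    sppf = count_sppf(cin, hyper),
    upsample = 0,
    concat = 0)
}

#' Count trainable parameters of a model graph
#'
#' Sums every trainable scalar of the graph: convolution weights, batch
#' norm affine pairs, squeeze-excitation transforms (with biases) and the
#' prediction-head convolutions (with biases). The closed forms are
#' verified in the test suite against brute-force enumeration of the
#' weights of an instantiated network.
#'
#' @param graph a [ModelGraph-class].
#' @param perLayer if `TRUE`, return the named per-layer breakdown
#'   (heads listed as `head<id>`) instead of the total.
#' @return integer total (or named numeric vector when `perLayer`).
#' @examples
#' countParameters(buildVariant("emnxx", 4)) / 1e6
#' @export
countParameters <- function(graph, perLayer = FALSE) {
  stopifnot(is(graph, "ModelGraph"))
  info <- graphInfo(graph)
  counts <- vapply(graph@layers, function(l) {
    layer_param_count(l@kind, info[[as.character(l@index)]]$cin, l@hyper)
  }, numeric(1))
  names(counts) <- vapply(graph@layers, function(l) as.character(l@index),
                          character(1))
  hc <- vapply(names(graph@heads), function(h) {
    count_head(info[[as.character(graph@heads[[h]])]]$cout, graph@nClasses)
  }, numeric(1))
  names(hc) <- paste0("head", names(graph@heads))
  out <- c(counts, hc)
  if (perLayer) out else sum(out)
}

# atomic-module tally per layer kind; the convention (each convolution,
# batch norm, activation, pool, upsample, concat and residual add counted
# once; linear projections carry no activation module) is documented in
# the vignette. Only the ordering across variants is asserted.
layer_module_count <- function(kind, cin, hyper) {
  switch(kind,
    conv = 3,
    bneck = {
      n <- 3 + 2                       # depthwise conv-bn-act + linear projection conv-bn
      if (hyper$exp != cin) n <- n + 3 # expansion conv-bn-act
      if (isTRUE(hyper$se)) n <- n + 6 # pool, fc, relu, fc, hsigmoid, scale
      if (hyper$stride == 1 && cin == hyper$cout) n <- n + 1  # residual add
      n
    },
    sppf = 3 + 3 + 1 + 3,              # conv-bn-act, three pools, concat, conv-bn-act
    upsample = 1,
    concat = 1)
}

#' Count atomic modules of a model graph
#'
#' Flattens the graph into atomic modules (convolutions, batch norms,
#' activations, pools, upsampling, concatenation, residual adds) and
#' counts each once, plus one module per prediction head.
#'
#' @param graph a [ModelGraph-class].
#' @return integer module count.
#' @export
countLayers <- function(graph) {
  stopifnot(is(graph, "ModelGraph"))
  info <- graphInfo(graph)
  n <- sum(vapply(graph@layers, function(l) {
    layer_module_count(l@kind, info[[as.character(l@index)]]$cin, l@hyper)
  }, numeric(1)))
  as.integer(n + length(graph@heads))
}

#' Model series summary table
#'
#' One row per variant with its kept layers, heads, atomic-module count
#' and trainable parameters (absolute and in millions), in the shape of
#' the published series tables.
#'
#' @param nClasses number of object classes.
#' @param widths channel-width assignment.
#' @return a `data.frame`.
#' @examples
#' parameterTable(4)
#' @export
parameterTable <- function(nClasses = 4L, widths = emnWidths()) {
  reg <- variantRegistry()
  rows <- lapply(names(reg), function(nm) {
    g <- buildVariant(nm, nClasses, widths)
    data.frame(model = nm,
               layers = compress_ranges(reg[[nm]]@keptLayers),
               heads = paste(reg[[nm]]@keptHeads, collapse = ","),
               modules = countLayers(g),
               parameters = countParameters(g),
               millions = round(countParameters(g) / 1e6, 2))
  })
  do.call(rbind, rows)[order(vapply(rows, function(r) r$parameters,
                                    numeric(1))), ]
}
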