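#' Read and write model graphs as editable YAML configs
#'
#' The whole architecture is data: one record per layer (`index`, `from`,
#' `kind`, `hyper`), the head map with strides and anchors, and the class
#' count. `writeModelConfig()` followed by `readModelConfig()` round-trips
#' bit-exactly (a second write produces an identical file).
#'
#' @param graph a [ModelGraph-class].
#' @param path file path of the YAML config.
#' @return `readModelConfig()` returns a [ModelGraph-class];
#'   `writeModelConfig()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' writeModelConfig(fullGraph(4), p)
#' g <- readModelConfig(p)
#' @export
writeModelConfig <- function(graph, path) {
  stopifnot(is(graph, "ModelGraph"))
  cfg <- list(
    name = graph@name,
    nClasses = graph@nClasses,
    heads = lapply(setNames(nm = names(graph@heads)), function(h) {
      list(layer = graph@heads[[h]], stride = graph@strides[[h]],
           anchors = apply(graph@anchors[[h]], 1, function(r)
             as.numeric(r), simplify = FALSE))
    }),
    layers = lapply(graph@layers, function(l) {
      rec <- list(index = l@index, from = as.numeric(l@from), kind = l@kind)
      if (length(l@hyper)) rec$hyper <- l@hyper
      rec
    })
  )
  writeLines(yaml::as.yaml(cfg, precision = 12), path)
  invisible(path)
}

#' @rdname writeModelConfig
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  layers <- lapply(cfg$layers, function(rec) {
    hy <- if (is.null(rec$hyper)) list() else rec$hyper
    hy <- lapply(hy, function(v) {
      if (is.numeric(v) && all(v == as.integer(v))) as.integer(v) else v
    })
    new("LayerSpec", index = as.integer(rec$index), kind = rec$kind,
        from = as.integer(rec$from), hyper = hy)
  })
  ids <- names(cfg$heads)
  heads <- vapply(cfg$heads, function(h) as.integer(h$layer), integer(1))
  strides <- vapply(cfg$heads, function(h) as.integer(h$stride), integer(1))
  anchors <- lapply(cfg$heads, function(h) {
    do.call(rbind, lapply(h$anchors, as.numeric))
  })
  names(heads) <- names(strides) <- names(anchors) <- ids
  g <- new("ModelGraph", name = cfg$name, layers = layers, heads = heads,
           strides = strides, nClasses = as.integer(cfg$nClasses),
           anchors = anchors)
  validObject(g)
  g
}
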