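# Instantiate a ModelGraph as a trainable network: a parameter tree plus
# forward/backward passes over the DAG.

#' Instantiate a trainable network from a model graph
#'
#' Allocates He-initialised weights for every layer of the graph and for
#' one prediction head per head id. Initialisation is deterministic given
#' `seed`.
#'
#' @param graph a [ModelGraph-class].
#' @param seed integer RNG seed for weight initialisation.
#' @return a network object (list with `graph`, `layers`, `heads`).
#' @export
initNetwork <- function(graph, seed = 1L) {
  stopifnot(is(graph, "ModelGraph"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  info <- graphInfo(graph)
  layers <- list()
  for (l in graph@layers) {
    key <- as.character(l@index)
    cin <- info[[key]]$cin
    layers[[key]] <- switch(l@kind,
      conv = init_conv_unit(cin, l@hyper$cout, l@hyper$k, l@hyper$stride,
                            l@hyper$act),
      bneck = init_bneck(cin, l@hyper),
      sppf = init_sppf(cin, l@hyper$hidden, l@hyper$cout, l@hyper$k),
      upsample = list(type = "upsample"),
      concat = list(type = "concat"))
  }
  heads <- lapply(setNames(nm = names(graph@heads)), function(h) {
    init_head(info[[as.character(graph@heads[[h]])]]$cout, graph@nClasses)
  })
  structure(list(graph = graph, layers = layers, heads = heads),
            class = "sectornet_network")
}

#' @export
print.sectornet_network <- function(x, ...) {
  cat(sprintf("network '%s': %d layers, heads {%s}, %s parameters\n",
              x$graph@name, length(x$layers),
              paste(names(x$heads), collapse = ","),
              format(networkParameterCount(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass of an instantiated network
#'
#' @param net network from [initNetwork()].
#' @param x input array `(H, W, 3, N)` or `(H, W, 3)`, values in `[0, 1]`.
#' @param train logical; `TRUE` uses batch statistics in the batch norms
#'   (and updates running averages), `FALSE` uses running averages.
#' @return list with `heads` (named list of raw prediction arrays
#'   `(Hg, Wg, nAnchors * (5 + nClasses), N)`), `caches` (when `train`),
#'   and the updated `net`.
#' @export
networkForward <- function(net, x, train = FALSE) {
  x <- as_nhwc(x)
  graph <- net$graph
  info <- graphInfo(graph)
  outs <- list(); caches <- list()
  for (l in graph@layers) {
    key <- as.character(l@index)
    from <- info[[key]]$from
    xin <- if (from[1] == -1L) x else outs[[as.character(from[1])]]
    p <- net$layers[[key]]
    r <- switch(l@kind,
      conv = conv_unit_fwd(p, xin, train),
      bneck = bneck_fwd(p, xin, train),
      sppf = sppf_fwd(p, xin, train),
      upsample = list(y = upsample2_fwd(xin), params = p, cache = NULL),
      concat = {
        srcs <- lapply(from, function(j) outs[[as.character(j)]])
        list(y = do.call(abind4, srcs), params = p,
             cache = list(channels = vapply(srcs, function(s) dim(s)[3],
                                            numeric(1))))
      })
    net$layers[[key]] <- r$params
    outs[[key]] <- r$y
    caches[[key]] <- r$cache
  }
  heads <- list(); hcaches <- list()
  for (h in names(graph@heads)) {
    r <- head_fwd(net$heads[[h]], outs[[as.character(graph@heads[[h]])]])
    heads[[h]] <- r$y
    hcaches[[h]] <- r$cache
  }
  list(heads = heads, outs = if (train) outs, caches = if (train) caches,
       hcaches = if (train) hcaches, net = net)
}

# Backward pass: dheads is a named list of gradients w.r.t. each raw head
# output. Returns the gradient tree mirroring the trainable parameters.
networkBackward <- function(net, x, fwd, dheads) {
  x <- as_nhwc(x)
  graph <- net$graph
  info <- graphInfo(graph)
  dacc <- list()
  add_d <- function(key, arr) {
    dacc[[key]] <<- if (is.null(dacc[[key]])) arr else dacc[[key]] + arr
  }
  grads <- list(layers = list(), heads = list())
  for (h in names(graph@heads)) {
    r <- head_bwd(net$heads[[h]], dheads[[h]], fwd$hcaches[[h]])
    grads$heads[[h]] <- r$grads
    add_d(as.character(graph@heads[[h]]), r$dx)
  }
  for (l in rev(graph@layers)) {
    key <- as.character(l@index)
    dy <- dacc[[key]]
    if (is.null(dy)) next
    from <- info[[key]]$from
    p <- net$layers[[key]]
    cache <- fwd$caches[[key]]
    if (l@kind == "concat") {
      parts <- split4(dy, cache$channels)
      for (i in seq_along(from)) add_d(as.character(from[i]), parts[[i]])
      next
    }
    if (l@kind == "upsample") {
      add_d(as.character(from[1]), upsample2_bwd(dy))
      next
    }
    r <- switch(l@kind,
      conv = conv_unit_bwd(p, dy, cache),
      bneck = bneck_bwd(p, dy, cache),
      sppf = sppf_bwd(p, dy, cache))
    grads$layers[[key]] <- r$grads
    if (from[1] != -1L) add_d(as.character(from[1]), r$dx)
  }
  grads
}

# --- generic parameter-tree utilities ------------------------------------

TRAINABLE_LEAVES <- c("w", "b", "w1", "b1", "w2", "b2", "gamma", "beta")

walk_params <- function(node, path = character(), fn) {
  if (is.list(node)) {
    for (nm in names(node)) {
      if (nm %in% c("type", "hyper", "cin", "k", "stride", "pad", "groups",
                    "act", "shortcut", "nAnchors", "nClasses",
                    "rmean", "rvar")) next
      walk_params(node[[nm]], c(path, nm), fn)
    }
  } else if (is.numeric(node) && length(path) &&
             path[length(path)] %in% TRAINABLE_LEAVES) {
    fn(path, node)
  }
  invisible(NULL)
}

tree_get <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}

tree_set <- function(tree, path, value) {
  if (length(path) == 1L) {
    tree[[path]] <- value
  } else {
    tree[[path[1]]] <- tree_set(tree[[path[1]]], path[-1], value)
  }
  tree
}

# every trainable leaf of a network, as a list of character paths
networkParamPaths <- function(net) {
  paths <- list()
  for (part in c("layers", "heads")) {
    for (key in names(net[[part]])) {
      walk_params(net[[part]][[key]], c(part, key), function(path, node) {
        paths[[length(paths) + 1L]] <<- path
      })
    }
  }
  paths
}

#' Count parameters of an instantiated network by weight enumeration
#'
#' Walks the parameter tree and sums the length of every trainable array
#' (convolution weights, biases, batch norm affine pairs, squeeze-
#' excitation transforms). Serves as the brute-force cross-check of the
#' closed-form [countParameters()].
#'
#' @param net network from [initNetwork()].
#' @return integer number of trainable scalars.
#' @export
networkParameterCount <- function(net) {
  n <- 0
  for (p in networkParamPaths(net)) n <- n + length(tree_get(net, p))
  as.integer(n)
}

# weight checksum used by the determinism tests
networkChecksum <- function(net) {
  s <- 0
  for (p in networkParamPaths(net)) s <- s + sum(tree_get(net, p))
  s
}
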