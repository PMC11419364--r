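#' Pooling window parameters for size-adaptive spatial pyramid pooling
#'
#' Given an input feature-map side length `w` (pixels) and a required output
#' side length `n`, returns the max-pooling window `k`, stride `s` and
#' padding `p` that map `w` onto exactly `n` output positions:
#' `k = s = ceiling(w / n)` and `p = floor((k * n - w + 1) / 2)`.
#'
#' @param w input spatial size (positive integer).
#' @param n output spatial size (positive integer, `n <= w`).
#' @return a list of class `"SPPFParams"` with elements `w`, `n`, `k`, `s`, `p`.
#' @examples
#' sppWindowParams(13, 4)  # k = s = 4, p = 2
#' sppWindowParams(8, 8)   # identity pooling
#' @export
sppWindowParams <- function(w, n) {
  if (length(w) != 1L || length(n) != 1L || !is.finite(w) || !is.finite(n) ||
      w != as.integer(w) || n != as.integer(n) || w < 1 || n < 1) {
    stop("`w` and `n` must be positive integers")
  }
  if (n > w) stop("output size `n` must not exceed input size `w`")
  k <- as.integer(ceiling(w / n))
  p <- as.integer(floor((k * n - w + 1) / 2))
  structure(list(w = as.integer(w), n = as.integer(n), k = k, s = k, p = p),
            class = "SPPFParams")
}

#' @export
print.SPPFParams <- function(x, ...) {
  cat(sprintf("SPPF pooling: %d -> %d positions (k = s = %d, p = %d)\n",
              x$w, x$n, x$k, x$p))
  invisible(x)
}

#' Fast spatial pyramid pooling forward pass
#'
#' Applies the serial form of multi-window spatial pyramid pooling: three
#' successive stride-1, same-padded max pools with an odd window are
#' concatenated with the unpooled map and fused by a 1x1 convolution.
#' Composing the serial pools reproduces parallel pooling with windows
#' `{k, 2k - 1, 3k - 2}` (for the default 5: `{5, 9, 13}`) at a fraction of
#' the cost.
#'
#' @param x feature map, array `(H, W, C, N)` (single images `(H, W, C)` are
#'   promoted).
#' @param hiddenChannels width of the 1x1 reduction before pooling.
#' @param poolWindow odd pooling window (default 5).
#' @param params optional parameter list from [initSppf()]; when `NULL`,
#'   deterministic He-initialised weights are created from `seed`.
#' @param seed integer seed for weight creation when `params` is `NULL`.
#' @return array `(H, W, Cout, N)` with spatial dims equal to the input.
#' @seealso [sppfPool()] for the pooling stage alone.
#' @export
sppfForward <- function(x, hiddenChannels, poolWindow = 5L, params = NULL,
                        seed = 1L) {
  x <- as_nhwc(x)
  if (poolWindow %% 2 == 0) {
    stop("`poolWindow` must be odd for stride-1 same padding")
  }
  if (min(dim(x)[1:2]) < poolWindow) {
    stop("input spatial dims must be at least `poolWindow`")
  }
  cin <- dim(x)[3]
  if (is.null(params)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    params <- init_sppf(cin, hiddenChannels, cin, poolWindow)
  }
  sppf_fwd(params, x, train = FALSE)$y
}

#' Serial max-pool pyramid (the pooling stage of SPPF)
#'
#' @param x feature map `(H, W, C, N)` or `(H, W, C)`.
#' @param poolWindow odd window size.
#' @return array with `4 * C` channels: input followed by the three serial
#'   pool outputs.
#' @export
sppfPool <- function(x, poolWindow = 5L) {
  x <- as_nhwc(x)
  if (poolWindow %% 2 == 0) stop("`poolWindow` must be odd")
  p <- (poolWindow - 1L) / 2L
  y1 <- maxpool_fwd(x, poolWindow, 1L, p)$y
  y2 <- maxpool_fwd(y1, poolWindow, 1L, p)$y
  y3 <- maxpool_fwd(y2, poolWindow, 1L, p)$y
  abind4(x, y1, y2, y3)
}

#' Parallel multi-window spatial pyramid pooling (reference form)
#'
#' The classic SPP arrangement: one max pool per window size, all stride 1
#' with same padding, concatenated with the input. Used as the independent
#' reference that the serial form must reproduce.
#'
#' @param x feature map `(H, W, C, N)` or `(H, W, C)`.
#' @param windows vector of odd window sizes.
#' @return array with `(1 + length(windows)) * C` channels.
#' @export
sppPool <- function(x, windows = c(5L, 9L, 13L)) {
  x <- as_nhwc(x)
  outs <- lapply(windows, function(k) {
    if (k %% 2 == 0) stop("windows must be odd")
    maxpool_fwd(x, as.integer(k), 1L, as.integer((k - 1) / 2))$y
  })
  do.call(abind4, c(list(x), outs))
}
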