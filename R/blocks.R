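# Trainable block units. Each unit has an init_* constructor producing a
# parameter list, a *_fwd returning list(y, cache, params) and a *_bwd
# returning list(dx, grads) with grads mirroring the parameter arrays.
# Parameter lists are plain so the optimiser can walk them generically.

# --- Conv -> BatchNorm -> activation -------------------------------------

init_conv_unit <- function(cin, cout, k, stride = 1L, act = "hswish",
                           groups = 1L) {
  list(type = "convunit", w = he_init(k, cin / groups, cout),
       bn = bn_init(cout), k = k, stride = as.integer(stride),
       pad = as.integer((k - 1) / 2), groups = as.integer(groups), act = act)
}

conv_unit_fwd <- function(p, x, train = TRUE) {
  z0 <- conv2d_fwd(x, p$w, p$stride, p$pad, p$groups)
  b <- bn_fwd(z0, p$bn, train = train)
  p$bn <- b$bn
  y <- activation_fn(p$act)(b$y)
  list(y = y, params = p, cache = list(x = x, z = b$y, bncache = b$cache))
}

conv_unit_bwd <- function(p, dy, cache) {
  da <- dy * activation_grad_fn(p$act)(cache$z)
  bb <- bn_bwd(da, p$bn, cache$bncache)
  cb <- conv2d_bwd(cache$x, p$w, bb$dx, p$stride, p$pad, p$groups)
  list(dx = cb$dx, grads = list(w = cb$dw, bn = list(gamma = bb$dgamma,
                                                    beta = bb$dbeta)))
}

# --- Squeeze-and-Excitation ----------------------------------------------

init_se <- function(c, reduction = 4L) {
  if (reduction <= 0) stop("`reduction` must be positive")
  r <- roundup8(c / reduction)
  list(type = "se",
       w1 = matrix(stats::rnorm(r * c, sd = sqrt(2 / c)), r, c),
       b1 = rep(0, r),
       w2 = matrix(stats::rnorm(c * r, sd = sqrt(2 / r)), c, r),
       b2 = rep(0, c))
}

bcast_cn <- function(v, d) array(rep(as.vector(v), each = d[1] * d[2]), d)

se_fwd <- function(p, x) {
  d <- dim(x)
  s <- global_avgpool(x)               # (C, N)
  pre1 <- p$w1 %*% s + p$b1
  h <- relu(pre1)
  pre2 <- p$w2 %*% h + p$b2
  g <- hsigmoid(pre2)                  # gate in [0, 1]
  y <- x * bcast_cn(g, d)
  list(y = y, params = p,
       cache = list(x = x, s = s, pre1 = pre1, h = h, pre2 = pre2, g = g))
}

se_bwd <- function(p, dy, cache) {
  d <- dim(cache$x)
  hw <- d[1] * d[2]
  dx <- dy * bcast_cn(cache$g, d)
  # gate gradient: per channel/sample sum of dy * x
  m <- matrix(aperm(dy * cache$x, c(1, 2, 4, 3)), ncol = d[3])
  dg <- t(rowsum(m, rep(seq_len(d[4]), each = hw)))          # (C, N)
  dpre2 <- hsigmoid_grad(cache$pre2) * dg
  dw2 <- dpre2 %*% t(cache$h)
  db2 <- rowSums(dpre2)
  dh <- t(p$w2) %*% dpre2
  dpre1 <- relu_grad(cache$pre1) * dh
  dw1 <- dpre1 %*% t(cache$s)
  db1 <- rowSums(dpre1)
  ds <- t(p$w1) %*% dpre1
  dx <- dx + bcast_cn(ds, d) / hw
  list(dx = dx, grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
}

#' Squeeze-and-excitation channel attention
#'
#' Per-channel global average pooling, a two-layer bottleneck transform
#' (reduce by `reduction`, ReLU, expand back), a hard-sigmoid gate in
#' `[0, 1]` and channel-wise rescaling of the input. The reduced width is
#' rounded up to the nearest multiple of 8.
#'
#' @param x feature map `(H, W, C, N)` or `(H, W, C)`.
#' @param reduction positive integer channel reduction factor.
#' @param params optional parameter list from `init_se`; deterministic
#'   weights are drawn from `seed` when absent.
#' @param seed integer seed used when `params` is `NULL`.
#' @return array of the same shape as `x`.
#' @export
squeezeExcite <- function(x, reduction = 4L, params = NULL, seed = 1L) {
  x <- as_nhwc(x)
  if (is.null(params)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    params <- init_se(dim(x)[3], reduction)
  }
  se_fwd(params, x)$y
}

# save/restore the RNG so convenience constructors do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# --- Inverted residual (bneck) block -------------------------------------

init_bneck <- function(cin, hyper) {
  p <- list(type = "bneck", cin = as.integer(cin), hyper = hyper)
  if (hyper$exp != cin) {
    p$expand <- init_conv_unit(cin, hyper$exp, 1L, 1L, hyper$act)
  }
  p$dw <- init_conv_unit(hyper$exp, hyper$exp, hyper$kernel, hyper$stride,
                         hyper$act, groups = hyper$exp)
  if (isTRUE(hyper$se)) p$se <- init_se(hyper$exp)
  p$proj <- init_conv_unit(hyper$exp, hyper$cout, 1L, 1L, "linear")
  p$shortcut <- hyper$stride == 1L && cin == hyper$cout
  p
}

bneck_fwd <- function(p, x, train = TRUE) {
  cache <- list()
  h <- x
  if (!is.null(p$expand)) {
    r <- conv_unit_fwd(p$expand, h, train); p$expand <- r$params
    cache$expand <- r$cache; h <- r$y
  }
  r <- conv_unit_fwd(p$dw, h, train); p$dw <- r$params
  cache$dw <- r$cache; h <- r$y
  if (!is.null(p$se)) {
    r <- se_fwd(p$se, h); cache$se <- r$cache; h <- r$y
  }
  r <- conv_unit_fwd(p$proj, h, train); p$proj <- r$params
  cache$proj <- r$cache; h <- r$y
  if (p$shortcut) h <- h + x
  list(y = h, params = p, cache = cache)
}

bneck_bwd <- function(p, dy, cache) {
  grads <- list()
  r <- conv_unit_bwd(p$proj, dy, cache$proj)
  grads$proj <- r$grads; d <- r$dx
  if (!is.null(p$se)) {
    r <- se_bwd(p$se, d, cache$se); grads$se <- r$grads; d <- r$dx
  }
  r <- conv_unit_bwd(p$dw, d, cache$dw)
  grads$dw <- r$grads; d <- r$dx
  if (!is.null(p$expand)) {
    r <- conv_unit_bwd(p$expand, d, cache$expand)
    grads$expand <- r$grads; d <- r$dx
  }
  if (p$shortcut) d <- d + dy
  list(dx = d, grads = grads)
}

#' Inverted residual (bneck) forward pass
#'
#' 1x1 expansion convolution (omitted when the expansion width equals the
#' input width), depthwise convolution at the block's stride, optional
#' squeeze-and-excitation, and a linear 1x1 projection. A residual
#' shortcut is added exactly when the stride is 1 and the input and output
#' widths match.
#'
#' @param x feature map `(H, W, C, N)` or `(H, W, C)`.
#' @param cfg list with `kernel` (3 or 5), `exp`, `cout`, `stride` (1 or
#'   2), `se` (logical), `act` (activation kind).
#' @param params optional parameters from `init_bneck`; created from
#'   `seed` when absent.
#' @param seed integer seed used when `params` is `NULL`.
#' @return feature map; spatial dims halve (ceiling) iff `stride` is 2.
#' @export
invertedResidual <- function(x, cfg, params = NULL, seed = 1L) {
  x <- as_nhwc(x)
  if (is.null(params)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    params <- init_bneck(dim(x)[3], cfg)
  }
  bneck_fwd(params, x, train = FALSE)$y
}

# --- SPPF ----------------------------------------------------------------

init_sppf <- function(cin, hidden, cout, k = 5L) {
  list(type = "sppf",
       cv1 = init_conv_unit(cin, hidden, 1L, 1L, "hswish"),
       cv2 = init_conv_unit(4L * hidden, cout, 1L, 1L, "hswish"),
       k = as.integer(k))
}

initSppf <- init_sppf

sppf_fwd <- function(p, x, train = TRUE) {
  r1 <- conv_unit_fwd(p$cv1, x, train); p$cv1 <- r1$params
  a <- r1$y
  pd <- (p$k - 1L) / 2L
  m1 <- maxpool_fwd(a, p$k, 1L, pd)
  m2 <- maxpool_fwd(m1$y, p$k, 1L, pd)
  m3 <- maxpool_fwd(m2$y, p$k, 1L, pd)
  cat4 <- abind4(a, m1$y, m2$y, m3$y)
  r2 <- conv_unit_fwd(p$cv2, cat4, train); p$cv2 <- r2$params
  list(y = r2$y, params = p,
       cache = list(cv1 = r1$cache, cv2 = r2$cache, adim = dim(a),
                    i1 = m1$idx, i2 = m2$idx, i3 = m3$idx))
}

sppf_bwd <- function(p, dy, cache) {
  r2 <- conv_unit_bwd(p$cv2, dy, cache$cv2)
  parts <- split4(r2$dx, rep(cache$adim[3], 4))
  d3 <- maxpool_bwd(parts[[4]], cache$i3, cache$adim)
  d2 <- maxpool_bwd(parts[[3]] + d3, cache$i2, cache$adim)
  d1 <- maxpool_bwd(parts[[2]] + d2, cache$i1, cache$adim)
  da <- parts[[1]] + d1
  r1 <- conv_unit_bwd(p$cv1, da, cache$cv1)
  list(dx = r1$dx, grads = list(cv1 = r1$grads, cv2 = r2$grads))
}

# --- Prediction head ------------------------------------------------------

init_head <- function(cin, nClasses, nAnchors = 3L) {
  cout <- nAnchors * (5L + nClasses)
  # channel layout: per anchor, (x, y, w, h, obj, classes...); objectness
  # and class biases start low so the initial prediction field is sparse
  list(type = "head",
       w = he_init(1L, cin, cout) * 0.01,
       b = rep(c(rep(0, 4), -4, rep(-2, nClasses)), times = nAnchors),
       nAnchors = as.integer(nAnchors), nClasses = as.integer(nClasses))
}

head_fwd <- function(p, x, train = TRUE) {
  z <- conv2d_fwd(x, p$w, 1L, 0L, 1L)
  d <- dim(z)
  z <- z + bcast_cn(matrix(p$b, d[3], d[4]), d)
  list(y = z, params = p, cache = list(x = x))
}

head_bwd <- function(p, dy, cache) {
  d <- dim(dy)
  db <- colSums(matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3]))
  cb <- conv2d_bwd(cache$x, p$w, dy, 1L, 0L, 1L)
  list(dx = cb$dx, grads = list(w = cb$dw, b = db))
}

#' Per-scale prediction head
#'
#' A 1x1 convolution (with bias) mapping a fused feature map to
#' `nAnchors * (5 + nClasses)` channels: per anchor, the raw box offsets
#' `(x, y, w, h)`, the objectness logit and the class logits. The output
#' grid equals the input spatial size.
#'
#' @param x feature map `(H, W, C, N)` or `(H, W, C)`.
#' @param nAnchors anchors per head.
#' @param nClasses number of classes.
#' @param params optional parameters from `init_head`.
#' @param seed integer seed used when `params` is `NULL`.
#' @return array `(H, W, nAnchors * (5 + nClasses), N)`.
#' @export
predictionHead <- function(x, nAnchors = 3L, nClasses = 4L, params = NULL,
                           seed = 1L) {
  x <- as_nhwc(x)
  if (is.null(params)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    params <- init_head(dim(x)[3], nClasses, nAnchors)
  }
  head_fwd(params, x)$y
}
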