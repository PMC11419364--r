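# Thin R layer over the compiled primitives plus the few ops that are
# cheap enough in vectorised R (batch norm, nearest upsampling, global
# average pooling). All feature maps are (H, W, C, N) double arrays.

as_nhwc <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps must be arrays")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature maps must have 2-4 dimensions")
  x
}

# concatenate 4-d arrays along the channel axis
abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  for (x in xs) {
    dx <- dim(x)
    if (!identical(dx[c(1, 2, 4)], d[c(1, 2, 4)])) {
      stop("concat sources must share spatial dims and batch size")
    }
  }
  cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(cs[i]), ] <- xs[[i]]
    at <- at + cs[i]
  }
  out
}

split4 <- function(dy, channels) {
  # inverse of abind4: split the channel axis into chunks of the given sizes
  at <- 0L
  lapply(channels, function(cc) {
    z <- dy[, , at + seq_len(cc), , drop = FALSE]
    at <<- at + cc
    z
  })
}

conv2d_fwd <- function(x, w, stride = 1L, pad = 0L, groups = 1L) {
  cpp_conv2d_fwd(x, w, as.integer(stride), as.integer(pad), as.integer(groups))
}

conv2d_bwd <- function(x, w, dy, stride = 1L, pad = 0L, groups = 1L) {
  cpp_conv2d_bwd(x, w, dy, as.integer(stride), as.integer(pad),
                 as.integer(groups))
}

maxpool_fwd <- function(x, k, stride, pad) {
  cpp_maxpool_fwd(x, as.integer(k), as.integer(stride), as.integer(pad))
}

maxpool_bwd <- function(dy, idx, xdim) {
  cpp_maxpool_bwd(dy, idx, as.integer(xdim))
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  ho <- seq(1L, d[1], by = 2L); wo <- seq(1L, d[2], by = 2L)
  dy[ho, wo, , , drop = FALSE] + dy[ho + 1L, wo, , , drop = FALSE] +
    dy[ho, wo + 1L, , , drop = FALSE] + dy[ho + 1L, wo + 1L, , , drop = FALSE]
}

# --- batch normalisation -------------------------------------------------
# Training mode normalises with batch statistics over (H, W, N) per channel
# and maintains exponential running averages for inference.

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       rmean = rep(0, c), rvar = rep(1, c))
}

bn_fwd <- function(x, bn, train = TRUE, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # rows: H*W*N
  if (train) {
    mu <- colMeans(m)
    xc <- sweep(m, 2, mu)
    va <- colMeans(xc * xc)
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * mu
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * va
  } else {
    mu <- bn$rmean; va <- bn$rvar
    xc <- sweep(m, 2, mu)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
  ya <- aperm(array(y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(y = ya, bn = bn,
       cache = list(xhat = xhat, istd = istd, dims = d, train = train))
}

bn_bwd <- function(dy, bn, cache) {
  d <- cache$dims
  dm <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  if (cache$train) {
    # full batch-statistics gradient
    t1 <- sweep(dm, 2, bn$gamma, `*`)
    s1 <- colMeans(t1)
    s2 <- colMeans(t1 * cache$xhat)
    dx <- sweep(t1, 2, s1) - sweep(cache$xhat, 2, s2, `*`)
    dx <- sweep(dx, 2, cache$istd, `*`)
  } else {
    dx <- sweep(sweep(dm, 2, bn$gamma, `*`), 2, cache$istd, `*`)
  }
  dxa <- aperm(array(dx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dxa, dgamma = dgamma, dbeta = dbeta)
}

global_avgpool <- function(x) {
  d <- dim(x)
  # returns (C, N)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  t(rowsum(m, rep(seq_len(d[4]), each = d[1] * d[2]))) / (d[1] * d[2])
}

# He-normal initialisation for a conv weight of shape (k, k, cin/groups, cout)
he_init <- function(k, cin_g, cout) {
  fan_in <- k * k * cin_g
  array(stats::rnorm(k * k * cin_g * cout, sd = sqrt(2 / fan_in)),
        c(k, k, cin_g, cout))
}
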